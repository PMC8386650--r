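# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no files are read.

# GIRK concentration-response parameter sets as printed for the four
# agonists (pEC50, Emax).
girk_legend_truths <- function(noise_sd = 0) {
  list(
    bret_truth("dopamine", "GIRK", 7.88, 1.07, noise_sd = noise_sd),
    bret_truth("S-5-OH-DPAT", "GIRK", 7.94, 1.99, noise_sd = noise_sd),
    bret_truth("R-5-OH-DPAT", "GIRK", 6.02, 0.78, noise_sd = noise_sd),
    bret_truth("p-tyramine", "GIRK", 4.06, 0.66, noise_sd = noise_sd)
  )
}

# Two-pathway operational dataset in which the test agonist carries a
# prescribed between-pathway ddlog(tau/KA) and the reference is unbiased.
two_pathway_bias_truth <- function(ddlog, base_log_r = 8) {
  lr <- data.frame(
    agonist = rep(c("reference", "test"), each = 2),
    pathway = rep(c("GoB", "barr2"), 2),
    log_r = c(base_log_r, base_log_r,
              base_log_r + ddlog / 2, base_log_r - ddlog / 2)
  )
  operational_truth(em = 1, Basal = 0, n = 1,
                    log_ka = c(reference = 0, test = 0), log_r = lr)
}

# Brute-force Hill oracle: exhaustive grid over (pEC50, hill_n) with the
# conditionally-linear (basal, top) solved in closed form per grid point.
grid_search_hill <- function(conc, resp, pec50_grid, n_grid) {
  x <- log10(conc)
  combs <- expand.grid(pec50 = pec50_grid, hill_n = n_grid,
                       KEEP.OUT.ATTRS = FALSE)
  m <- length(x)
  best <- list(rss = Inf)
  for (i in seq_len(nrow(combs))) {
    s <- 1 / (1 + 10^(combs$hill_n[i] * (-combs$pec50[i] - x)))
    s1 <- sum(s); s2 <- sum(s * s)
    sy <- sum(resp); ssy <- sum(s * resp)
    den <- m * s2 - s1^2
    if (abs(den) < 1e-12) next
    top <- (m * ssy - s1 * sy) / den
    basal <- (sy - top * s1) / m
    rss <- sum((resp - basal - top * s)^2)
    if (rss < best$rss) {
      best <- list(rss = rss, pec50 = combs$pec50[i],
                   hill_n = combs$hill_n[i], top = top, basal = basal)
    }
  }
  best
}
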