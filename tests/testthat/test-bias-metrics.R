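test_that("AUC matches the analytic log-domain integral at unit slope", {
  d <- generate_bret_dataset(bret_truth("a", "p", 6, 1, hill_n = 1),
                             n_rep = 1)
  f <- fit_hill(d)
  auc <- compute_auc(f, window = c(-9, -3))
  # closed form: (1/ln10) [ln(1 + 10^(x + pEC50))] over the window
  softplus10 <- function(x) log(1 + 10^(x + 6)) / log(10)
  expect_equal(auc, softplus10(-3) - softplus10(-9), tolerance = 1e-4)

  # linearity in top (basal excluded from the integral)
  f2 <- f
  f2$top <- 2 * f$top
  expect_equal(compute_auc(f2, c(-9, -3)), 2 * auc, tolerance = 1e-9)

  # zero span integrates to zero; unconverged fits propagate as NA
  f0 <- f
  f0$top <- 0
  expect_equal(compute_auc(f0, c(-9, -3)), 0)
  fu <- f
  fu$converged <- FALSE
  expect_true(is.na(compute_auc(fu, c(-9, -3))))
})

test_that("coupling ratios are exactly 1 for the reference and scale-free", {
  aucs <- expand.grid(agonist = c("dopamine", "x"),
                      pathway = c("GoB", "Gz", "Gi2", "barr2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  aucs$auc <- c(2, 4, 1, 2, 3, 6, 1.5, 3)  # x = 2 * dopamine everywhere
  prof <- coupling_ratios(aucs, "dopamine")
  expect_true(all(prof$normalized$dopamine == 1))
  # uniform scaling of one agonist cancels
  expect_true(all(abs(prof$normalized$x - 1) < 1e-12))
  # reciprocal symmetry ratio(i,j) * ratio(j,i) = 1
  m <- prof$normalized$x
  expect_equal(m * t(m), matrix(1, 4, 4, dimnames = dimnames(m)))
})

test_that("halving one pathway AUC doubles the opposing coupling ratio", {
  aucs <- expand.grid(agonist = c("dopamine", "ptyr"),
                      pathway = c("GoB", "Gz", "barr2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  aucs$auc <- 1
  aucs$auc[aucs$agonist == "ptyr" & aucs$pathway == "barr2"] <- 0.5
  prof <- coupling_ratios(aucs, "dopamine")
  expect_equal(prof$normalized$ptyr["GoB", "barr2"], 2)
  expect_equal(prof$normalized$ptyr["barr2", "GoB"], 0.5)
})

test_that("coupling ratios are invariant to per-pathway assay scaling", {
  trs <- list(bret_truth("dopamine", "GoB", 7.5, 1),
              bret_truth("dopamine", "barr2", 7.2, 0.8),
              bret_truth("x", "GoB", 6.5, 0.9),
              bret_truth("x", "barr2", 6.0, 0.3))
  d <- generate_bret_dataset(trs, n_rep = 1)
  p1 <- auc_coupling_pipeline(d, "dopamine")
  # rescale one biosensor's responses (all agonists) by a constant
  d2 <- d
  sel <- d2$pathway == "barr2"
  d2$response[sel] <- d2$response[sel] * 5
  p2 <- auc_coupling_pipeline(d2, "dopamine")
  expect_equal(p2$normalized$x, p1$normalized$x, tolerance = 1e-6)
})

test_that("zero or missing reference AUCs raise named errors", {
  aucs <- data.frame(agonist = rep(c("r", "x"), each = 2),
                     pathway = rep(c("p1", "p2"), 2),
                     auc = c(1, 0, 1, 1))
  expect_error(coupling_ratios(aucs, "r"), "p2")
  expect_error(coupling_ratios(aucs[-2, ], "r"), "p2")
})

test_that("global operational fit recovers shared and per-agonist truth", {
  lr <- data.frame(agonist = c("reference", "test", "weak"),
                   pathway = "GoB",
                   log_r = c(8, 7.2, 6.1))
  ot <- operational_truth(em = 1, Basal = 0, n = 1,
                          log_ka = c(reference = 0, test = 0, weak = 0),
                          log_r = lr)
  d <- generate_operational_dataset(ot, n_rep = 1)
  fit <- fit_operational_global(d)
  expect_true(fit$converged)
  for (a in lr$agonist) {
    expect_equal(unname(fit$log_r[[a]]), lr$log_r[lr$agonist == a],
                 tolerance = 0.02 / 8)
  }
  expect_equal(fit$em, 1, tolerance = 0.01)
  expect_equal(fit$n, 1, tolerance = 0.02)

  expect_error(fit_operational_global(d[d$agonist == "test", ]),
               "at least 2 agonists")
})

test_that("full-agonist curves have their half-max at 1/tau", {
  # KA fixed at 1 M and [A] << 1 M: midpoint at [A] = 1/R
  mid <- operational_response(10^-7.3, em = 1, Basal = 0.05, n = 1,
                              log_ka = 0, log_r = 7.3)
  expect_equal(mid, 0.05 + (1 - 0.05) / 2, tolerance = 1e-6)
})

test_that("delta log R and bias factors obey their arithmetic identities", {
  lr <- data.frame(agonist = c("a", "b"), pathway = "p",
                   log_r = c(6.5, 7.0))
  ot <- operational_truth(em = 1, Basal = 0, n = 1,
                          log_ka = c(a = 0, b = 0), log_r = lr)
  fit <- fit_operational_global(generate_operational_dataset(ot, n_rep = 1))
  expect_equal(delta_log_r(fit, "b", "b"), 0)
  expect_equal(delta_log_r(fit, "a", "b"), -0.5, tolerance = 1e-3)
  expect_equal(delta_log_r(fit, "a", "b"), -delta_log_r(fit, "b", "a"))
  expect_error(delta_log_r(fit, "zz", "b"), "zz")

  expect_equal(bias_factor(0.3, 0.3), 1)
  expect_equal(bias_factor(1, 0) * bias_factor(0, 1), 1)
})

test_that("two-pathway pipeline recovers a planted 12-fold bias", {
  d <- generate_operational_dataset(two_pathway_bias_truth(log10(12)),
                                    n_rep = 1)
  bt <- bias_table(d, reference = "reference",
                   pathways = c("GoB", "barr2"))
  expect_equal(bt$bias[bt$agonist == "reference"], 1, tolerance = 1e-6)
  expect_equal(bt$bias[bt$agonist == "test"], 12, tolerance = 0.05)
  # antisymmetry of the pathway order
  bt2 <- bias_table(d, reference = "reference",
                    pathways = c("barr2", "GoB"))
  expect_equal(bt$bias[bt$agonist == "test"] *
                 bt2$bias[bt2$agonist == "test"], 1, tolerance = 1e-6)
})

test_that("bootstrap CI covers the generating bias under noise", {
  d <- generate_operational_dataset(two_pathway_bias_truth(log10(12)),
                                    n_rep = 3, noise_sd = 0.05, seed = 31)
  bt <- bias_table(d, reference = "reference",
                   pathways = c("GoB", "barr2"), n_boot = 200, seed = 8)
  row <- bt[bt$agonist == "test", ]
  expect_lt(row$ci_lo, 12)
  expect_gt(row$ci_hi, 12)
  expect_lt(row$ci_lo, row$ci_hi)
})
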