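#' Normalize a GIRK trace to its peak current
#'
#' Divides the current by its maximum so the output peaks at exactly 1.
#' When a \code{baseline} is supplied (the agonist-independent current
#' level) it is subtracted first.
#'
#' @param trace data.frame with columns \code{time_s}, \code{current}
#' @param baseline optional agonist-independent current to subtract
#'   before normalization
#' @return the trace with normalized current
#' @export
normalize_to_peak <- function(trace, baseline = NULL) {
  validate_girk_trace(trace)
  if (!is.null(baseline)) trace$current <- trace$current - baseline
  peak <- max(trace$current)
  if (peak <= 0) stop("peak current must be positive")
  trace$current <- trace$current / peak
  trace
}

validate_girk_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "current") %in% names(trace)))
  if (nrow(trace) < 2) stop("trace needs at least 2 samples")
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  invisible(trace)
}

#' Residual current fraction at the end of an application
#'
#' Mean peak-normalized current over the final averaging window ending at
#' \code{t_end} (default 5 s wide, for noise robustness at 156 Hz
#' sampling). A value near 1 means no desensitization; small values mean
#' strong desensitization over the application.
#'
#' @param trace GIRK trace data.frame
#' @param t_end end of the readout window, s (within the trace)
#' @param window averaging window width, s
#' @return fraction of peak remaining
#' @export
residual_fraction <- function(trace, t_end = 415, window = 5) {
  validate_girk_trace(trace)
  dt <- stats::median(diff(trace$time_s))
  if (t_end > max(trace$time_s) + dt) {  # one sample period of slack
    stop("t_end is beyond the end of the trace")
  }
  tr <- normalize_to_peak(trace)
  sel <- tr$time_s >= (t_end - window) & tr$time_s <= t_end
  if (!any(sel)) sel <- which.min(abs(tr$time_s - t_end))
  mean(tr$current[sel])
}

#' Fit a monoexponential decay to the post-peak segment
#'
#' Least-squares fit of \code{plateau + (1 - plateau) exp(-(t - t_peak) /
#' tau)} to the peak-normalized current after the peak. A trace with no
#' measurable decay (plateau ~ 1) leaves tau unidentifiable and is
#' flagged rather than raising an error.
#'
#' @param trace GIRK trace data.frame
#' @param from_peak logical; fit from the peak sample (TRUE) or from the
#'   trace start
#' @return list with \code{decay_tau} (s), \code{plateau},
#'   \code{t_peak}, \code{converged}, \code{identifiable}
#' @export
fit_monoexponential_decay <- function(trace, from_peak = TRUE) {
  tr <- normalize_to_peak(trace)
  i_peak <- if (from_peak) which.max(tr$current) else 1L
  seg <- tr[i_peak:nrow(tr), ]
  if (nrow(seg) < 20) stop("need at least 20 samples after the peak")
  t <- seg$time_s - seg$time_s[1]
  y <- seg$current

  out <- list(decay_tau = NA_real_, plateau = mean(y),
              t_peak = tr$time_s[i_peak], converged = FALSE,
              identifiable = TRUE)
  if (diff(range(y)) < 1e-6) {
    out$identifiable <- FALSE
    return(out)
  }
  resid_fun <- function(p) {
    y - (p[["plateau"]] + (1 - p[["plateau"]]) * exp(-t / p[["tau"]]))
  }
  best <- NULL
  for (tau0 in c(0.1, 0.5, 2) * max(t[length(t)], 1)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = c(plateau = min(y), tau = tau0),
                         lower = c(plateau = -1, tau = 1e-6),
                         upper = c(plateau = 1, tau = Inf),
                         fn = resid_fun),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(res = res,
                                                              rss = rss)
  }
  if (is.null(best)) return(out)
  out$decay_tau <- best$res$par[["tau"]]
  out$plateau <- best$res$par[["plateau"]]
  out$converged <- best$res$info %in% 1:4
  # plateau at 1 means the exponential term never acts: tau is meaningless
  if (out$plateau > 1 - 1e-4) out$identifiable <- FALSE
  out
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Standard one-way ANOVA across condition groups of residual-current
#' fractions (or any scalar readout), followed by pairwise two-sided
#' pooled-SD t tests with Bonferroni adjustment (raw p multiplied by the
#' number of pairs, capped at 1).
#'
#' @param values numeric readouts
#' @param group condition labels, same length
#' @return list with \code{F}, \code{p}, \code{df}, and \code{pairwise}
#'   (data.frame of group pairs with raw and adjusted p)
#' @export
compare_groups <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  n_per <- table(group)
  if (any(n_per < 2)) stop("every group needs at least 2 observations")

  fit <- stats::aov(values ~ group)
  a <- summary(fit)[[1]]
  pt <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                               pool.sd = TRUE)
  raw <- pt$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  k <- nrow(pairs)
  pairwise <- data.frame(
    group1 = rownames(raw)[pairs[, 1]],
    group2 = colnames(raw)[pairs[, 2]],
    p_raw = raw[pairs],
    p_bonferroni = pmin(1, raw[pairs] * k)
  )
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       df = a[["Df"]], pairwise = pairwise)
}

#' Read / write a GIRK current trace CSV (columns time_s, current)
#'
#' @param path file path
#' @return data.frame (reader)
#' @export
read_girk_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_girk_trace(d)
  d
}

#' @rdname read_girk_csv
#' @param trace trace to write
#' @export
write_girk_csv <- function(trace, path) {
  validate_girk_trace(trace)
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
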