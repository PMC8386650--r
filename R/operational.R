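#' Black-Leff operational model of agonism
#'
#' Effect as a function of agonist concentration in the tau-explicit form
#' \deqn{E = Basal + (E_m - Basal) \frac{\tau^n [A]^n}
#'   {([A] + K_A)^n + \tau^n [A]^n},}
#' with \eqn{\tau = 10^{\log R + \log K_A}} so that \eqn{\log R =
#' \log(\tau/K_A)} is the transduction coefficient reported per agonist.
#'
#' @param conc agonist concentration, molar
#' @param em system maximal response
#' @param Basal response in the absence of agonist (\code{em > Basal})
#' @param n transducer slope
#' @param log_ka log10 functional dissociation constant (molar); 0 for
#'   full agonists
#' @param log_r log10 transduction ratio log(tau/KA)
#' @return numeric vector of effects
#' @export
operational_response <- function(conc, em, Basal, n, log_ka, log_r) {
  if (em <= Basal) stop("em must exceed Basal")
  stopifnot(n > 0, all(conc >= 0))
  ka <- 10^log_ka
  tau <- 10^(log_r + log_ka)
  num <- (tau * conc)^n
  Basal + (em - Basal) * num / ((conc + ka)^n + num)
}

#' Global operational-model fit for one pathway
#'
#' Joint least-squares fit of the operational equation to all agonists'
#' curves in one pathway. \code{Basal}, \code{Em} and \code{n} are shared
#' across agonists; each agonist gets its own log R = log(tau/KA). For
#' agonists listed as full, log KA is constrained to zero; for partial
#' agonists it is estimated. Starting values come from a deterministic
#' grid (per-curve Hill fits seed log R; slopes 0.5, 1, 2), the start
#' with the lowest residual sum of squares winning.
#'
#' @param data long-format concentration-response data.frame restricted
#'   to a single pathway (or carrying one \code{pathway} level)
#' @param full_agonists character vector of agonist labels treated as
#'   full (log KA fixed at 0); defaults to all agonists
#' @return an \code{operational_fit}: list with shared \code{em},
#'   \code{basal}, \code{n}; named vectors \code{log_r}, \code{log_ka},
#'   \code{se_log_r}; \code{rss}, \code{converged}, \code{pathway},
#'   and the fitted data in \code{data}
#' @export
fit_operational_global <- function(data, full_agonists = NULL) {
  validate_crc_data(data)
  if (length(unique(data$pathway)) != 1) {
    stop("fit one pathway at a time")
  }
  agonists <- sort(unique(data$agonist))
  if (length(agonists) < 2) {
    stop("parameter sharing needs at least 2 agonists")
  }
  if (is.null(full_agonists)) full_agonists <- agonists
  partial <- setdiff(agonists, full_agonists)

  tab <- table(data$agonist, data$conc_M)
  if (any(rowSums(tab > 0) < 4)) {
    stop("each agonist needs at least 4 distinct concentrations")
  }

  conc <- data$conc_M
  resp <- data$response
  ag_idx <- match(data$agonist, agonists)
  n_ag <- length(agonists)

  # parameter vector: em, basal, n, log_r[1..n_ag], log_ka[partial]
  unpack <- function(p) {
    log_ka <- stats::setNames(rep(0, n_ag), agonists)
    if (length(partial)) {
      log_ka[partial] <- p[paste0("log_ka.", partial)]
    }
    list(em = p[["em"]], basal = p[["basal"]], n = p[["n"]],
         log_r = stats::setNames(p[paste0("log_r.", agonists)], agonists),
         log_ka = log_ka)
  }
  resid_fun <- function(p) {
    q <- unpack(p)
    ka <- 10^q$log_ka[ag_idx]
    tau <- 10^(q$log_r[ag_idx] + q$log_ka[ag_idx])
    num <- (tau * conc)^q$n
    resp - (q$basal + (q$em - q$basal) * num / ((conc + ka)^q$n + num))
  }

  # deterministic initials: per-curve Hill fits give log R ~ pEC50 (KA = 1)
  hl <- lapply(split(data, data$agonist), function(d) {
    tryCatch(fit_hill(d), error = function(e) NULL)
  })
  lr0 <- vapply(agonists, function(a) {
    f <- hl[[a]]
    if (!is.null(f) && isTRUE(f$converged)) f$pec50 else -mean(log10(conc))
  }, numeric(1))
  em0 <- max(resp)
  basal0 <- min(resp)

  lower <- c(em = -Inf, basal = -Inf, n = 0.1,
             stats::setNames(rep(-Inf, n_ag), paste0("log_r.", agonists)))
  upper <- c(em = Inf, basal = Inf, n = 10,
             stats::setNames(rep(Inf, n_ag), paste0("log_r.", agonists)))
  if (length(partial)) {
    lower <- c(lower, stats::setNames(rep(-12, length(partial)),
                                      paste0("log_ka.", partial)))
    upper <- c(upper, stats::setNames(rep(6, length(partial)),
                                      paste0("log_ka.", partial)))
  }

  best <- NULL
  for (n0 in c(0.5, 1, 2)) {
    p0 <- c(em = em0, basal = basal0, n = n0,
            stats::setNames(lr0, paste0("log_r.", agonists)))
    if (length(partial)) {
      p0 <- c(p0, stats::setNames(rep(0, length(partial)),
                                  paste0("log_ka.", partial)))
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(res = res,
                                                              rss = rss)
  }
  if (is.null(best)) stop("operational fit failed from all starts")

  q <- unpack(best$res$par)
  se <- rep(NA_real_, length(best$res$par))
  names(se) <- names(best$res$par)
  dof <- length(resp) - length(best$res$par)
  if (dof > 0) {
    cv <- tryCatch(chol2inv(chol(t(best$res$jac) %*% best$res$jac)) *
                     best$rss / dof, error = function(e) NULL)
    if (!is.null(cv)) se[] <- sqrt(pmax(diag(cv), 0))
  }
  structure(list(
    em = q$em, basal = q$basal, n = q$n,
    log_r = q$log_r, log_ka = q$log_ka,
    se_log_r = stats::setNames(se[paste0("log_r.", agonists)], agonists),
    full_agonists = intersect(agonists, full_agonists),
    rss = best$rss, converged = best$res$info %in% 1:4,
    pathway = unique(data$pathway), data = data
  ), class = "operational_fit")
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("Operational-model fit, pathway %s\n", x$pathway))
  cat(sprintf("  shared: Em = %.3f  Basal = %.3f  n = %.3f  RSS = %.3g\n",
              x$em, x$basal, x$n, x$rss))
  for (a in names(x$log_r)) {
    cat(sprintf("  %-14s logR = %7.3f  logKA = %6.2f%s\n", a,
                x$log_r[[a]], x$log_ka[[a]],
                if (a %in% x$full_agonists) " (full)" else " (partial)"))
  }
  invisible(x)
}

#' Reference-normalized transduction coefficient
#'
#' Delta log(tau/KA) of an agonist against the reference agonist within
#' one fitted pathway.
#'
#' @param fit an \code{operational_fit}
#' @param agonist,reference agonist labels present in the fit
#' @return numeric Delta log(tau/KA)
#' @export
delta_log_r <- function(fit, agonist, reference) {
  stopifnot(inherits(fit, "operational_fit"))
  for (a in c(agonist, reference)) {
    if (!a %in% names(fit$log_r)) stop("agonist '", a, "' not in fit")
  }
  unname(fit$log_r[[agonist]] - fit$log_r[[reference]])
}

#' Between-pathway bias factor
#'
#' \code{10^(delta1 - delta2)}: the fold preference of pathway 1 over
#' pathway 2 after reference-agonist normalization. The sign convention
#' is pathway1 minus pathway2.
#'
#' @param delta1,delta2 Delta log(tau/KA) of the same agonist vs the same
#'   reference in the two pathways
#' @return fold bias (ratio scale)
#' @export
bias_factor <- function(delta1, delta2) {
  10^(delta1 - delta2)
}

#' Full bias table for a two-pathway comparison
#'
#' Runs the global operational fit in each pathway, normalizes log(tau/KA)
#' to the reference agonist, and reports the between-pathway
#' delta-delta log(tau/KA) and fold bias per agonist, optionally with a
#' percentile bootstrap CI from residual resampling (each bootstrap
#' dataset refits both pathways from the original fit's parameters).
#'
#' @param data long-format data.frame with exactly the two pathways
#' @param reference reference agonist label (its bias is 1 by construction)
#' @param pathways character(2): the ordered pathway pair; bias > 1 means
#'   preference for \code{pathways[1]}
#' @param full_agonists labels with log KA fixed at 0 (default all)
#' @param n_boot bootstrap replicates (0 = no CI)
#' @param seed RNG seed for the bootstrap
#' @return a \code{bias_table} data.frame: agonist, delta_1, delta_2,
#'   ddlog, bias, and (with bootstrap) ci_lo, ci_hi; fits attached as
#'   attributes \code{fit1}, \code{fit2}
#' @export
bias_table <- function(data, reference, pathways = NULL,
                       full_agonists = NULL, n_boot = 0, seed = 1) {
  validate_crc_data(data)
  if (is.null(pathways)) pathways <- sort(unique(data$pathway))
  stopifnot(length(pathways) == 2)
  d1 <- data[data$pathway == pathways[1], ]
  d2 <- data[data$pathway == pathways[2], ]
  fit1 <- fit_operational_global(d1, full_agonists)
  fit2 <- fit_operational_global(d2, full_agonists)
  agonists <- intersect(names(fit1$log_r), names(fit2$log_r))
  if (!reference %in% agonists) stop("reference must be in both pathways")

  one_table <- function(f1, f2) {
    dd <- vapply(agonists, function(a) {
      delta_log_r(f1, a, reference) - delta_log_r(f2, a, reference)
    }, numeric(1))
    dd
  }
  dd <- one_table(fit1, fit2)
  out <- data.frame(
    agonist = agonists,
    delta_1 = vapply(agonists, delta_log_r, numeric(1), fit = fit1,
                     reference = reference),
    delta_2 = vapply(agonists, delta_log_r, numeric(1), fit = fit2,
                     reference = reference),
    ddlog = dd,
    bias = 10^dd,
    row.names = NULL
  )

  if (n_boot > 0) {
    boot <- withr::with_seed(seed, {
      replicate(n_boot, {
        b1 <- resample_residuals(fit1)
        b2 <- resample_residuals(fit2)
        f1 <- tryCatch(fit_operational_global(b1, full_agonists),
                       error = function(e) NULL)
        f2 <- tryCatch(fit_operational_global(b2, full_agonists),
                       error = function(e) NULL)
        if (is.null(f1) || is.null(f2)) rep(NA_real_, length(agonists))
        else one_table(f1, f2)
      })
    })
    boot <- matrix(boot, nrow = length(agonists))
    qs <- apply(10^boot, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    out$ci_lo <- qs[1, ]
    out$ci_hi <- qs[2, ]
  }
  attr(out, "pathways") <- pathways
  attr(out, "reference") <- reference
  attr(out, "fit1") <- fit1
  attr(out, "fit2") <- fit2
  class(out) <- c("bias_table", "data.frame")
  out
}

# Parametric bootstrap dataset: fitted means + resampled residuals.
resample_residuals <- function(fit) {
  d <- fit$data
  ka <- 10^fit$log_ka[d$agonist]
  tau <- 10^(fit$log_r[d$agonist] + fit$log_ka[d$agonist])
  num <- (tau * d$conc_M)^fit$n
  mu <- fit$basal + (fit$em - fit$basal) * num /
    ((d$conc_M + ka)^fit$n + num)
  r <- d$response - mu
  d$response <- mu + sample(r, length(r), replace = TRUE)
  d
}
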