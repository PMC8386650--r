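#' Variable-slope sigmoid (Hill) response
#'
#' Evaluates the four-parameter logistic used for concentration-response
#' curves, parameterized on the log10-concentration axis:
#' \deqn{Y = basal + top / (1 + 10^{n (-pEC50 - \log_{10} c)})}
#' so that \code{Y(EC50) = basal + top/2} and \code{top} is the span above
#' basal (the maximal response, Emax, when \code{basal = 0}).
#'
#' @param conc agonist concentration in molar (strictly positive)
#' @param pec50 negative log10 of the half-maximal concentration
#' @param top maximal response above basal (Emax)
#' @param hill_n Hill slope (> 0)
#' @param basal response in the absence of agonist
#' @return numeric vector of responses
#' @export
hill_response <- function(conc, pec50, top, hill_n = 1, basal = 0) {
  stopifnot(all(conc > 0), is.finite(pec50), hill_n > 0)
  basal + top / (1 + 10^(hill_n * (-pec50 - log10(conc))))
}

# Deterministic grid of starting values spanning the assayed window.
# pEC50 initials are ordered increasing so that the RSS tie-break
# ("lowest pEC50 initial wins") is simply the first best.
hill_start_grid <- function(logc, resp) {
  pec50_0 <- seq(-max(logc), -min(logc), length.out = 7)
  span <- max(resp) - min(resp)
  expand.grid(
    pec50 = pec50_0,
    top = if (span > 0) span else 1,
    hill_n = c(0.5, 1, 2),
    basal = min(resp),
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Fit a variable-slope concentration-response curve
#'
#' Unweighted least-squares fit of \code{\link{hill_response}} to one curve.
#' The optimizer is started from a fixed deterministic grid of initial
#' values (7 pEC50 values spanning the assayed window crossed with Hill
#' slopes 0.5, 1, 2); the start with the lowest residual sum of squares
#' wins, ties going to the lowest pEC50 initial. The Hill slope is
#' constrained to (0.1, 10) to prevent degenerate step-function fits.
#'
#' @param data data.frame with columns \code{conc_M} and \code{response}
#'   (one curve; aggregate or replicate-level rows both work)
#' @param fix_basal optional numeric; when given, basal is held at this
#'   value rather than estimated
#' @return an object of class \code{hill_fit}: a list with elements
#'   \code{pec50}, \code{top}, \code{hill_n}, \code{basal}, \code{se}
#'   (named vector of standard errors), \code{rss}, \code{converged},
#'   \code{extrapolated} (TRUE when the fitted pEC50 lies more than one
#'   log unit outside the assayed window), \code{n_obs} and
#'   \code{logc_range}.
#' @export
fit_hill <- function(data, fix_basal = NULL) {
  stopifnot(is.data.frame(data), all(c("conc_M", "response") %in% names(data)))
  if (any(data$conc_M <= 0)) stop("concentrations must be strictly positive")
  if (!all(is.finite(data$response))) stop("responses must be finite")
  n_conc <- length(unique(data$conc_M))
  if (n_conc < 4) stop("need at least 4 distinct concentrations to fit")

  logc <- log10(data$conc_M)
  resp <- data$response
  fit0 <- list(
    pec50 = NA_real_, top = NA_real_, hill_n = NA_real_, basal = NA_real_,
    se = c(pec50 = NA_real_, top = NA_real_, hill_n = NA_real_,
           basal = NA_real_),
    rss = NA_real_, converged = FALSE, extrapolated = FALSE,
    n_obs = length(resp), logc_range = range(logc)
  )
  class(fit0) <- "hill_fit"

  # A flat curve carries no information about pEC50: flag, don't error.
  if (diff(range(resp)) <= 1e-12 * max(1, abs(mean(resp)))) {
    fit0$basal <- mean(resp)
    fit0$top <- 0
    return(fit0)
  }

  starts <- hill_start_grid(logc, resp)
  fixed_basal <- !is.null(fix_basal)
  lower <- c(pec50 = -max(logc) - 6, top = -Inf, hill_n = 0.1)
  upper <- c(pec50 = -min(logc) + 6, top = Inf, hill_n = 10)
  if (!fixed_basal) {
    lower <- c(lower, basal = -Inf)
    upper <- c(upper, basal = Inf)
  }

  resid_fun <- function(p) {
    b <- if (fixed_basal) fix_basal else p[["basal"]]
    resp - (b + p[["top"]] / (1 + 10^(p[["hill_n"]] * (-p[["pec50"]] - logc))))
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(pec50 = starts$pec50[i], top = starts$top[i],
            hill_n = starts$hill_n[i])
    if (!fixed_basal) p0 <- c(p0, basal = starts$basal[i])
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(res = res, rss = rss)
    }
  }
  if (is.null(best)) return(fit0)

  p <- best$res$par
  fit <- fit0
  fit$pec50 <- p[["pec50"]]
  fit$top <- p[["top"]]
  fit$hill_n <- p[["hill_n"]]
  fit$basal <- if (fixed_basal) fix_basal else p[["basal"]]
  fit$rss <- best$rss
  fit$converged <- best$res$info %in% 1:4
  fit$extrapolated <-
    fit$pec50 < (-max(logc) - 1) || fit$pec50 > (-min(logc) + 1)

  # SEs from the local Jacobian; may be NA near a singular fit.
  fit$se[] <- NA_real_
  dof <- length(resp) - length(p)
  if (dof > 0) {
    cv <- tryCatch(chol2inv(chol(t(best$res$jac) %*% best$res$jac)) *
                     best$rss / dof, error = function(e) NULL)
    if (!is.null(cv)) fit$se[names(p)] <- sqrt(pmax(diag(cv), 0))
  }
  fit
}

#' Predict responses from a fitted Hill curve
#'
#' @param fit a \code{hill_fit} from \code{\link{fit_hill}}
#' @param conc concentrations in molar
#' @return numeric vector of predicted responses
#' @export
predict_curve <- function(fit, conc) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) stop("cannot predict from an unconverged fit")
  hill_response(conc, fit$pec50, fit$top, fit$hill_n, fit$basal)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Variable-slope Hill fit\n")
  if (!isTRUE(x$converged)) {
    cat("  (not converged)\n")
  }
  cat(sprintf("  pEC50 = %.3f (SE %.3f)\n", x$pec50, x$se[["pec50"]]))
  cat(sprintf("  top   = %.3f (SE %.3f)\n", x$top, x$se[["top"]]))
  cat(sprintf("  hill  = %.3f   basal = %.3f   RSS = %.3g\n",
              x$hill_n, x$basal, x$rss))
  if (isTRUE(x$extrapolated)) {
    cat("  note: pEC50 lies > 1 log unit outside the assayed window\n")
  }
  invisible(x)
}
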