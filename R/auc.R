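#' Area under a fitted concentration-response curve
#'
#' Integrates the baseline-subtracted fitted sigmoid over a
#' log10-concentration window (composite trapezoid on a dense grid).
#' Because the curve, not the raw points, is integrated, the AUC reflects
#' potency, efficacy and the Hill slope together.
#'
#' @param fit a converged \code{hill_fit}
#' @param window numeric(2) log10-molar integration window; typically
#'   the assayed range, identical across pathways so it cancels in ratios
#' @param n_grid number of grid points (>= 1000)
#' @return AUC in response x log10-M units; \code{NA} for an unconverged
#'   fit
#' @export
compute_auc <- function(fit, window = NULL, n_grid = 2001) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) return(NA_real_)
  if (is.null(window)) window <- fit$logc_range
  stopifnot(length(window) == 2, window[2] > window[1], n_grid >= 1000)
  x <- seq(window[1], window[2], length.out = n_grid)
  y <- hill_response(10^x, fit$pec50, fit$top, fit$hill_n, 0)
  pracma::trapz(x, y)
}

#' AUC-based coupling profile normalized to a reference agonist
#'
#' For each agonist, forms the matrix of pairwise AUC ratios across
#' pathways, then divides it element-wise by the reference agonist's
#' matrix. The reference normalization cancels assay-scale differences
#' between biosensors, so the reference agonist's normalized matrix is
#' exactly 1 everywhere; values > 1 mean preferential coupling of the row
#' pathway over the column pathway relative to the reference.
#'
#' @param aucs data.frame with columns \code{agonist}, \code{pathway},
#'   \code{auc}
#' @param reference reference agonist label (needs an AUC in every
#'   pathway)
#' @return an \code{auc_coupling_profile}: list with \code{auc} (the
#'   input), \code{ratios} (per-agonist pathway x pathway matrices) and
#'   \code{normalized} (ratios divided by the reference's)
#' @export
coupling_ratios <- function(aucs, reference) {
  stopifnot(is.data.frame(aucs),
            all(c("agonist", "pathway", "auc") %in% names(aucs)))
  pathways <- sort(unique(aucs$pathway))
  agonists <- unique(aucs$agonist)
  if (!reference %in% agonists) stop("reference agonist missing")

  get_auc <- function(ag) {
    v <- stats::setNames(rep(NA_real_, length(pathways)), pathways)
    rows <- aucs$agonist == ag
    v[aucs$pathway[rows]] <- aucs$auc[rows]
    v
  }
  ref_auc <- get_auc(reference)
  if (anyNA(ref_auc)) {
    stop("reference agonist lacks an AUC for pathway(s): ",
         paste(pathways[is.na(ref_auc)], collapse = ", "))
  }
  if (any(ref_auc == 0)) {
    stop("reference AUC is zero for pathway(s): ",
         paste(pathways[ref_auc == 0], collapse = ", "))
  }
  ratio_matrix <- function(v) outer(v, v, "/")
  ref_mat <- ratio_matrix(ref_auc)
  ratios <- lapply(stats::setNames(agonists, agonists),
                   function(ag) ratio_matrix(get_auc(ag)))
  normalized <- lapply(ratios, function(m) m / ref_mat)
  structure(list(auc = aucs, pathways = pathways, reference = reference,
                 ratios = ratios, normalized = normalized),
            class = "auc_coupling_profile")
}

#' @export
print.auc_coupling_profile <- function(x, ...) {
  cat(sprintf("AUC coupling profile (%d agonists x %d pathways), reference '%s'\n",
              length(x$ratios), length(x$pathways), x$reference))
  for (ag in names(x$normalized)) {
    cat("\n ", ag, "(normalized ratios):\n")
    print(round(x$normalized[[ag]], 3))
  }
  invisible(x)
}

#' Full AUC coupling-ratio pipeline from raw data
#'
#' Fits every (agonist, pathway) curve, integrates each over the shared
#' assayed window, and normalizes pairwise ratios to the reference.
#'
#' @param data long-format concentration-response data.frame
#' @param reference reference agonist label
#' @param window optional log10-M window (default: full assayed range)
#' @return an \code{auc_coupling_profile}
#' @export
auc_coupling_pipeline <- function(data, reference, window = NULL) {
  validate_crc_data(data)
  if (is.null(window)) window <- range(log10(data$conc_M))
  fits <- fit_hill_all(data)
  keys <- strsplit(names(fits), "|", fixed = TRUE)
  aucs <- data.frame(
    agonist = vapply(keys, `[`, "", 1),
    pathway = vapply(keys, `[`, "", 2),
    auc = vapply(fits, compute_auc, numeric(1), window = window)
  )
  coupling_ratios(aucs, reference)
}
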