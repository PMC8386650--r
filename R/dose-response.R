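#' Validate a long-format concentration-response dataset
#'
#' Datasets are plain data.frames with one row per measured well:
#' columns \code{agonist}, \code{pathway}, \code{conc_M} (molar, > 0),
#' \code{replicate} and \code{response}.
#'
#' @param data data.frame to check
#' @return the data, invisibly, after validation
#' @export
validate_crc_data <- function(data) {
  req <- c("agonist", "pathway", "conc_M", "replicate", "response")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(data$conc_M <= 0)) stop("conc_M must be strictly positive")
  invisible(data)
}

#' Subtract per-curve baseline responses
#'
#' For each (agonist, pathway) curve the baseline is subtracted from every
#' response. When no \code{baseline} column is present, the baseline
#' defaults to the mean response at the lowest assayed concentration of
#' that curve. Idempotent after the first application (the subtracted
#' curve's own lowest-concentration mean is ~0).
#'
#' @param data concentration-response data.frame
#' @return data.frame with baseline-corrected responses (any
#'   \code{baseline} column consumed and dropped)
#' @export
subtract_baseline <- function(data) {
  validate_crc_data(data)
  key <- interaction(data$agonist, data$pathway, drop = TRUE)
  if ("baseline" %in% names(data)) {
    data$response <- data$response - data$baseline
    data$baseline <- NULL
    return(data)
  }
  for (k in levels(key)) {
    idx <- key == k
    low <- min(data$conc_M[idx])
    b <- mean(data$response[idx & data$conc_M == low])
    data$response[idx] <- data$response[idx] - b
  }
  data
}

#' Normalize responses to a reference condition
#'
#' Divides every response by the mean response of a reference condition
#' (e.g. the maximal response to 1 uM dopamine). When a \code{batch}
#' column is present, normalization is per batch.
#'
#' @param data concentration-response data.frame
#' @param ref_agonist reference agonist label
#' @param ref_conc_M reference concentration in molar; when NULL, the
#'   reference agonist's highest assayed concentration is used
#' @return data.frame with normalized responses
#' @export
normalize_to_reference <- function(data, ref_agonist, ref_conc_M = NULL) {
  validate_crc_data(data)
  norm_one <- function(d) {
    ref <- d$agonist == ref_agonist
    if (!any(ref)) stop("reference agonist '", ref_agonist, "' not in data")
    cc <- if (is.null(ref_conc_M)) max(d$conc_M[ref]) else ref_conc_M
    sel <- ref & abs(log10(d$conc_M) - log10(cc)) < 1e-9
    if (!any(sel)) stop("reference concentration not found in data")
    m <- mean(d$response[sel])
    if (m <= 0) stop("reference mean response is not positive")
    d$response <- d$response / m
    d
  }
  if ("batch" %in% names(data)) {
    parts <- split(data, data$batch)
    data <- do.call(rbind, lapply(parts, norm_one))
    rownames(data) <- NULL
    data
  } else {
    norm_one(data)
  }
}

#' Fit Hill curves for every (agonist, pathway) combination
#'
#' Convenience wrapper around \code{\link{fit_hill}} for long-format data.
#'
#' @param data concentration-response data.frame
#' @param fix_basal optional fixed basal passed to \code{fit_hill}
#' @return named list of \code{hill_fit} objects, names
#'   \code{"agonist|pathway"}
#' @export
fit_hill_all <- function(data, fix_basal = NULL) {
  validate_crc_data(data)
  key <- interaction(data$agonist, data$pathway, drop = TRUE, sep = "|")
  lapply(split(data, key), fit_hill, fix_basal = fix_basal)
}

#' Read / write long-format concentration-response CSV
#'
#' UTF-8, '.' decimal, columns agonist, pathway, conc_M, replicate,
#' response (extra columns such as batch or baseline are preserved).
#'
#' @param path file path
#' @return data.frame (for the reader)
#' @export
read_crc_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_crc_data(d)
  d
}

#' @rdname read_crc_csv
#' @param data dataset to write
#' @export
write_crc_csv <- function(data, path) {
  validate_crc_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
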