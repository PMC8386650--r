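#' Direct polar contact test for one frame
#'
#' A ligand-atom/residue pair is in direct contact when the Euclidean
#' distance between the two atoms is at or below the cutoff (closed
#' interval: distance == cutoff counts). The default 3.5 A is a standard
#' heavy-atom donor-acceptor criterion.
#'
#' @param frame data.frame of one frame's coordinates: columns
#'   \code{atom_id}, \code{x}, \code{y}, \code{z} (A)
#' @param pairs data.frame with columns \code{ligand_atom},
#'   \code{residue}
#' @param cutoff contact cutoff, A (> 0)
#' @return logical vector, one per pair
#' @export
direct_contact <- function(frame, pairs, cutoff = 3.5) {
  stopifnot(cutoff > 0, all(c("atom_id", "x", "y", "z") %in% names(frame)))
  coords <- function(id) {
    i <- match(id, frame$atom_id)
    if (anyNA(i)) {
      stop("atom(s) not found in frame: ",
           paste(id[is.na(i)], collapse = ", "))
    }
    m <- as.matrix(frame[i, c("x", "y", "z")])
    if (!all(is.finite(m))) stop("non-finite coordinates")
    m
  }
  a <- coords(pairs$ligand_atom)
  b <- coords(pairs$residue)
  unname(sqrt(rowSums((a - b)^2)) <= cutoff)
}

#' Water-mediated contact test for one frame
#'
#' TRUE when at least one water oxygen lies within the cutoff of both
#' partners (a bridging water).
#'
#' @param frame one frame's coordinates (must include the pair atoms)
#' @param pairs data.frame with columns \code{ligand_atom}, \code{residue}
#' @param waters data.frame of water-oxygen coordinates: columns
#'   \code{x}, \code{y}, \code{z}
#' @param cutoff contact cutoff, A
#' @return logical vector, one per pair
#' @export
water_mediated_contact <- function(frame, pairs, waters, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  if (is.null(waters) || nrow(waters) == 0) {
    return(rep(FALSE, nrow(pairs)))
  }
  w <- as.matrix(waters[, c("x", "y", "z")])
  vapply(seq_len(nrow(pairs)), function(i) {
    p <- direct_contact_point(frame, pairs$ligand_atom[i])
    q <- direct_contact_point(frame, pairs$residue[i])
    dw_p <- sqrt(colSums((t(w) - p)^2))
    dw_q <- sqrt(colSums((t(w) - q)^2))
    any(dw_p <= cutoff & dw_q <= cutoff)
  }, logical(1))
}

direct_contact_point <- function(frame, id) {
  i <- match(id, frame$atom_id)
  if (is.na(i)) stop("atom not found in frame: ", id)
  as.numeric(frame[i, c("x", "y", "z")])
}

#' Contact frequencies across a trajectory of frames
#'
#' For each pair, the fraction of frames in which the pair is in contact
#' (direct, or direct-or-water-mediated when \code{include_water} is
#' TRUE; a frame counts at most once per pair, so direct and mediated
#' contacts are never double counted).
#'
#' @param frames long data.frame of coordinates with a \code{frame}
#'   column plus \code{atom_id}, \code{x}, \code{y}, \code{z}; water
#'   oxygens carry \code{role == "water"} when present
#' @param pairs data.frame with columns \code{ligand_atom}, \code{residue}
#' @param cutoff contact cutoff, A
#' @param include_water also count water-bridged contacts
#' @return a \code{contact_frequency_map}: data.frame pair columns plus
#'   \code{frequency}, \code{n_direct}, \code{n_mediated} (frames with a
#'   water bridge but no direct contact) and attribute \code{n_frames}
#' @export
contact_frequencies <- function(frames, pairs, cutoff = 3.5,
                                include_water = FALSE) {
  stopifnot(is.data.frame(frames), "frame" %in% names(frames))
  by_frame <- split(frames, frames$frame)
  ids <- names(by_frame)
  if (length(ids) == 0) stop("no frames supplied")

  n_direct <- integer(nrow(pairs))
  n_mediated <- integer(nrow(pairs))
  n_any <- integer(nrow(pairs))
  for (fid in ids) {
    fr <- by_frame[[fid]]
    wat <- if ("role" %in% names(fr)) fr[fr$role == "water", ] else fr[0, ]
    core <- if ("role" %in% names(fr)) fr[fr$role != "water", ] else fr
    d <- direct_contact(core, pairs, cutoff)
    m <- rep(FALSE, nrow(pairs))
    if (include_water && nrow(wat) > 0) {
      m <- water_mediated_contact(core, pairs, wat, cutoff) & !d
    }
    n_direct <- n_direct + d
    n_mediated <- n_mediated + m
    n_any <- n_any + (d | m)
  }
  out <- data.frame(pairs, frequency = n_any / length(ids),
                    n_direct = n_direct, n_mediated = n_mediated)
  attr(out, "n_frames") <- length(ids)
  class(out) <- c("contact_frequency_map", "data.frame")
  out
}

#' Export a contact-frequency matrix (ligand atoms x residues) as CSV
#'
#' @param cfm a \code{contact_frequency_map}
#' @param path file path
#' @export
write_contact_matrix_csv <- function(cfm, path) {
  stopifnot(inherits(cfm, "contact_frequency_map"))
  m <- stats::xtabs(frequency ~ ligand_atom + residue, data = cfm)
  utils::write.csv(as.data.frame.matrix(m), path, quote = FALSE)
  invisible(path)
}
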