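#' Reconstruct a free-energy profile from deposited hills
#'
#' Sums the deposited Gaussians into the bias potential
#' \deqn{V(s) = \sum_k h_k e^{-(s - c_k)^2 / 2\sigma_k^2}}
#' and applies the well-tempered estimator
#' \eqn{F(s) = -\gamma/(\gamma - 1)\, V(s)}, shifted so the global
#' minimum is zero. Hill order does not matter: the bias is a plain sum.
#'
#' @param hills a \code{\link{hills_record}}
#' @param grid CV grid, A
#' @return a \code{free_energy_profile} data.frame with columns
#'   \code{cv}, \code{free_energy} (kcal/mol; min = 0)
#' @export
reconstruct_fes <- function(hills, grid) {
  stopifnot(inherits(hills, "hills_record"))
  if (nrow(hills) == 0) stop("no hills to reconstruct from")
  gamma_f <- attr(hills, "bias_factor")
  # grid x hills Gaussian sum, blocked to bound memory on long records
  v <- numeric(length(grid))
  block <- 20000L
  for (i0 in seq(1L, nrow(hills), by = block)) {
    i1 <- min(i0 + block - 1L, nrow(hills))
    d2 <- outer(grid, hills$center[i0:i1], "-")^2
    v <- v + as.vector(
      exp(-sweep(d2, 2, 2 * hills$sigma[i0:i1]^2, "/")) %*%
        hills$height[i0:i1])
  }
  f <- -gamma_f / (gamma_f - 1) * v
  f <- f - min(f)
  structure(data.frame(cv = grid, free_energy = f),
            class = c("free_energy_profile", "data.frame"))
}

#' Free-energy convergence series
#'
#' Recomputes the profile from the first k * block deposited Gaussians
#' (in global deposition-time order) for k = 1, 2, ...; the final element
#' uses all hills. Stabilization of successive profiles indicates a
#' converged landscape.
#'
#' @param hills a \code{hills_record}
#' @param grid CV grid
#' @param block number of Gaussians per increment (>= 1)
#' @return list of \code{free_energy_profile}s
#' @export
convergence_series <- function(hills, grid, block = 20000) {
  stopifnot(inherits(hills, "hills_record"), block >= 1)
  ord <- order(hills$time)
  n <- nrow(hills)
  ks <- seq_len(max(1, floor(n / block)))
  ends <- unique(c(pmin(ks * block, n), n))
  lapply(ends, function(e) {
    sub <- hills[ord[seq_len(e)], ]
    attr(sub, "bias_factor") <- attr(hills, "bias_factor")
    class(sub) <- class(hills)
    reconstruct_fes(sub, grid)
  })
}

#' Root-mean-square difference between two profiles on a shared grid
#'
#' Profiles are re-anchored to min = 0 before comparison, optionally over
#' a restricted CV region.
#'
#' @param fes1,fes2 \code{free_energy_profile}s on the same grid
#' @param region optional numeric(2) CV interval to compare over
#' @return RMS difference, kcal/mol
#' @export
fes_rms_difference <- function(fes1, fes2, region = NULL) {
  stopifnot(nrow(fes1) == nrow(fes2),
            all(abs(fes1$cv - fes2$cv) < 1e-9))
  sel <- rep(TRUE, nrow(fes1))
  if (!is.null(region)) sel <- fes1$cv >= region[1] & fes1$cv <= region[2]
  a <- fes1$free_energy[sel] - min(fes1$free_energy[sel])
  b <- fes2$free_energy[sel] - min(fes2$free_energy[sel])
  sqrt(mean((a - b)^2))
}

#' Locate free-energy wells and the barriers between them
#'
#' Wells are local minima whose prominence (the smaller of the two
#' ridges separating them from deeper territory or the profile edge)
#' exceeds a threshold. Barriers are reported for each ordered well pair
#' as the highest point on the path between them minus the first well's
#' free energy.
#'
#' @param fes a \code{free_energy_profile}
#' @param prominence minimum well prominence, kcal/mol
#' @return list with \code{wells} (data.frame cv, free_energy,
#'   prominence) and \code{barriers} (data.frame from, to,
#'   barrier_kcal_mol); empty data.frames when no well qualifies
#' @export
find_wells_and_barriers <- function(fes, prominence = 0.5) {
  f <- fes$free_energy
  x <- fes$cv
  n <- length(f)
  # local minima including the profile edges (pad with +Inf);
  # plateau-safe via the loose/strict comparison pair
  fp <- c(Inf, f, Inf)
  is_min <- which(vapply(seq_len(n), function(i) {
    fp[i + 1] <= fp[i] && fp[i + 1] < fp[i + 2]
  }, logical(1)))

  prom <- vapply(is_min, function(i) {
    left <- if (i > 1) max(f[1:(i - 1)]) else Inf
    right <- if (i < n) max(f[(i + 1):n]) else Inf
    # ridge only counts up to the next deeper point on that side
    deeper_l <- which(f[seq_len(i - 1)] < f[i])
    if (length(deeper_l)) left <- max(f[max(deeper_l):(i - 1)])
    deeper_r <- which(f[(i + 1):n] < f[i]) + i
    if (length(deeper_r)) right <- max(f[(i + 1):min(deeper_r)])
    min(left, right) - f[i]
  }, numeric(1))

  keep <- prom >= prominence
  wells <- data.frame(cv = x[is_min][keep], free_energy = f[is_min][keep],
                      prominence = prom[keep])
  wells <- wells[order(wells$cv), ]
  rownames(wells) <- NULL

  barriers <- data.frame(from = numeric(0), to = numeric(0),
                         barrier_kcal_mol = numeric(0))
  if (nrow(wells) >= 2) {
    idx <- match(wells$cv, x)
    combs <- expand.grid(i = seq_len(nrow(wells)), j = seq_len(nrow(wells)))
    combs <- combs[combs$i != combs$j, ]
    barriers <- do.call(rbind, lapply(seq_len(nrow(combs)), function(r) {
      i <- combs$i[r]; j <- combs$j[r]
      path <- idx[i]:idx[j]
      data.frame(from = wells$cv[i], to = wells$cv[j],
                 barrier_kcal_mol = max(f[path]) - wells$free_energy[i])
    }))
    rownames(barriers) <- NULL
  }
  list(wells = wells, barriers = barriers)
}

#' Write / read a free-energy profile as two-column CSV
#'
#' Columns \code{cv_A}, \code{F_kcal_mol}.
#'
#' @param fes profile to write
#' @param path file path
#' @export
write_fes_csv <- function(fes, path) {
  utils::write.csv(
    data.frame(cv_A = fes$cv, F_kcal_mol = fes$free_energy),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fes_csv
#' @export
read_fes_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(data.frame(cv = d$cv_A, free_energy = d$F_kcal_mol),
            class = c("free_energy_profile", "data.frame"))
}
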