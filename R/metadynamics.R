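KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

#' Metadynamics run parameters
#'
#' Defaults follow the production settings used throughout: Gaussian
#' hills of 0.1 kcal/mol with a 0.1 A spread deposited every 4 ps, a
#' well-tempered bias factor of 10, a one-sided harmonic wall with
#' kappa = 100 kcal/mol/A^2 acting beyond 12 A, 6 walkers contributing
#' to a shared bias refreshed every 20 ps, at 300 K.
#'
#' @param hill_height w0, kcal/mol
#' @param hill_sigma Gaussian spread, A
#' @param deposition_stride time between hills per walker, ps
#' @param bias_factor well-tempered gamma (> 1)
#' @param wall_kappa wall force constant, kcal/mol/A^2
#' @param wall_position upper wall onset, A
#' @param wall_lower lower wall onset, A (confines the toy CV near 0)
#' @param n_walkers number of walkers sharing the bias
#' @param walker_sync_stride shared-bias refresh interval, ps
#' @param temperature K
#' @param timestep integration step, ps
#' @param friction Langevin friction, kcal/mol * ps / A^2 (sets the
#'   diffusion constant D = kT / friction)
#' @return a \code{metad_params} list
#' @export
metad_params <- function(hill_height = 0.1, hill_sigma = 0.1,
                         deposition_stride = 4, bias_factor = 10,
                         wall_kappa = 100, wall_position = 12,
                         wall_lower = 0, n_walkers = 6,
                         walker_sync_stride = 20, temperature = 300,
                         timestep = 0.002, friction = 1) {
  if (bias_factor <= 1) stop("well-tempered bias factor must exceed 1")
  stopifnot(deposition_stride > 0, walker_sync_stride > 0, timestep > 0,
            temperature > 0, friction > 0, hill_height >= 0,
            hill_sigma > 0, n_walkers >= 1)
  structure(list(hill_height = hill_height, hill_sigma = hill_sigma,
                 deposition_stride = deposition_stride,
                 bias_factor = bias_factor, wall_kappa = wall_kappa,
                 wall_position = wall_position, wall_lower = wall_lower,
                 n_walkers = n_walkers,
                 walker_sync_stride = walker_sync_stride,
                 temperature = temperature, timestep = timestep,
                 friction = friction),
            class = "metad_params")
}

#' Run well-tempered multiple-walker metadynamics on a toy potential
#'
#' Overdamped Langevin dynamics (Euler-Maruyama) on
#' \code{U(s) + V_bias(s) + V_wall(s)}. Every deposition stride each
#' walker drops a Gaussian of height
#' \code{w0 exp(-V_bias(s) / ((gamma - 1) kB T))}; walkers keep recent
#' hills in a private buffer merged into the shared bias every
#' \code{walker_sync_stride}. The wall is one-sided harmonic,
#' \code{kappa (s - s_wall)^2} beyond its onset.
#'
#' Before running, the timestep is checked against the stiffest curvature
#' of the tabulated potential (stable when
#' \code{dt < friction / max |U''|}); a too-large step is an error, not a
#' warning, because an unstable integration produces silent garbage.
#'
#' @param potential a \code{\link{toy_potential}}
#' @param params a \code{\link{metad_params}}
#' @param n_steps integration steps per walker
#' @param seed RNG seed
#' @param cv_range numeric(2) CV support for the bias/force grid; default
#'   covers \code{[wall_lower - 1, wall_position + 2]}
#' @param record_stride trajectory sampling interval in steps
#' @return list with \code{trajectory} (data.frame time_ps, walker, cv),
#'   \code{hills} (a \code{hills_record}), and \code{params}
#' @export
run_langevin_metadynamics <- function(potential, params = metad_params(),
                                      n_steps, seed = 1, cv_range = NULL,
                                      record_stride = 100) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(params, "metad_params"), n_steps >= 1)
  if (is.null(cv_range)) {
    cv_range <- c(params$wall_lower - 1, params$wall_position + 2)
  }
  h <- params$hill_sigma / 4  # grid resolution well below the hill width
  grid <- seq(cv_range[1], cv_range[2], by = h)
  u <- potential$u(grid)

  # timestep stability: dt must resolve the stiffest local curvature
  upp <- diff(diff(u)) / h^2
  k_max <- max(abs(upp), 2 * params$wall_kappa)
  if (params$timestep >= params$friction / k_max) {
    stop(sprintf(
      "timestep %.3g ps unstable for stiffness %.3g kcal/mol/A^2 (need < %.3g)",
      params$timestep, k_max, params$friction / k_max))
  }

  kT <- KB_KCAL * params$temperature
  dep_steps <- max(1L, round(params$deposition_stride / params$timestep))
  sync_steps <- max(1L, round(params$walker_sync_stride / params$timestep))

  res <- withr::with_seed(seed, {
    s0 <- stats::runif(params$n_walkers, cv_range[1] + 0.5,
                       min(cv_range[2], params$wall_position) - 0.5)
    run_metad_cpp(s0, u, grid[1], h,
                  params$timestep, as.integer(n_steps), params$friction,
                  kT, params$hill_height, params$hill_sigma,
                  params$bias_factor, as.integer(dep_steps),
                  as.integer(sync_steps), params$wall_kappa,
                  params$wall_position, params$wall_lower,
                  as.integer(record_stride))
  })

  nw <- params$n_walkers
  traj <- data.frame(
    time_ps = rep(res$traj_time, nw),
    walker = rep(seq_len(nw), each = length(res$traj_time)),
    cv = as.vector(res$traj)
  )
  hills <- hills_record(
    time = res$hill_time, center = res$hill_center,
    sigma = rep(params$hill_sigma, length(res$hill_time)),
    height = res$hill_height, walker = res$hill_walker,
    bias_factor = params$bias_factor
  )
  list(trajectory = traj, hills = hills, params = params)
}

#' Deposited-Gaussian (hills) record
#'
#' Ordered table of deposited Gaussians: time (ps), center (A), sigma
#' (A), deposited height (kcal/mol) and walker id, with the well-tempered
#' bias factor carried as an attribute.
#'
#' @param time,center,sigma,height,walker parallel vectors
#' @param bias_factor well-tempered gamma used during deposition
#' @param cv_label collective-variable name (for the hills file header)
#' @return a \code{hills_record} data.frame
#' @export
hills_record <- function(time, center, sigma, height, walker = 1,
                         bias_factor = 10, cv_label = "cv1") {
  d <- data.frame(time = time, center = center, sigma = sigma,
                  height = height, walker = walker)
  for (w in unique(d$walker)) {
    if (is.unsorted(d$time[d$walker == w])) {
      stop("hill times must be non-decreasing within each walker")
    }
  }
  if (any(d$height <= 0)) stop("deposited heights must be positive")
  attr(d, "bias_factor") <- bias_factor
  attr(d, "cv_label") <- cv_label
  class(d) <- c("hills_record", "data.frame")
  d
}

#' Read / write hills files
#'
#' Whitespace-separated columns time, center, sigma, height, biasf
#' (walker id appended as a sixth column when present), with a
#' \code{#! FIELDS} header naming the collective variable, for
#' interoperability with the common hills dialect.
#'
#' @param path file path
#' @return a \code{hills_record} (reader)
#' @export
read_hills <- function(path) {
  first <- readLines(path, n = 1)
  cv_label <- "cv1"
  if (startsWith(first, "#!")) {
    flds <- strsplit(sub("^#!\\s*FIELDS\\s*", "", first), "\\s+")[[1]]
    if (length(flds) >= 2) cv_label <- flds[2]
  }
  d <- utils::read.table(path, comment.char = "#")
  if (ncol(d) < 5) stop("hills file needs >= 5 columns")
  names(d)[1:5] <- c("time", "center", "sigma", "height", "biasf")
  walker <- if (ncol(d) >= 6) d[[6]] else 1
  hills_record(d$time, d$center, d$sigma, d$height, walker,
               bias_factor = d$biasf[1], cv_label = cv_label)
}

#' @rdname read_hills
#' @param hills a \code{hills_record} to write
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hills_record"))
  cv <- attr(hills, "cv_label")
  hdr <- sprintf("#! FIELDS time %s sigma_%s height biasf walker", cv, cv)
  body <- sprintf("%.6g %.8g %.6g %.8g %.6g %d",
                  hills$time, hills$center, hills$sigma, hills$height,
                  attr(hills, "bias_factor"), hills$walker)
  writeLines(c(hdr, body), path)
  invisible(path)
}
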