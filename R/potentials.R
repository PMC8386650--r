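#' Analytic one-dimensional toy potentials
#'
#' Stand-ins for the binding-distance free-energy landscape: the
#' collective variable s is a distance in Angstrom and energies are in
#' kcal/mol. Three forms are supported:
#' \describe{
#'   \item{harmonic}{\code{U = 0.5 k (s - center)^2}}
#'   \item{double_well}{quartic with minima at \code{wells[1]},
#'     \code{wells[2]} (both at U = 0) and a barrier of height
#'     \code{barrier} at the midpoint; an optional \code{tilt} (kcal/mol)
#'     raises the second well linearly to break the symmetry}
#'   \item{tabulated}{linear interpolation of user-supplied (s, U)}
#' }
#'
#' @param form one of "harmonic", "double_well", "tabulated"
#' @param k,center harmonic stiffness (kcal/mol/A^2) and minimum (A)
#' @param wells numeric(2) well positions, A
#' @param barrier barrier height at the midpoint, kcal/mol (>= 0)
#' @param tilt linear tilt applied across the two wells, kcal/mol
#' @param s,u tabulated grid and energies
#' @return a \code{toy_potential}: list with \code{u(s)} and the stated
#'   parameters
#' @export
toy_potential <- function(form = c("double_well", "harmonic", "tabulated"),
                          k = 1, center = 0,
                          wells = c(2.8, 5.5), barrier = 1.3, tilt = 0,
                          s = NULL, u = NULL) {
  form <- match.arg(form)
  pot <- switch(form,
    harmonic = {
      stopifnot(k > 0)
      list(u = function(x) 0.5 * k * (x - center)^2,
           k = k, center = center)
    },
    double_well = {
      stopifnot(length(wells) == 2, wells[2] > wells[1], barrier >= 0)
      m <- mean(wells)
      w <- diff(wells) / 2
      list(u = function(x) {
        barrier * ((x - m)^2 - w^2)^2 / w^4 +
          tilt * (x - wells[1]) / (2 * w)
      }, wells = wells, barrier = barrier, tilt = tilt)
    },
    tabulated = {
      stopifnot(!is.null(s), !is.null(u), length(s) == length(u),
                !is.unsorted(s, strictly = TRUE))
      list(u = stats::approxfun(s, u, rule = 2), s = s, tab_u = u)
    }
  )
  pot$form <- form
  class(pot) <- "toy_potential"
  pot
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("Toy potential:", x$form, "\n")
  if (x$form == "double_well") {
    cat(sprintf("  wells at %.2f / %.2f A, barrier %.2f kcal/mol",
                x$wells[1], x$wells[2], x$barrier))
    if (x$tilt != 0) cat(sprintf(", tilt %.2f kcal/mol", x$tilt))
    cat("\n")
  }
  invisible(x)
}

#' Boltzmann free-energy oracle for a 1D potential
#'
#' For one-dimensional overdamped Langevin dynamics the free energy along
#' the coordinate equals the potential itself, so \code{U(s) - min U}
#' over the grid is the exact reference profile against which a
#' reconstructed FES can be checked.
#'
#' @param potential a \code{toy_potential}
#' @param grid CV grid, A
#' @return data.frame with columns \code{cv}, \code{free_energy}
#' @export
potential_fes_reference <- function(potential, grid) {
  stopifnot(inherits(potential, "toy_potential"))
  u <- potential$u(grid)
  data.frame(cv = grid, free_energy = u - min(u))
}
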