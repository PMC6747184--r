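#' Analytic toy potentials
#'
#' A `toy_potential` bundles an energy function, its gradient, and the
#' analytic Boltzmann density, so that boosted sampling and reweighting can
#' be validated against a closed form. The "dihedral" component used by the
#' dual-boost path is a designated fraction of the total energy; for 1-D
#' potentials with `dihedral_fraction = 1` the dual boost degenerates to a
#' total-only boost.
#'
#' @name toy_potential
NULL

new_toy_potential <- function(form, params, dim, energy, gradient,
                              dihedral_fraction = 1) {
  stopifnot(is.function(energy), is.function(gradient),
            dihedral_fraction >= 0, dihedral_fraction <= 1)
  structure(
    list(form = form, params = params, dim = dim,
         energy = energy, gradient = gradient,
         dihedral_fraction = dihedral_fraction),
    class = "toy_potential")
}

#' Symmetric quartic double well
#'
#' \eqn{V(x) = h\,[(x/a)^2 - 1]^2}: minima of depth 0 at \eqn{x = \pm a},
#' barrier of height \eqn{h} at \eqn{x = 0}. The analytic PMF is \eqn{V(x)}
#' itself up to an additive constant, which makes the double well the
#' closure test for the boost/reweighting chain.
#'
#' @param barrier_height Barrier height \eqn{h} in kcal mol^-1 (> 0).
#' @param well_separation Half-distance \eqn{a} between the minima in
#'   Angstrom (default 1).
#' @param kT Thermal energy in kcal mol^-1 used by [boltzmann_density()]
#'   and stored for downstream analysis (default 300 K).
#' @param dihedral_fraction Fraction of the energy treated as the
#'   "dihedral" component by the dual-boost path.
#' @return A `toy_potential`.
#' @examples
#' dw <- make_double_well(5)
#' dw$energy(0)    # barrier: 5
#' dw$energy(1)    # well: 0
#' @export
make_double_well <- function(barrier_height, well_separation = 1,
                             kT = KB_KCAL * 300, dihedral_fraction = 1) {
  if (!is.numeric(barrier_height) || length(barrier_height) != 1 ||
      !is.finite(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be a single positive number")
  if (well_separation <= 0) stop("well_separation must be positive")
  h <- barrier_height
  a <- well_separation
  pot <- new_toy_potential(
    form = "double_well",
    params = list(barrier_height = h, well_separation = a, kT = kT),
    dim = 1L,
    energy = function(x) h * ((x / a)^2 - 1)^2,
    gradient = function(x) 4 * h * x * ((x / a)^2 - 1) / a^2,
    dihedral_fraction = dihedral_fraction)
  pot
}

#' Analytic Boltzmann density of a toy potential
#'
#' Normalised \eqn{p(x) \propto \exp(-V(x)/kT)} evaluated by adaptive
#' quadrature on `[lower, upper]`.
#'
#' @param potential A `toy_potential` (1-D).
#' @param kT Thermal energy (defaults to the value stored in the potential).
#' @param lower,upper Integration domain.
#' @return A function `p(x)` returning the normalised density.
#' @export
boltzmann_density <- function(potential, kT = NULL, lower = -Inf, upper = Inf) {
  stopifnot(inherits(potential, "toy_potential"), potential$dim == 1L)
  if (is.null(kT)) kT <- potential$params$kT
  if (is.infinite(lower) || is.infinite(upper)) {
    a <- if (!is.null(potential$params$well_separation))
      potential$params$well_separation else 1
    lower <- -10 * a
    upper <- 10 * a
  }
  un <- function(x) exp(-potential$energy(x) / kT)
  Z <- stats::integrate(un, lower, upper, rel.tol = 1e-10)$value
  function(x) un(x) / Z
}

#' Analytic Boltzmann CDF of a toy potential
#'
#' Used as the reference distribution for Kolmogorov-Smirnov checks of
#' unboosted Langevin sampling.
#'
#' @inheritParams boltzmann_density
#' @param n_grid Quadrature grid size for the cumulative integral.
#' @return A vectorised CDF function suitable for [stats::ks.test()].
#' @export
boltzmann_cdf <- function(potential, kT = NULL, lower = NULL, upper = NULL,
                          n_grid = 4096) {
  stopifnot(inherits(potential, "toy_potential"), potential$dim == 1L)
  if (is.null(kT)) kT <- potential$params$kT
  a <- if (!is.null(potential$params$well_separation))
    potential$params$well_separation else 1
  if (is.null(lower)) lower <- -8 * a
  if (is.null(upper)) upper <- 8 * a
  xg <- seq(lower, upper, length.out = n_grid)
  dens <- exp(-potential$energy(xg) / kT)
  cum <- cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(xg))
  cdf_y <- c(0, cum / cum[length(cum)])
  function(q) {
    out <- stats::approx(xg, cdf_y, xout = q, yleft = 0, yright = 1)$y
    out
  }
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential>", x$form, "dim", x$dim, "\n")
  cat("  params:", paste(names(x$params), unlist(x$params),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Analytic PMF of a toy potential at histogram resolution
#'
#' The binned reference for PMF-recovery checks: the Boltzmann probability
#' of each bin by quadrature, converted to \eqn{-kT \ln(p_i/w_i)}. A binned
#' estimator should be compared against the analytic PMF binned the same
#' way, not against point values, which differ by the within-bin average
#' wherever the potential is steep.
#'
#' @param potential A `toy_potential` (1-D).
#' @param edges Bin edge vector.
#' @param kT Thermal energy (defaults to the potential's stored value).
#' @return PMF per bin in kcal mol^-1, minimum-shifted to zero.
#' @export
analytic_pmf_binned <- function(potential, edges, kT = NULL) {
  stopifnot(inherits(potential, "toy_potential"), potential$dim == 1L)
  if (is.null(kT)) kT <- potential$params$kT
  p <- vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(function(x) exp(-potential$energy(x) / kT),
                     edges[i], edges[i + 1], rel.tol = 1e-10)$value, 0)
  pmf <- -kT * log(p / diff(edges))
  pmf - min(pmf)
}
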