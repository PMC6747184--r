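#' aMD boost parameters from calibration averages
#'
#' Accelerated MD raises the potential below a threshold `E` by
#' \eqn{\Delta V = (E - V)^2 / (\alpha + E - V)}. The thresholds and
#' smoothing constants are set from average potential energies of an
#' unboosted calibration run plus system-size terms: the dihedral threshold
#' grows with the residue count at a per-residue coefficient (typically
#' 4-4.5 kcal mol^-1 per residue, with \eqn{\alpha_{dihed}} one fifth of
#' that term), and the total-potential threshold grows with the atom count
#' at a per-atom coefficient (typically 0.16-0.20 kcal mol^-1 per atom,
#' with \eqn{\alpha_{total}} equal to that term).
#'
#' @param V_avg_dihed Average dihedral energy from the calibration run
#'   (kcal mol^-1).
#' @param V_avg_total Average total potential energy (kcal mol^-1).
#' @param a1,a2 Per-atom ("Total") coefficients, kcal mol^-1 per atom:
#'   `a1` enters `E_total`, `a2` enters `alpha_total`.
#' @param b1,b2 Per-residue ("Dihedral") coefficients, kcal mol^-1 per
#'   residue: `b1` enters `E_dihed`, `b2` enters `alpha_dihed`.
#' @param N_res Number of residues.
#' @param N_atoms Number of atoms in the system.
#' @param mode Boost mode: `"dual"`, `"total"` or `"dihedral"`.
#' @return An `amd_parameters` object with fields `E_dihed`, `alpha_dihed`,
#'   `E_total`, `alpha_total` and the inputs.
#' @examples
#' # 21-residue peptide, dihedral coefficients 4/4:
#' p <- compute_boost_parameters(V_avg_dihed = 100, V_avg_total = -40000,
#'                               a1 = 0.16, a2 = 0.16, b1 = 4, b2 = 4,
#'                               N_res = 21, N_atoms = 14391)
#' p$E_dihed      # 184
#' p$alpha_dihed  # 16.8
#' @export
compute_boost_parameters <- function(V_avg_dihed, V_avg_total,
                                     a1, a2, b1, b2,
                                     N_res, N_atoms,
                                     mode = c("dual", "total", "dihedral")) {
  mode <- match.arg(mode)
  if (N_res <= 0 || N_atoms <= 0) stop("N_res and N_atoms must be positive")
  if (any(c(a1, a2, b1, b2) < 0)) stop("coefficients must be non-negative")
  E_dihed <- V_avg_dihed + b1 * N_res
  alpha_dihed <- b2 * N_res / 5
  E_total <- V_avg_total + a1 * N_atoms
  alpha_total <- a2 * N_atoms
  if ((mode %in% c("dual", "dihedral") && alpha_dihed <= 0) ||
      (mode %in% c("dual", "total") && alpha_total <= 0))
    warning("zero alpha: thresholds equal the calibration averages and the ",
            "parameters cannot drive a boosted run")
  structure(
    list(E_dihed = E_dihed, alpha_dihed = alpha_dihed,
         E_total = E_total, alpha_total = alpha_total,
         V_avg_dihed = V_avg_dihed, V_avg_total = V_avg_total,
         a1 = a1, a2 = a2, b1 = b1, b2 = b2,
         N_res = N_res, N_atoms = N_atoms, mode = mode),
    class = "amd_parameters")
}

#' Direct construction of boost parameters
#'
#' For toy potentials the thresholds are more naturally stated directly
#' than through system-size coefficients.
#'
#' @param E_total,alpha_total Total-potential threshold and smoothing
#'   (kcal mol^-1); `NA` disables the total boost.
#' @param E_dihed,alpha_dihed Dihedral threshold and smoothing; `NA`
#'   disables the dihedral boost.
#' @return An `amd_parameters` object.
#' @export
amd_parameters <- function(E_total = NA, alpha_total = NA,
                           E_dihed = NA, alpha_dihed = NA) {
  total_on <- is.finite(E_total)
  dihed_on <- is.finite(E_dihed)
  if (!total_on && !dihed_on) stop("at least one boost term must be active")
  if (total_on && (!is.finite(alpha_total) || alpha_total <= 0))
    stop("alpha_total must be positive when the total boost is active")
  if (dihed_on && (!is.finite(alpha_dihed) || alpha_dihed <= 0))
    stop("alpha_dihed must be positive when the dihedral boost is active")
  mode <- if (total_on && dihed_on) "dual" else if (total_on) "total" else "dihedral"
  structure(
    list(E_dihed = E_dihed, alpha_dihed = alpha_dihed,
         E_total = E_total, alpha_total = alpha_total, mode = mode),
    class = "amd_parameters")
}

#' @export
print.amd_parameters <- function(x, ...) {
  cat("<amd_parameters> mode:", x$mode, "\n")
  cat(sprintf("  E_dihed = %s  alpha_dihed = %s\n", x$E_dihed, x$alpha_dihed))
  cat(sprintf("  E_total = %s  alpha_total = %s\n", x$E_total, x$alpha_total))
  invisible(x)
}

#' The aMD boost energy
#'
#' \eqn{\Delta V(V) = (E - V)^2/(\alpha + E - V)} for \eqn{V < E}, zero
#' otherwise. Non-negative everywhere, continuous (with continuous first
#' derivative) at \eqn{V = E}, and monotonically decreasing in `V` below
#' the threshold.
#'
#' @param V Potential energy (kcal mol^-1); vectorised.
#' @param E Threshold energy.
#' @param alpha Smoothing parameter (> 0).
#' @return \eqn{\Delta V \ge 0}, same length as `V`.
#' @export
boost_energy <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  u <- E - V
  ifelse(u > 0, u * u / (alpha + u), 0)
}

#' Derivative of the boosted potential with respect to the bare one
#'
#' \eqn{dV^*/dV = \alpha^2/(\alpha + E - V)^2} on \eqn{V < E} and 1 above;
#' multiplies the bare force to give the boosted force.
#'
#' @inheritParams boost_energy
#' @return Scaling factor in (0, 1].
#' @export
boost_force_scale <- function(V, E, alpha) {
  u <- E - V
  ifelse(u > 0, alpha^2 / (alpha + u)^2, 1)
}

#' Langevin configuration
#'
#' @param temperature Temperature in K.
#' @param friction Langevin friction in ps^-1.
#' @param timestep Integration step in ps.
#' @param n_steps Number of steps.
#' @param save_stride Save a frame every this many steps.
#' @param mass Particle mass in g mol^-1.
#' @param x0 Initial coordinate(s).
#' @param seed RNG seed.
#' @return A `langevin_config` list.
#' @export
langevin_config <- function(temperature = 300, friction = 5, timestep = 0.004,
                            n_steps = 1e5, save_stride = 10, mass = 10,
                            x0 = 0, seed = 1) {
  stopifnot(temperature > 0, friction > 0, timestep > 0, n_steps >= 1,
            save_stride >= 1, mass > 0)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride), mass = mass,
                 x0 = x0, seed = as.integer(seed)),
            class = "langevin_config")
}

## Split the potential into the "dihedral" component and the remainder and
## return V_total, V_dihed, dV_total, dV_dihed and the force scale factor
## for the configured boost mode. The dual boost first raises the dihedral
## component, then applies the total boost to the already-raised total.
boosted_state <- function(V, f_dihed, params) {
  V_dihed <- f_dihed * V
  if (is.null(params)) {
    return(list(V = V, V_dihed = V_dihed, dV_total = 0, dV_dihed = 0,
                scale = 1))
  }
  mode <- params$mode
  dV_d <- 0
  scale_d <- 1
  if (mode %in% c("dual", "dihedral")) {
    dV_d <- boost_energy(V_dihed, params$E_dihed, params$alpha_dihed)
    ## d(dV_d)/dx = g'(V_dihed) * f_dihed * V'(x)
    scale_d <- 1 + f_dihed * (boost_force_scale(V_dihed, params$E_dihed,
                                                params$alpha_dihed) - 1)
  }
  V1 <- V + dV_d
  dV_t <- 0
  scale_t <- 1
  if (mode %in% c("dual", "total")) {
    dV_t <- boost_energy(V1, params$E_total, params$alpha_total)
    scale_t <- boost_force_scale(V1, params$E_total, params$alpha_total)
  }
  ## V* = V1 + g(V1); dV*/dx = scale_t * dV1/dx = scale_t * scale_d * V'(x)
  list(V = V, V_dihed = V_dihed, dV_total = dV_t, dV_dihed = dV_d,
       scale = scale_t * scale_d)
}

#' Langevin dynamics on a toy potential, optionally aMD-boosted
#'
#' BAOAB-splitting Langevin integration of a single particle on a
#' `toy_potential`. When `params` is supplied the particle moves on the
#' boosted potential \eqn{V^* = V + \Delta V}, with forces propagated
#' through the boost by the chain rule; the per-frame boost energies are
#' recorded for reweighting. Deterministic under a fixed seed.
#'
#' @param potential A `toy_potential` (1-D).
#' @param config A [langevin_config()].
#' @param params An `amd_parameters` object, or `NULL` for plain Langevin.
#' @return A `langevin_run`: list with `coords` (saved positions),
#'   `energies` (data.frame `time`, `V_total`, `V_dihed`, `dV_total`,
#'   `dV_dihed`), and the inputs.
#' @export
run_langevin <- function(potential, config, params = NULL) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(config, "langevin_config"),
            is.null(params) || inherits(params, "amd_parameters"))
  dt <- config$timestep
  gamma <- config$friction
  m <- config$mass
  kT_ <- KB_KCAL * config$temperature
  f_dihed <- potential$dihedral_fraction
  energy <- potential$energy
  gradient <- potential$gradient

  n <- config$n_steps
  stride <- config$save_stride
  n_save <- n %/% stride
  xs <- numeric(n_save)
  Vs <- numeric(n_save)
  dVt <- numeric(n_save)
  dVd <- numeric(n_save)
  Vd <- numeric(n_save)

  c1 <- exp(-gamma * dt)
  c2 <- sqrt((1 - c1 * c1) * MD_ACCEL * kT_ / m)
  fscale <- MD_ACCEL / m

  set.seed(config$seed)
  x <- config$x0
  v <- sqrt(MD_ACCEL * kT_ / m) * stats::rnorm(1)
  st <- boosted_state(energy(x), f_dihed, params)
  force <- -gradient(x) * st$scale
  xi <- stats::rnorm(n)

  for (i in seq_len(n)) {
    v <- v + 0.5 * dt * force * fscale
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * xi[i]
    x <- x + 0.5 * dt * v
    st <- boosted_state(energy(x), f_dihed, params)
    force <- -gradient(x) * st$scale
    if (!is.finite(x) || !is.finite(v))
      stop("numeric overflow at step ", i,
           ": reduce the time step or check the potential stiffness")
    v <- v + 0.5 * dt * force * fscale
    if (i %% stride == 0) {
      j <- i %/% stride
      xs[j] <- x
      Vs[j] <- st$V
      Vd[j] <- st$V_dihed
      dVt[j] <- st$dV_total
      dVd[j] <- st$dV_dihed
    }
  }

  structure(
    list(coords = xs,
         energies = data.frame(time = seq_len(n_save) * stride * dt,
                               V_total = Vs, V_dihed = Vd,
                               dV_total = dVt, dV_dihed = dVd),
         potential = potential, config = config, params = params),
    class = "langevin_run")
}

#' @export
print.langevin_run <- function(x, ...) {
  cat("<langevin_run>", length(x$coords), "saved frames,",
      if (is.null(x$params)) "unboosted" else paste0("boost mode ", x$params$mode),
      "\n")
  cat(sprintf("  mean boost %.3f kcal/mol\n",
              mean(x$energies$dV_total + x$energies$dV_dihed)))
  invisible(x)
}

#' Total applied boost per frame
#'
#' @param run A `langevin_run` or a `BoostedEnergySeries` data frame with
#'   `dV_total` and `dV_dihed` columns.
#' @return Numeric vector \eqn{\Delta V_{total} + \Delta V_{dihed}} per frame.
#' @export
total_boost <- function(run) {
  e <- if (inherits(run, "langevin_run")) run$energies else run
  e$dV_total + e$dV_dihed
}

#' Kolmogorov-Smirnov check of Langevin sampling against Boltzmann
#'
#' Subsamples the coordinate series at an estimated decorrelation stride
#' (first autocorrelation crossing below `acf_cut`, estimated on a
#' decimated series, times `safety`) and applies a two-sided KS test
#' against the analytic Boltzmann CDF of the potential. For barriers many
#' kT high the effective sample count is set by the number of well visits,
#' so the test has low power there - which is precisely the sampling
#' problem boosting addresses.
#'
#' @param run A `langevin_run` (unboosted).
#' @param potential Toy potential (default: the run's).
#' @param acf_cut Autocorrelation threshold defining the stride.
#' @param safety Multiplier on the estimated stride (default 2).
#' @return The `htest` from [stats::ks.test()], with attributes `n_eff`
#'   and `stride`.
#' @export
boltzmann_ks_test <- function(run, potential = NULL, acf_cut = 0.05,
                              safety = 2) {
  stopifnot(inherits(run, "langevin_run"))
  if (is.null(potential)) potential <- run$potential
  x <- run$coords
  n <- length(x)
  dec <- max(1L, n %/% 10000L)
  xd <- x[seq(1L, n, by = dec)]
  ac <- stats::acf(xd, lag.max = min(length(xd) - 1, 2000), plot = FALSE)$acf
  lag0 <- which(ac < acf_cut)[1]
  if (is.na(lag0)) lag0 <- length(ac)
  stride <- max(1L, as.integer(round(safety * lag0 * dec)))
  xs <- x[seq(1L, n, by = stride)]
  kT_ <- KB_KCAL * run$config$temperature
  ht <- stats::ks.test(xs, boltzmann_cdf(potential, kT_))
  attr(ht, "n_eff") <- length(xs)
  attr(ht, "stride") <- stride
  ht
}
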