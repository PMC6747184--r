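#' Specification of the synthetic membrane/pore/water system
#'
#' A statistical surrogate for a peptide-pore-bearing bilayer patch:
#' pseudo-lipids are rigid all-trans zigzag chains plus a head bead, each
#' chain drawn per frame from an axially symmetric tilt distribution
#' calibrated so the reconstructed C-H order parameter |S_CD| matches
#' `target_scd`; waters perform an exact Brownian walk with diffusion
#' coefficient `D_water` (coordinates stored unwrapped); the pore is a
#' static cylinder of wall beads. Chemistry is out of scope - the point is
#' known ground truth for every estimator.
#'
#' @param n_lipids_leaflet Lipids per leaflet (two leaflets).
#' @param chain_length Chain carbons per lipid.
#' @param target_scd Target |S_CD| magnitude in `[0, 0.5)`; the underlying
#'   signed value is negative, as for real acyl chains. 0 selects
#'   isotropic tilts.
#' @param n_water Number of water beads (oxygens).
#' @param D_water True water diffusion coefficient, Angstrom^2 ps^-1.
#' @param pore_radius Pore cylinder radius (Angstrom); 0 disables the pore.
#' @param pore_length Pore length along z (Angstrom).
#' @param pore_vdw Van der Waals radius of the wall beads (Angstrom).
#' @param box Length-3 box (Angstrom), centred on the origin.
#' @param seed RNG seed.
#' @return A `membrane_spec` list.
#' @export
membrane_spec <- function(n_lipids_leaflet = 32, chain_length = 12,
                          target_scd = 0.16, n_water = 200, D_water = 0.03,
                          pore_radius = 11, pore_length = 30, pore_vdw = 1.5,
                          box = c(60, 60, 70), seed = 1) {
  stopifnot(target_scd >= 0, target_scd < 0.5, D_water >= 0,
            pore_radius >= 0, length(box) == 3)
  if (pore_radius >= min(box[1], box[2]) / 2)
    stop("pore radius must be smaller than half the lateral box")
  structure(list(n_lipids_leaflet = as.integer(n_lipids_leaflet),
                 chain_length = as.integer(chain_length),
                 target_scd = target_scd, n_water = as.integer(n_water),
                 D_water = D_water, pore_radius = pore_radius,
                 pore_length = pore_length, pore_vdw = pore_vdw,
                 box = box, seed = as.integer(seed)),
            class = "membrane_spec")
}

## |S_CD| of a chain with tilt beta (C-H perpendicular to the chain axis,
## azimuthally averaged) is |P2(cos beta)| / 2. To hit a target |S_CD| = s
## we need <P2(cos beta)> = 2 s for the (negative-S_CD) acyl convention.
## Tilt distribution family: p(c) proportional to exp(lambda * P2(c)) on
## c = cos(beta) in [0, 1] (Maier-Saupe); lambda = 0 is isotropic.
p2 <- function(c_) 0.5 * (3 * c_^2 - 1)

ms_mean_p2 <- function(lambda) {
  f1 <- function(c_) p2(c_) * exp(lambda * p2(c_))
  f2 <- function(c_) exp(lambda * p2(c_))
  stats::integrate(f1, 0, 1, rel.tol = 1e-10)$value /
    stats::integrate(f2, 0, 1, rel.tol = 1e-10)$value
}

## Solve the Maier-Saupe concentration for a target <P2>.
solve_ms_lambda <- function(target_p2) {
  if (abs(target_p2) < 1e-12) return(0)
  if (target_p2 >= 1 || target_p2 <= -0.5)
    stop("target order parameter out of the reachable range (-0.5, 1)")
  f <- function(l) ms_mean_p2(l) - target_p2
  lo <- -50; hi <- 200
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

## Draw n tilt cosines from the Maier-Saupe density by inverse-CDF on a grid.
sample_ms_cos <- function(n, lambda) {
  if (lambda == 0) return(stats::runif(n))
  cg <- seq(0, 1, length.out = 2001)
  w <- exp(lambda * p2(cg) - max(lambda * p2(cg)))
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, cg, xout = stats::runif(n), rule = 2)$y
}

## All-trans zigzag chain of n carbons along +z in its body frame.
zigzag_chain <- function(n, bond = 1.54, angle = 111) {
  half <- (angle / 2) * pi / 180
  rise <- bond * sin(half)
  lat <- bond * cos(half)
  cbind(x = lat * (seq_len(n) %% 2), y = 0, z = -(seq_len(n) - 1) * rise)
}

#' Generate the synthetic membrane system
#'
#' @param spec A [membrane_spec()].
#' @param n_frames Number of frames.
#' @param dt Frame spacing in ps (the water walk uses `sigma^2 = 2 D dt`
#'   per axis per frame).
#' @return List with `trajectory`, `topology`, and `truth` (the ground
#'   truth: `D_water`, `target_scd`, `free_pore_radius`, tilt lambda).
#' @export
make_membrane_system <- function(spec, n_frames = 100, dt = 1) {
  stopifnot(inherits(spec, "membrane_spec"))
  set.seed(spec$seed)
  box <- spec$box
  nl <- spec$n_lipids_leaflet
  cl <- spec$chain_length
  lambda <- solve_ms_lambda(2 * spec$target_scd)

  tops <- list(); coord0 <- list()
  ## -- lipid placement (xy sites outside the pore, both leaflets) --
  lipid_sites <- NULL
  if (nl > 0) {
    sites <- matrix(NA_real_, 2 * nl, 2)
    got <- 0
    while (got < 2 * nl) {
      cand <- cbind(stats::runif(64, -box[1] / 2 + 3, box[1] / 2 - 3),
                    stats::runif(64, -box[2] / 2 + 3, box[2] / 2 - 3))
      ok <- sqrt(rowSums(cand^2)) > spec$pore_radius + 3 | spec$pore_radius == 0
      cand <- cand[ok, , drop = FALSE]
      take <- min(nrow(cand), 2 * nl - got)
      if (take > 0) sites[(got + 1):(got + take), ] <- cand[seq_len(take), ]
      got <- got + take
    }
    lipid_sites <- sites
    chain0 <- zigzag_chain(cl)
    rise_total <- abs(chain0[cl, 3])
    head_z <- rise_total + 2
    n_lipid_at <- cl + 1
    lip_top <- data.frame(
      name = rep(c("HD", sprintf("C%d", seq_len(cl))), 2 * nl),
      element = rep(c("P", rep("C", cl)), 2 * nl),
      resid = rep(seq_len(2 * nl), each = n_lipid_at),
      resname = "LIP",
      role = rep(c("head", rep("chain", cl)), 2 * nl),
      stringsAsFactors = FALSE)
    tops$lipid <- lip_top
  }
  ## -- pore wall beads: rings along z --
  pore_xyz <- NULL
  if (spec$pore_radius > 0) {
    zs <- seq(-spec$pore_length / 2, spec$pore_length / 2, by = 1.5)
    m <- 24
    ang <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
    pore_xyz <- do.call(rbind, lapply(zs, function(z)
      cbind(spec$pore_radius * cos(ang), spec$pore_radius * sin(ang), z)))
    tops$pore <- data.frame(
      name = "PW", element = "C",
      resid = seq_len(nrow(pore_xyz)), resname = "POR", role = "pore",
      stringsAsFactors = FALSE)
  }
  ## -- waters --
  if (spec$n_water > 0) {
    w0 <- cbind(stats::runif(spec$n_water, -box[1] / 2, box[1] / 2),
                stats::runif(spec$n_water, -box[2] / 2, box[2] / 2),
                stats::runif(spec$n_water, -box[3] / 2, box[3] / 2))
    tops$water <- data.frame(
      name = "OW", element = "O",
      resid = seq_len(spec$n_water), resname = "WAT", role = "water",
      stringsAsFactors = FALSE)
  }
  if (!length(tops)) stop("empty system: no lipids, pore, or waters")

  top_df <- do.call(rbind, tops)
  top_df$resid <- cumsum(c(1, diff(as.integer(factor(
    paste(top_df$resname, top_df$resid)))) != 0))
  row.names(top_df) <- NULL
  top <- topology(top_df)
  top$vdw[top$role == "pore"] <- spec$pore_vdw

  n_at <- nrow(top)
  coords <- array(NA_real_, c(n_at, 3, n_frames))
  is_lip <- top$role %in% c("head", "chain")
  is_pore <- top$role == "pore"
  is_wat <- top$role == "water"

  ## pore static; waters: Brownian increments; lipids: per-frame tilts
  if (spec$n_water > 0) {
    sig <- sqrt(2 * spec$D_water * dt)
    wat <- w0
  }
  for (f in seq_len(n_frames)) {
    if (nl > 0) {
      cosb <- sample_ms_cos(2 * nl, lambda)
      beta <- acos(cosb)
      phi <- stats::runif(2 * nl, 0, 2 * pi)     # tilt azimuth
      rho <- stats::runif(2 * nl, 0, 2 * pi)     # zigzag-plane spin
      lip_coords <- matrix(NA_real_, sum(is_lip), 3)
      chain0 <- zigzag_chain(cl)
      for (l in seq_len(2 * nl)) {
        upper <- l <= nl
        Rspin <- rotation_about_axis(c(0, 0, 1), rho[l])
        Rtilt <- rotation_about_axis(c(0, 1, 0), beta[l])
        Razim <- rotation_about_axis(c(0, 0, 1), phi[l])
        R <- Razim %*% Rtilt %*% Rspin
        body <- rbind(c(0, 0, 2), chain0)   # head bead above chain start
        if (!upper) body[, 3] <- -body[, 3] # lower leaflet points up
        placed <- body %*% t(R)
        z_anchor <- if (upper) box[3] / 4 else -box[3] / 4
        placed <- sweep(placed, 2,
                        c(lipid_sites[l, 1], lipid_sites[l, 2], z_anchor), `+`)
        rows <- ((l - 1) * (cl + 1) + 1):(l * (cl + 1))
        lip_coords[rows, ] <- placed
      }
      coords[is_lip, , f] <- lip_coords
    }
    if (!is.null(pore_xyz)) coords[is_pore, , f] <- pore_xyz
    if (spec$n_water > 0) {
      if (f > 1) wat <- wat + matrix(stats::rnorm(spec$n_water * 3, sd = sig),
                                     spec$n_water, 3)
      coords[is_wat, , f] <- wat
    }
  }

  list(trajectory = trajectory(coords, time = (seq_len(n_frames) - 1) * dt,
                               box = box),
       topology = top,
       truth = list(D_water = spec$D_water, target_scd = spec$target_scd,
                    lambda = lambda,
                    free_pore_radius = if (spec$pore_radius > 0)
                      spec$pore_radius - spec$pore_vdw else NA_real_),
       spec = spec)
}
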