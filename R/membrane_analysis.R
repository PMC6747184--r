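## Wrap coordinates into the origin-centred box.
wrap_coord <- function(x, L) x - L * round(x / L)

resolve_selection <- function(top, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.character(selection)) {
    idx <- which(top$role %in% selection | top$name %in% selection)
    if (!length(idx)) stop("selection matched no atoms: ",
                           paste(selection, collapse = ", "))
    return(idx)
  }
  stop("selection must be atom indices or role/name strings")
}

#' Electron density profile along the bilayer normal
#'
#' Histograms per-atom electron counts along z (wrapped into the box),
#' averages over frames and divides by the slab volume. One profile per
#' atom `role` group plus the total.
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` with an `electrons` column.
#' @param bin_width z bin width in Angstrom (default 1).
#' @param groups Roles to profile (default: all present).
#' @return A data.frame: `z` (bin centers), one column per group and
#'   `total`, in e- per Angstrom^3.
#' @export
electron_density_profile <- function(traj, top, bin_width = 1, groups = NULL) {
  if (is.null(top$electrons) || anyNA(top$electrons))
    stop("topology must provide electron counts for every atom")
  box <- traj$box[1, ]
  nf <- n_frames(traj)
  if (is.null(groups)) groups <- unique(top$role)
  edges <- seq(-box[3] / 2, box[3] / 2, by = bin_width)
  if (edges[length(edges)] < box[3] / 2) edges <- c(edges, box[3] / 2)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  slab_vol <- box[1] * box[2] * diff(edges)
  prof <- data.frame(z = centers)
  total <- numeric(length(centers))
  for (g in groups) {
    idx <- which(top$role == g)
    if (!length(idx)) next
    z <- wrap_coord(as.numeric(traj$coords[idx, 3, ]), box[3])
    w <- rep(top$electrons[idx], nf)
    b <- findInterval(z, edges, rightmost.closed = TRUE, all.inside = TRUE)
    dens <- numeric(length(centers))
    s <- rowsum(w, b)
    dens[as.integer(rownames(s))] <- s
    prof[[g]] <- dens / nf / slab_vol
    total <- total + prof[[g]]
  }
  prof$total <- total
  prof
}

#' Acyl chain deuterium order parameter profile
#'
#' For each interior chain carbon the two C-H directions are reconstructed
#' from the united-atom geometry (perpendicular to the C(i-1)-C(i+1) axis,
#' tetrahedral split about the bisector) and
#' \eqn{S_{CD} = 0.5\,\langle 3\cos^2\theta - 1\rangle} is averaged over
#' lipids, frames and the two hydrogens, with \eqn{\theta} the angle to
#' the bilayer normal (z).
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` whose chain atoms have `role == "chain"` and
#'   names `C1`, `C2`, ... within each lipid residue.
#' @return A data.frame: `carbon` (index), `scd` (signed mean), `abs_scd`.
#' @export
scd_profile <- function(traj, top) {
  ch <- which(top$role == "chain")
  if (!length(ch)) stop("no chain atoms in topology")
  lipids <- unique(top$resid[ch])
  cn <- as.integer(sub("^C", "", top$name[ch]))
  n_c <- max(cn)
  if (n_c < 3) stop("chains need at least 3 carbons")
  idx <- matrix(NA_integer_, length(lipids), n_c)
  for (li in seq_along(lipids)) {
    rows <- ch[top$resid[ch] == lipids[li]]
    idx[li, cn[match(rows, ch)]] <- rows
  }
  nf <- n_frames(traj)
  half_hch <- (109.47 / 2) * pi / 180
  out <- data.frame(carbon = 2:(n_c - 1), scd = NA_real_, abs_scd = NA_real_)
  flat <- function(ai) {
    ## -> (n_lipids*nf) x 3 matrix
    m <- traj$coords[ai, , , drop = FALSE]
    dim(m) <- c(length(ai), 3, nf)
    m <- aperm(m, c(1, 3, 2))
    dim(m) <- c(length(ai) * nf, 3)
    m
  }
  normalize <- function(m) m / sqrt(rowSums(m^2))
  cross_m <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
  for (i in 2:(n_c - 1)) {
    Cm <- flat(idx[, i - 1]); C0 <- flat(idx[, i]); Cp <- flat(idx[, i + 1])
    u <- normalize(Cp - Cm)
    w <- (Cm - C0) + (Cp - C0)
    w <- w - u * rowSums(w * u)
    w <- normalize(w)
    nv <- cross_m(u, w)
    h1 <- -w * cos(half_hch) + nv * sin(half_hch)
    h2 <- -w * cos(half_hch) - nv * sin(half_hch)
    s <- 0.5 * (3 * c(h1[, 3], h2[, 3])^2 - 1)
    out$scd[i - 1] <- mean(s)
    out$abs_scd[i - 1] <- abs(mean(s))
  }
  out
}

#' Mean square displacement and diffusion coefficient
#'
#' Origin-averaged MSD over a set of lag times, least-squares slope on a
#' window of the lag range, and the diffusion coefficient via
#' \eqn{D = \mathrm{slope} \times 10.0/(2N)} (slope in Angstrom^2 ps^-1,
#' `D` in 1e-5 cm^2 s^-1; the raw Angstrom^2 ps^-1 value is
#' \eqn{\mathrm{slope}/(2N)}). Requires unwrapped coordinates; frame-to-
#' frame jumps larger than half the box abort with an unwrap hint. Motion
#' with a log-log MSD slope near 2 is flagged ballistic (non-diffusive).
#'
#' @param traj A `Trajectory` (unwrapped coordinates).
#' @param selection Atom indices, or role/name strings resolved against
#'   `top` (e.g. `"water"`).
#' @param dims Number of dimensions `N`: 3 = xyz, 2 = xy, 1 = z.
#' @param fit_window Fraction range of the maximum lag used for the fit
#'   (default `c(0.1, 0.5)`).
#' @param n_lags Number of lag values sampled (default 60).
#' @param origin_stride Time-origin spacing in frames (default: every
#'   10 ps worth of frames).
#' @param top A `Topology`, required for character selections.
#' @return An `msd_series`: data.frame `lag` (ps), `msd` (Angstrom^2);
#'   attributes `slope`, `D_raw` (A^2/ps), `D` (1e-5 cm^2/s),
#'   `dims`, `ballistic`.
#' @export
msd_diffusion <- function(traj, selection, dims = 3,
                          fit_window = c(0.1, 0.5), n_lags = 60,
                          origin_stride = NULL, top = NULL) {
  stopifnot(dims %in% 1:3)
  idx <- if (is.numeric(selection)) as.integer(selection) else {
    if (is.null(top)) stop("character selections need a topology (top =)")
    resolve_selection(top, selection)
  }
  coords_sel <- traj$coords[idx, , , drop = FALSE]
  nf <- dim(coords_sel)[3]
  if (nf < 4) stop("need at least 4 frames")
  dt <- if (nf > 1) stats::median(diff(traj$time)) else 1
  box <- traj$box[1, ]
  jumps <- abs(coords_sel[, , -1, drop = FALSE] -
                 coords_sel[, , -nf, drop = FALSE])
  if (any(apply(jumps, 2, max) > box / 2))
    stop("wrapped coordinates detected (jump > box/2): ",
         "unwrap the trajectory before computing MSD")
  dsel <- if (dims == 1) 3 else seq_len(dims)
  if (is.null(origin_stride)) origin_stride <- max(1L, round(10 / dt))
  origins <- seq(1L, nf - 1L, by = origin_stride)
  lags <- unique(round(seq(1, floor(nf / 2), length.out = n_lags)))
  msd <- vapply(lags, function(lg) {
    og <- origins[origins + lg <= nf]
    d <- coords_sel[, dsel, og + lg, drop = FALSE] -
      coords_sel[, dsel, og, drop = FALSE]
    sum(d * d) / (length(idx) * length(og))
  }, 0)
  lag_ps <- lags * dt
  ## ballistic check: slope of log msd vs log lag
  ll <- stats::coef(stats::lm(log(msd) ~ log(lag_ps)))[2]
  ballistic <- is.finite(ll) && ll > 1.5
  sel_fit <- lag_ps >= fit_window[1] * max(lag_ps) &
    lag_ps <= fit_window[2] * max(lag_ps)
  fit <- stats::lm(msd[sel_fit] ~ lag_ps[sel_fit])
  slope <- stats::coef(fit)[2]
  structure(data.frame(lag = lag_ps, msd = msd),
            class = c("msd_series", "data.frame"),
            slope = unname(slope),
            D_raw = unname(slope) / (2 * dims),
            D = unname(slope) * 10.0 / (2 * dims),
            dims = dims, ballistic = ballistic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("<msd_series> N = %d, slope = %.4g A^2/ps, D = %.4g x1e-5 cm^2/s%s\n",
              attr(x, "dims"), attr(x, "slope"), attr(x, "D"),
              if (attr(x, "ballistic")) " [BALLISTIC - not diffusive]" else ""))
  invisible(x)
}

#' Volumetric water density on a regular grid
#'
#' Histograms water oxygens on a cubic grid (default 1 Angstrom spacing),
#' normalised per frame, wrapped into the box. The grid sums to the mean
#' water count per frame and can be written for VMD with [write_dx()].
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` with water oxygens (`role == "water"`).
#' @param spacing Grid spacing in Angstrom (> 0).
#' @return List: `grid` (3-D array, mean occupancy per frame), `origin`,
#'   `spacing`.
#' @export
water_grid_density <- function(traj, top, spacing = 1) {
  if (spacing <= 0) stop("spacing must be positive")
  idx <- which(top$role == "water")
  if (!length(idx)) stop("no water atoms in topology")
  box <- traj$box[1, ]
  nbin <- pmax(1L, ceiling(box / spacing))
  origin <- -box / 2
  nf <- n_frames(traj)
  counts <- array(0, nbin)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[idx, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    xyz <- sweep(xyz, 2, box, function(x, L) wrap_coord(x, L))
    b <- lapply(1:3, function(j)
      pmin(nbin[j], pmax(1L, 1L + floor((xyz[, j] - origin[j]) / spacing))))
    flat <- (b[[3]] - 1L) * nbin[1] * nbin[2] + (b[[2]] - 1L) * nbin[1] + b[[1]]
    tb <- tabulate(flat, nbins = prod(nbin))
    counts <- counts + array(tb, nbin)
  }
  list(grid = counts / nf, origin = origin, spacing = spacing)
}

#' Water count in the pore shell
#'
#' Counts, per frame, the water oxygens within `cutoff` of any pore atom.
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology`.
#' @param pore_selection Atom indices or role/name strings for the pore
#'   atoms (default role `"pore"`).
#' @param cutoff Shell distance in Angstrom (default 3.4).
#' @return Integer vector, one count per frame.
#' @export
pore_water_count <- function(traj, top, pore_selection = "pore",
                             cutoff = 3.4) {
  pidx <- resolve_selection(top, pore_selection)
  widx <- which(top$role == "water")
  if (!length(pidx)) stop("empty pore selection")
  if (!length(widx)) return(integer(n_frames(traj)))
  nf <- n_frames(traj)
  cut2 <- cutoff^2
  vapply(seq_len(nf), function(f) {
    W <- traj$coords[widx, , f, drop = FALSE]; dim(W) <- c(length(widx), 3)
    P <- traj$coords[pidx, , f, drop = FALSE]; dim(P) <- c(length(pidx), 3)
    d2 <- outer(rowSums(W^2), rowSums(P^2), `+`) - 2 * W %*% t(P)
    sum(apply(d2, 1, min) <= cut2 + 1e-9)
  }, 1L)
}

#' Pore radius profile along z
#'
#' For each z slice, the pore radius is the largest clearance of any point
#' of an in-plane search grid: `max over grid points of (min over nearby
#' atoms of (3-D distance - atom vdW radius))`, capped at `max_radius`.
#' The grid (default 0.25 Angstrom spacing) is centred on the wall-atom
#' centroid of the slice; slices without atoms in the search shell return
#' the cap and are flagged.
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` with `vdw` radii; wall atoms selected by role
#'   `"pore"` by default.
#' @param z_range Length-2 z interval (default: span of the wall atoms).
#' @param z_step Slice spacing in Angstrom (default 1.5).
#' @param max_radius Search cap in Angstrom (default 15).
#' @param grid_spacing In-plane grid resolution (default 0.25).
#' @param wall_selection Selection for wall atoms.
#' @param shell_dz Include atoms within this |dz| of the slice (default 4).
#' @return A data.frame `z`, `radius` (mean over frames), `sd`, `capped`.
#' @export
pore_radius_profile <- function(traj, top, z_range = NULL, z_step = 1.5,
                                max_radius = 15, grid_spacing = 0.25,
                                wall_selection = "pore", shell_dz = 4) {
  widx <- resolve_selection(top, wall_selection)
  vdw <- top$vdw[widx]
  nf <- n_frames(traj)
  if (is.null(z_range))
    z_range <- range(traj$coords[widx, 3, ])
  zs <- seq(z_range[1], z_range[2], by = z_step)
  gr <- seq(-max_radius, max_radius, by = grid_spacing)
  gxy <- as.matrix(expand.grid(gx = gr, gy = gr))
  gxy <- gxy[rowSums(gxy^2) <= max_radius^2, ]
  res <- matrix(NA_real_, length(zs), nf)
  capped <- matrix(FALSE, length(zs), nf)
  for (f in seq_len(nf)) {
    W <- traj$coords[widx, , f, drop = FALSE]; dim(W) <- c(length(widx), 3)
    for (zi in seq_along(zs)) {
      z0 <- zs[zi]
      near <- which(abs(W[, 3] - z0) <= shell_dz)
      if (!length(near)) {
        res[zi, f] <- max_radius
        capped[zi, f] <- TRUE
        next
      }
      ctr <- colMeans(W[near, 1:2, drop = FALSE])
      dz2 <- (W[near, 3] - z0)^2
      ## clearance at each grid point: min over atoms of (dist - vdw)
      px <- gxy[, 1] + ctr[1]
      py <- gxy[, 2] + ctr[2]
      best <- rep(Inf, length(px))
      for (a in seq_along(near)) {
        d <- sqrt((px - W[near[a], 1])^2 + (py - W[near[a], 2])^2 + dz2[a]) -
          vdw[near[a]]
        best <- pmin(best, d)
      }
      r <- max(best)
      if (r >= max_radius) capped[zi, f] <- TRUE
      res[zi, f] <- min(r, max_radius)
    }
  }
  data.frame(z = zs,
             radius = rowMeans(res),
             sd = apply(res, 1, stats::sd),
             capped = apply(capped, 1, any))
}

#' Percent alpha-helicity per monomer per frame
#'
#' A residue is counted helical when its (phi, psi) pair falls in the
#' alpha-helical window (defaults `[-100, -30] x [-67, -7]` degrees);
#' the percentage is over residues with both angles defined.
#'
#' @param dihedrals A `dihedral_series`.
#' @param monomer_map Integer/factor of length `n_res` assigning residues
#'   to monomers (default: all one monomer).
#' @param phi_range,psi_range Helical windows in degrees.
#' @return Matrix `n_frames x n_monomers` of percentages.
#' @export
percent_helicity <- function(dihedrals, monomer_map = NULL,
                             phi_range = c(-100, -30),
                             psi_range = c(-67, -7)) {
  phi <- dihedrals$phi
  psi <- dihedrals$psi
  nres <- ncol(phi)
  if (is.null(monomer_map)) monomer_map <- rep(1L, nres)
  stopifnot(length(monomer_map) == nres)
  helical <- phi >= phi_range[1] & phi <= phi_range[2] &
    psi >= psi_range[1] & psi <= psi_range[2]
  assignable <- !is.na(phi) & !is.na(psi)
  mons <- sort(unique(monomer_map))
  out <- sapply(mons, function(m) {
    cols <- which(monomer_map == m)
    100 * rowSums(helical[, cols, drop = FALSE], na.rm = TRUE) /
      pmax(1L, rowSums(assignable[, cols, drop = FALSE]))
  })
  out <- matrix(out, nrow = nrow(phi))
  colnames(out) <- paste0("monomer", mons)
  out
}

#' Helix bend angle per frame per monomer
#'
#' Fits a line direction (principal axis) through the residue centres of
#' mass of the N-terminal window and of the C-terminal window, orients
#' each direction away from the monomer midpoint, and reports the angle
#' between the two oriented vectors: a straight helix gives ~180 degrees
#' and bending decreases the angle.
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology`.
#' @param n_term_residues,c_term_residues Residue indices (within each
#'   monomer, 1-based from the monomer start) of the two windows; default
#'   first and last 5 residues.
#' @return Matrix `n_frames x n_monomers` of angles in degrees (`NA` when
#'   a window is degenerate).
#' @export
bend_angle <- function(traj, top, n_term_residues = NULL,
                       c_term_residues = NULL) {
  nf <- n_frames(traj)
  mons <- sort(unique(top$monomer))
  out <- matrix(NA_real_, nf, length(mons))
  colnames(out) <- paste0("monomer", mons)
  for (mi in seq_along(mons)) {
    midx <- which(top$monomer == mons[mi])
    resids <- sort(unique(top$resid[midx]))
    nres <- length(resids)
    nt <- if (is.null(n_term_residues)) seq_len(min(5, nres %/% 2))
          else n_term_residues
    ct <- if (is.null(c_term_residues)) (nres - min(5, nres %/% 2) + 1):nres
          else c_term_residues
    if (length(nt) < 2 || length(ct) < 2)
      stop("need at least 2 residues per terminal window")
    res_atoms <- lapply(resids, function(r) midx[top$resid[midx] == r])
    masses <- lapply(res_atoms, function(a) top$mass[a])
    for (f in seq_len(nf)) {
      com <- t(vapply(seq_len(nres), function(r) {
        xyz <- traj$coords[res_atoms[[r]], , f, drop = FALSE]
        dim(xyz) <- c(length(res_atoms[[r]]), 3)
        colSums(xyz * masses[[r]]) / sum(masses[[r]])
      }, numeric(3)))
      mid <- colMeans(com)
      dir_of <- function(rows) {
        P <- com[rows, , drop = FALSE]
        Pc <- sweep(P, 2, colMeans(P))
        sv <- svd(Pc)
        if (sv$d[1] < 1e-8) return(NULL)  # degenerate window
        v <- sv$v[, 1]
        if (sum(v * (colMeans(P) - mid)) < 0) v <- -v
        v
      }
      vN <- dir_of(nt)
      vC <- dir_of(ct)
      if (is.null(vN) || is.null(vC)) next
      cosang <- max(-1, min(1, sum(vN * vC)))
      out[f, mi] <- acos(cosang) * 180 / pi
    }
  }
  out
}

#' Electric field unit conversions
#'
#' Completes a partial field specification. `efz` is the applied field in
#' kcal (mol Angstrom e)^-1; the conversion constant is
#' 4184 J mol^-1 / Faraday = 0.043364 V per Angstrom per unit `efz`
#' (0.43364 V nm^-1). Alternatively a transmembrane `potential_V` across
#' `thickness_nm` gives the field directly.
#'
#' @param efz Field intensity in kcal (mol A e)^-1.
#' @param potential_V Transmembrane potential in volts.
#' @param thickness_nm Membrane thickness in nm.
#' @return List: `efz`, `field_V_per_A`, `field_V_per_nm`, `potential_V`,
#'   `thickness_nm` (mutually consistent; `NA` where underdetermined).
#' @examples
#' field_convert(efz = 0.080)$field_V_per_nm          # 0.0347 -> "0.03"
#' field_convert(potential_V = 0.07, thickness_nm = 3.5)$field_V_per_nm # 0.02
#' @export
field_convert <- function(efz = NULL, potential_V = NULL, thickness_nm = NULL) {
  if (is.null(efz) && (is.null(potential_V) || is.null(thickness_nm)))
    stop("give either efz or both potential_V and thickness_nm")
  if (!is.null(thickness_nm) && !is.null(potential_V) && thickness_nm == 0)
    stop("thickness must be nonzero")
  if (!is.null(efz)) {
    f_A <- efz * KCAL_PER_MOL_E_A_TO_V_PER_A
    f_nm <- 10 * f_A
    pot <- if (!is.null(thickness_nm)) f_nm * thickness_nm else NA_real_
    list(efz = efz, field_V_per_A = f_A, field_V_per_nm = f_nm,
         potential_V = pot, thickness_nm = thickness_nm %||% NA_real_)
  } else {
    f_nm <- potential_V / thickness_nm
    f_A <- f_nm / 10
    list(efz = f_A / KCAL_PER_MOL_E_A_TO_V_PER_A,
         field_V_per_A = f_A, field_V_per_nm = f_nm,
         potential_V = potential_V, thickness_nm = thickness_nm)
  }
}
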