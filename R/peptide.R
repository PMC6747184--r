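## Internal-coordinate chain building (natural extension reference frame):
## place atom D given A, B, C, the B-C-D... i.e. bond C-D, angle B-C-D,
## torsion A-B-C-D.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Ideal backbone geometry (Engh-Huber-like values).
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2)

#' Build an N-CA-C backbone chain from phi/psi angles
#'
#' Constructs ideal-geometry backbone coordinates for given per-residue
#' torsions (omega fixed at 180 degrees). The default phi = -57, psi = -47
#' is the ideal alpha helix with a rise close to 1.5 Angstrom per residue.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone torsions in degrees (scalar or per residue).
#' @return `3 n_res x 3` coordinate matrix, atoms ordered N, CA, C per
#'   residue.
#' @export
build_backbone <- function(n_res, phi = -57, psi = -47) {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  xyz <- matrix(NA_real_, 3 * n_res, 3)
  g <- BB_GEOM
  ## seed residue in a canonical pose
  xyz[1, ] <- c(0, 0, 0)                                   # N1
  xyz[2, ] <- c(g$b_n_ca, 0, 0)                            # CA1
  ang <- g$a_n_ca_c * pi / 180
  xyz[3, ] <- xyz[2, ] + c(-g$b_ca_c * cos(ang), g$b_ca_c * sin(ang), 0) # C1
  for (i in seq_len(n_res - 1)) {
    Ni <- 3 * i - 2; CAi <- 3 * i - 1; Ci <- 3 * i
    ## N(i+1): torsion psi_i about N(i)-CA(i)-C(i)
    xyz[Ci + 1, ] <- place_atom(xyz[Ni, ], xyz[CAi, ], xyz[Ci, ],
                                g$b_c_n, g$a_ca_c_n, psi[i])
    ## CA(i+1): omega = 180 about CA(i)-C(i)-N(i+1)
    xyz[Ci + 2, ] <- place_atom(xyz[CAi, ], xyz[Ci, ], xyz[Ci + 1, ],
                                g$b_n_ca, g$a_c_n_ca, 180)
    ## C(i+1): torsion phi_(i+1) about C(i)-N(i+1)-CA(i+1)
    xyz[Ci + 3, ] <- place_atom(xyz[Ci, ], xyz[Ci + 1, ], xyz[Ci + 2, ],
                                g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

ca_index <- function(res) 3 * res - 1

rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
    3, 3, byrow = TRUE)
}

## Two ideal-helix arms joined by a hinge: the torsions of residues
## hinge-1 .. hinge+1 are interpolated from helical values toward a
## turn-like pair by a scalar t in [0, ~1]; t controls the inter-arm angle
## and hence the terminal CA-CA distance.
HINGE_TURN <- c(phi = 75, psi = 130)

hinge_torsions <- function(n_res, hinge, t) {
  phi <- rep(-57, n_res)
  psi <- rep(-47, n_res)
  psi[hinge - 1] <- -47 + t * (HINGE_TURN["psi"] + 47)
  phi[hinge] <- -57 + t * (HINGE_TURN["phi"] + 57)
  psi[hinge] <- -47 + t * (HINGE_TURN["psi"] + 47)
  phi[hinge + 1] <- -57 + t * (HINGE_TURN["phi"] + 57)
  list(phi = phi, psi = psi)
}

hinge_chain <- function(n_res, hinge, t) {
  tor <- hinge_torsions(n_res, hinge, t)
  build_backbone(n_res, tor$phi, tor$psi)
}

## Smallest t whose chain hits the CA(1)-CA(n) target distance.
solve_hinge <- function(n_res, hinge, target) {
  d_of <- function(t) {
    z <- hinge_chain(n_res, hinge, t)
    sqrt(sum((z[ca_index(n_res), ] - z[ca_index(1), ])^2)) - target
  }
  grid <- seq(0, 1.2, length.out = 61)
  vals <- vapply(grid, d_of, 0)
  if (vals[1] <= 0) return(0)  # straight helix already at/below target
  k <- which(vals <= 0)[1]
  if (is.na(k)) stop("end-to-end target ", target,
                     " Angstrom is not reachable for this chain")
  stats::uniroot(d_of, c(grid[k - 1], grid[k]), tol = 1e-8)$root
}

#' Specification of the synthetic two-state peptide
#'
#' A backbone-only peptide that interconverts between a bent hairpin-like
#' helix and a (nearly) linear helix, mimicking a 20-residue pore-forming
#' peptide with a flexible hinge at a central glycine. Each generated frame
#' is independently bent with probability `p_bent`; the bent and linear
#' geometries are two rigid ideal-helix arms joined at the hinge, with the
#' inter-arm angle solved so the terminal CA-CA distance hits the
#' respective target.
#'
#' @param n_res Residue count (default 20).
#' @param hinge Hinge residue index, strictly inside the chain (default 11).
#' @param p_bent Probability that a frame is in the bent state
#'   (default 0.8, placing the linear basin about 0.8 kcal mol^-1 above
#'   the bent one at 300 K).
#' @param noise Gaussian per-coordinate noise sigma in Angstrom.
#' @param bent_target Bent-state terminal CA-CA distance (Angstrom).
#' @param linear_target Linear-state terminal CA-CA distance (Angstrom), or
#'   `NA` (default) for the unbent ideal helix (about 29.8 Angstrom for 20
#'   residues at a 1.5 Angstrom rise; real helical peptides read shorter
#'   because of terminal fraying, which this surrogate does not model).
#' @param seed RNG seed.
#' @return A `peptide_spec` list.
#' @export
peptide_spec <- function(n_res = 20, hinge = 11, p_bent = 0.8, noise = 0.15,
                         bent_target = 10, linear_target = NA, seed = 1) {
  stopifnot(p_bent >= 0, p_bent <= 1, bent_target > 0,
            is.na(linear_target) || linear_target > 0, noise >= 0)
  if (hinge <= 1 || hinge >= n_res)
    stop("hinge must lie strictly inside the chain")
  structure(list(n_res = as.integer(n_res), hinge = as.integer(hinge),
                 p_bent = p_bent, noise = noise, bent_target = bent_target,
                 linear_target = linear_target, seed = as.integer(seed)),
            class = "peptide_spec")
}

#' Generate a two-state helix trajectory
#'
#' @param spec A [peptide_spec()].
#' @param n_frames Number of frames.
#' @param dt Frame spacing in ps (time stamps only; frames are independent
#'   draws from the two-state mixture, not dynamics).
#' @return List with `trajectory` (`Trajectory`), `topology` (`Topology`),
#'   and `state` (per-frame factor `"bent"`/`"linear"`, the ground truth).
#' @export
make_two_state_helix_trajectory <- function(spec, n_frames = 1000, dt = 1) {
  stopifnot(inherits(spec, "peptide_spec"))
  n_res <- spec$n_res
  t_bent <- solve_hinge(n_res, spec$hinge, spec$bent_target)
  t_lin <- if (is.na(spec$linear_target)) 0
           else solve_hinge(n_res, spec$hinge, spec$linear_target)
  xyz_bent <- hinge_chain(n_res, spec$hinge, t_bent)
  xyz_lin <- hinge_chain(n_res, spec$hinge, t_lin)
  d_lin <- sqrt(sum((xyz_lin[ca_index(n_res), ] - xyz_lin[ca_index(1), ])^2))
  sep <- abs(d_lin - spec$bent_target)
  ## end-to-end noise sd is ~ sqrt(2) * per-coordinate sigma
  if (spec$noise > 0 && sep < 3 * sqrt(2) * spec$noise)
    warning("coordinate noise is large enough to blur the two states ",
            "(separation < 3 sigma)")

  set.seed(spec$seed)
  bent <- stats::runif(n_frames) < spec$p_bent
  n_at <- 3 * n_res
  coords <- array(NA_real_, c(n_at, 3, n_frames))
  for (i in seq_len(n_frames)) {
    base <- if (bent[i]) xyz_bent else xyz_lin
    coords[, , i] <- base + matrix(stats::rnorm(n_at * 3, sd = spec$noise),
                                   n_at, 3)
  }
  resname <- rep("ALA", n_res)
  resname[spec$hinge] <- "GLY"
  top <- topology(data.frame(
    name = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res),
    resid = rep(seq_len(n_res), each = 3),
    resname = rep(resname, each = 3),
    role = "peptide", monomer = 1L,
    stringsAsFactors = FALSE))
  list(trajectory = trajectory(coords, time = (seq_len(n_frames) - 1) * dt),
       topology = top,
       state = factor(ifelse(bent, "bent", "linear"),
                      levels = c("bent", "linear")),
       spec = spec)
}

#' Terminal CA-CA end-to-end distance per frame
#'
#' The first and last residues' alpha carbons stand in for the N- and
#' C-terminal reference atoms of the real peptide.
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` with CA atoms named `"CA"`.
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
end_to_end_distance <- function(traj, top) {
  ca <- which(top$name == "CA")
  if (length(ca) < 2) stop("topology has fewer than two CA atoms")
  i <- ca[1]; j <- ca[length(ca)]
  d <- traj$coords[j, , ] - traj$coords[i, , ]
  if (is.null(dim(d))) d <- matrix(d, 3, 1)
  sqrt(colSums(d^2))
}
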