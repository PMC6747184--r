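## Shared fixture builders: everything is generated in code at test time.

## Minimal backbone topology for an n-residue N/CA/C chain.
bb_topology <- function(n_res, hinge = NULL) {
  resname <- rep("ALA", n_res)
  if (!is.null(hinge)) resname[hinge] <- "GLY"
  topology(data.frame(
    name = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res),
    resid = rep(seq_len(n_res), each = 3),
    resname = rep(resname, each = 3),
    role = "peptide",
    stringsAsFactors = FALSE))
}

## Random rigid transform (proper rotation + translation).
random_rigid <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, rt) sweep(xyz %*% rt$R, 2, rt$t, `+`)

## Apply a rigid transform to every frame of a trajectory.
transform_trajectory <- function(traj, rt) {
  for (f in seq_len(dim(traj$coords)[3]))
    traj$coords[, , f] <- apply_rigid(traj$coords[, , f], rt)
  traj
}

## Brute-force O(waters x pore) shell count, written independently of
## pore_water_count (per-pair loop, no vectorised distance trick).
brute_force_shell_count <- function(traj, top, cutoff = 3.4) {
  widx <- which(top$role == "water")
  pidx <- which(top$role == "pore")
  vapply(seq_len(dim(traj$coords)[3]), function(f) {
    n <- 0L
    for (w in widx) {
      inside <- FALSE
      for (p in pidx) {
        if (sqrt(sum((traj$coords[w, , f] - traj$coords[p, , f])^2)) <= cutoff) {
          inside <- TRUE
          break
        }
      }
      if (inside) n <- n + 1L
    }
    n
  }, 1L)
}

## Four points realising a prescribed torsion angle about the 2-3 bond
## (p2-p3 along z; p4 rotated about that axis by the angle from the
## p1 half-plane; rotation by +a yields IUPAC torsion +a).
four_point_torsion <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rbind(c(1, 0, -0.5),
        c(0, 0, 0),
        c(0, 0, 1.5),
        c(cos(a), sin(a), 2))
}
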