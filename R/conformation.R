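#' Torsion angle of four points
#'
#' Standard IUPAC sign convention, degrees in (-180, 180]. Vectorised over
#' frames when the inputs are `n x 3` matrices.
#'
#' @param p1,p2,p3,p4 Length-3 vectors or `n x 3` matrices.
#' @return Torsion angle(s) in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, 1, 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross_m <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross_m(b1, b2)
  n2 <- cross_m(b2, b3)
  m1 <- cross_m(b2 / sqrt(rowSums(b2^2)), n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Backbone phi/psi dihedrals per frame
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1) over
#' the `N`,`CA`,`C` atoms of each residue; terminal residues lacking a
#' neighbour yield `NA`. Residues with missing backbone atoms are flagged
#' (warning) and return `NA`, not an error.
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` with backbone atoms named `N`, `CA`, `C`.
#' @return A `dihedral_series`: list with `phi` and `psi`
#'   (`n_frames x n_res` matrices, degrees) and `resid`.
#' @export
compute_dihedrals <- function(traj, top) {
  resids <- unique(top$resid[top$role %in% c("peptide", "other") |
                               top$name %in% c("N", "CA", "C")])
  resids <- sort(resids)
  nres <- length(resids)
  nf <- n_frames(traj)
  at <- function(res, nm) which(top$resid == res & top$name == nm)[1]
  Ni <- vapply(resids, at, 1L, nm = "N")
  CAi <- vapply(resids, at, 1L, nm = "CA")
  Ci <- vapply(resids, at, 1L, nm = "C")
  broken <- is.na(Ni) | is.na(CAi) | is.na(Ci)
  if (any(broken))
    warning("residue(s) with incomplete backbone flagged as NA: ",
            paste(resids[broken], collapse = ", "))
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  xyz_at <- function(j) t(traj$coords[j, , , drop = TRUE])  # nf x 3
  for (r in seq_len(nres)) {
    if (broken[r]) next
    if (r > 1 && !broken[r - 1])
      phi[, r] <- torsion_angle(xyz_at(Ci[r - 1]), xyz_at(Ni[r]),
                                xyz_at(CAi[r]), xyz_at(Ci[r]))
    if (r < nres && !broken[r + 1])
      psi[, r] <- torsion_angle(xyz_at(Ni[r]), xyz_at(CAi[r]),
                                xyz_at(Ci[r]), xyz_at(Ni[r + 1]))
  }
  structure(list(phi = phi, psi = psi, resid = resids), class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("<dihedral_series>", nrow(x$phi), "frames x", ncol(x$phi), "residues\n")
  invisible(x)
}

#' Dihedral principal component analysis
#'
#' Maps every available phi/psi angle to its (cos, sin) pair, removes
#' all-`NA` columns (chain termini), column-centres, and
#' eigendecomposes the covariance. Projections are returned for all
#' frames.
#'
#' @param dihedrals A `dihedral_series` from [compute_dihedrals()], or a
#'   plain numeric matrix of angles in degrees (frames x angles).
#' @return A `pc_model`: `mean`, `loadings` (eigenvectors in columns),
#'   `eigenvalues` (non-increasing), `var_explained`, `projections`
#'   (frames x modes).
#' @export
dihedral_pca <- function(dihedrals) {
  ang <- if (inherits(dihedrals, "dihedral_series"))
    cbind(dihedrals$phi, dihedrals$psi) else as.matrix(dihedrals)
  if (nrow(ang) < 2) stop("need at least 2 frames")
  keep <- colSums(!is.na(ang)) == nrow(ang)
  ang <- ang[, keep, drop = FALSE]
  rad <- ang * pi / 180
  X <- cbind(cos(rad), sin(rad))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / (nrow(X) - 1)
  tot <- sum(ev)
  structure(list(mean = mu, loadings = sv$v, eigenvalues = ev,
                 var_explained = if (tot > 0) ev / tot else rep(0, length(ev)),
                 projections = Xc %*% sv$v),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  k <- min(3, length(x$eigenvalues))
  cat("<pc_model>", nrow(x$projections), "frames,",
      length(x$eigenvalues), "modes; leading variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project new dihedral data on an existing PC basis
#'
#' @param model A `pc_model`.
#' @param dihedrals Angles (same layout used to fit `model`).
#' @return Projection matrix (frames x modes).
#' @export
project_dihedrals <- function(model, dihedrals) {
  ang <- if (inherits(dihedrals, "dihedral_series"))
    cbind(dihedrals$phi, dihedrals$psi) else as.matrix(dihedrals)
  keep <- colSums(!is.na(ang)) == nrow(ang)
  ang <- ang[, keep, drop = FALSE]
  rad <- ang * pi / 180
  X <- cbind(cos(rad), sin(rad))
  if (ncol(X) != length(model$mean))
    stop("angle layout does not match the PC basis")
  sweep(X, 2, model$mean) %*% model$loadings
}

#' 2-D free-energy landscape over PC1/PC2
#'
#' Delegates to [reweighted_pmf()] on the first two projections.
#'
#' @param pc_model A `pc_model`.
#' @param delta_V Per-frame boost series (or `NULL`).
#' @param scheme A [reweight_scheme()].
#' @param bins Bins per axis (default 60).
#' @return An `fe_surface` (2-D).
#' @export
fel_2d <- function(pc_model, delta_V = NULL, scheme = reweight_scheme(),
                   bins = 60) {
  reweighted_pmf(pc_model$projections[, 1:2, drop = FALSE], delta_V,
                 bins = bins, scheme = scheme)
}

#' k-means clustering of conformations in PC space
#'
#' Deterministic under the seed (10 restarts). The representative of each
#' cluster is the frame nearest its centroid.
#'
#' @param pc_model A `pc_model`.
#' @param k Number of clusters.
#' @param n_pcs Leading PCs to cluster on (default 2).
#' @param seed RNG seed.
#' @return A `cluster_result`: `labels` (per frame), `k`,
#'   `representative` (frame index per cluster), `population` (fractions
#'   summing to 1), `centers`.
#' @export
cluster_conformations <- function(pc_model, k, n_pcs = 2, seed = 1) {
  X <- pc_model$projections[, seq_len(min(n_pcs, ncol(pc_model$projections))),
                            drop = FALSE]
  if (k < 1 || k > nrow(X)) stop("k must be between 1 and the frame count")
  if (k > nrow(unique(as.data.frame(X))))
    stop("k exceeds the number of distinct points")
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
  rep_idx <- vapply(seq_len(k), function(c_) {
    members <- which(km$cluster == c_)
    d2 <- rowSums((X[members, , drop = FALSE] -
                     matrix(km$centers[c_, ], length(members), ncol(X),
                            byrow = TRUE))^2)
    members[which.min(d2)]
  }, 1L)
  structure(list(labels = km$cluster, k = k, representative = rep_idx,
                 population = as.numeric(table(factor(km$cluster,
                                                      levels = seq_len(k)))) /
                   nrow(X),
                 centers = km$centers),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$k, "clusters; populations:",
      paste(sprintf("%.2f", x$population), collapse = ", "), "\n")
  invisible(x)
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `reference` with a
#' proper rotation (SVD with determinant correction), then RMSD.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`, with
#'   row-wise correspondence.
#' @return RMSD in Angstrom after the fit.
#' @export
superpose_rmsd <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            all(dim(mobile) == dim(reference)))
  if (nrow(mobile) < 3) stop("need at least 3 atoms")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  A <- sweep(mobile, 2, mc)
  B <- sweep(reference, 2, rc)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  sqrt(mean(rowSums((fitted - B)^2)))
}

#' Kullback-Leibler divergence between two sample sets
#'
#' Histograms both samples on shared bins spanning the pooled range with
#' an additive pseudo-count (mandatory: disjoint supports would otherwise
#' give an infinite divergence), renormalises, and returns
#' \eqn{KLD(P\|Q) = \sum_i p_i \ln(p_i/q_i)}. The `"kde"` backend
#' evaluates Gaussian kernel density estimates on a shared grid instead of
#' bin counts.
#'
#' @param p_samples,q_samples Numeric sample vectors.
#' @param bins Number of shared bins / grid points (default 100).
#' @param pseudo Additive pseudo-count per bin (default 1e-6).
#' @param backend `"bin"` or `"kde"`.
#' @return Non-negative scalar divergence (nats).
#' @export
kld_divergence <- function(p_samples, q_samples, bins = 100, pseudo = 1e-6,
                           backend = c("bin", "kde")) {
  backend <- match.arg(backend)
  rng <- range(c(p_samples, q_samples))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  if (backend == "bin") {
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    hp <- tabulate(findInterval(p_samples, br, rightmost.closed = TRUE,
                                all.inside = TRUE), nbins = bins)
    hq <- tabulate(findInterval(q_samples, br, rightmost.closed = TRUE,
                                all.inside = TRUE), nbins = bins)
    p <- hp / sum(hp) + pseudo
    q <- hq / sum(hq) + pseudo
  } else {
    bw <- stats::bw.nrd0(c(p_samples, q_samples))
    grid <- seq(rng[1] - 3 * bw, rng[2] + 3 * bw, length.out = bins)
    dp <- stats::density(p_samples, bw = bw, from = grid[1],
                         to = grid[bins], n = bins)
    dq <- stats::density(q_samples, bw = bw, from = grid[1],
                         to = grid[bins], n = bins)
    p <- dp$y / sum(dp$y) + pseudo
    q <- dq$y / sum(dq$y) + pseudo
  }
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' KLD convergence diagnostics between two runs
#'
#' For each window time `t`, compares the distributions of one PC mode's
#' projections accumulated over `[0, t]` in the two runs; the runs must be
#' projected on a common basis (fit the basis on the concatenated data).
#' Convergence time is the first `t` from which the divergence stays below
#' the threshold.
#'
#' @param proj_a,proj_b Projection matrices (frames x modes) of the two
#'   runs on the common basis.
#' @param mode PC mode index (default 1).
#' @param window_times Evaluation times as frame counts, or fractions of
#'   the shorter run when all values are <= 1.
#' @param threshold Convergence cutoff (default 0.025).
#' @param bins,pseudo,backend Passed to [kld_divergence()].
#' @return A `kld_series`: data.frame `time`, `kld` plus attributes
#'   `mode`, `threshold`, `converged_at` (`NA` if never sustained).
#' @export
kld_convergence <- function(proj_a, proj_b, mode = 1,
                            window_times = seq(0.1, 1, by = 0.1),
                            threshold = 0.025, bins = 100, pseudo = 1e-6,
                            backend = c("bin", "kde")) {
  backend <- match.arg(backend)
  a <- if (is.matrix(proj_a)) proj_a[, mode] else proj_a
  b <- if (is.matrix(proj_b)) proj_b[, mode] else proj_b
  nmin <- min(length(a), length(b))
  wt <- if (all(window_times <= 1)) pmax(2L, round(window_times * nmin))
        else as.integer(window_times)
  wt <- sort(unique(pmin(wt, nmin)))
  kld <- vapply(wt, function(n)
    kld_divergence(a[seq_len(n)], b[seq_len(n)], bins = bins,
                   pseudo = pseudo, backend = backend), 0)
  below <- kld < threshold
  conv <- NA_real_
  if (any(below)) {
    ## first index from which every later window stays below the cutoff
    sustained <- rev(cumprod(rev(below))) > 0
    if (any(sustained)) conv <- wt[which(sustained)[1]]
  }
  structure(data.frame(time = wt, kld = kld),
            class = c("kld_series", "data.frame"),
            mode = mode, threshold = threshold, converged_at = conv)
}

#' @export
print.kld_series <- function(x, ...) {
  cat("<kld_series> mode", attr(x, "mode"),
      "threshold", attr(x, "threshold"), "\n")
  print.data.frame(x)
  conv <- attr(x, "converged_at")
  cat(if (is.na(conv)) "  not converged\n"
      else sprintf("  converged at t = %g\n", conv))
  invisible(x)
}
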