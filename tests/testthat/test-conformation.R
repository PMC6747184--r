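test_that("torsion angles match constructions and the bio3d oracle", {
  ## planar all-trans: 180 degrees
  p <- four_point_torsion(180)
  expect_equal(abs(torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])), 180,
               tolerance = 1e-9)
  ## constructed +60 and a sweep, against construction and bio3d
  for (a in c(60, -60, 25.3, 145, -179)) {
    p <- four_point_torsion(a)
    expect_equal(torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]), a,
                 tolerance = 1e-6)
    expect_equal(torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4),
                 tolerance = 1e-6)
  }
})

test_that("dihedral extraction handles termini and broken residues", {
  xyz <- build_backbone(6)
  top <- bb_topology(6)
  dih <- compute_dihedrals(trajectory(xyz), top)
  expect_true(is.na(dih$phi[1, 1]))      # no preceding C
  expect_true(is.na(dih$psi[1, 6]))      # no following N
  expect_equal(dih$phi[1, 3], -57, tolerance = 1e-6)
  expect_equal(dih$psi[1, 3], -47, tolerance = 1e-6)
  ## remove one CA: flagged residue, not a failure
  top_b <- top[-(3 * 2 - 1), ]
  tr_b <- trajectory(xyz[-(3 * 2 - 1), , drop = FALSE])
  expect_warning(dih_b <- compute_dihedrals(tr_b, top_b), "incomplete")
  expect_true(all(is.na(dih_b$phi[, 2])))
})

test_that("dihedral PCA: degeneracy, trace identity, state separation", {
  ## constant input: all variance zero
  const <- matrix(50, nrow = 10, ncol = 6)
  pc0 <- dihedral_pca(const)
  expect_equal(sum(pc0$eigenvalues), 0)
  expect_equal(max(abs(pc0$projections)), 0)
  ## variance fractions sum to one over all modes
  set.seed(2)
  ang <- matrix(runif(600, -180, 180), 50, 12)
  pc <- dihedral_pca(ang)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))
  ## frame order irrelevance: same eigenvalues after shuffling frames
  pc_sh <- dihedral_pca(ang[sample(50), ])
  expect_equal(pc$eigenvalues, pc_sh$eigenvalues, tolerance = 1e-9)
  ## two-state helix: PC1 sign recovers the generator labels
  sys <- make_two_state_helix_trajectory(peptide_spec(p_bent = 0.5, seed = 23),
                                         n_frames = 600)
  m <- dihedral_pca(compute_dihedrals(sys$trajectory, sys$topology))
  lab <- m$projections[, 1] > 0
  truth <- sys$state == "bent"
  acc <- max(mean(lab == truth), mean(lab != truth))
  expect_gte(acc, 0.95)
})

test_that("2-D FEL reflects mixture populations", {
  sys <- make_two_state_helix_trajectory(peptide_spec(p_bent = 0.6, seed = 14),
                                         n_frames = 3000)
  m <- dihedral_pca(compute_dihedrals(sys$trajectory, sys$topology))
  fel <- fel_2d(m, bins = 40)
  expect_s3_class(fel, "fe_surface")
  expect_equal(fel$dims, 2)
  ## integrate probability on each side of PC1 = 0: matches p_bent
  side <- sign(m$projections[, 1])
  p_pos <- mean(side > 0)
  p_basin <- max(p_pos, 1 - p_pos)
  se <- sqrt(0.6 * 0.4 / 3000)
  expect_lt(abs(p_basin - 0.6), 4 * se)
  ## single state: a connected low-energy region only
  one <- make_two_state_helix_trajectory(peptide_spec(p_bent = 1, seed = 3),
                                         n_frames = 500)
  m1 <- dihedral_pca(compute_dihedrals(one$trajectory, one$topology))
  fel1 <- fel_2d(m1, bins = 20)
  expect_equal(sum(fel1$prob), 1, tolerance = 1e-12)
})

test_that("k-means clustering recovers well-separated states", {
  sys <- make_two_state_helix_trajectory(peptide_spec(p_bent = 0.5, seed = 29),
                                         n_frames = 800)
  m <- dihedral_pca(compute_dihedrals(sys$trajectory, sys$topology))
  cl <- cluster_conformations(m, 2, seed = 7)
  expect_equal(sum(cl$population), 1, tolerance = 1e-12)
  truth <- sys$state == "bent"
  agree <- max(mean((cl$labels == 1) == truth), mean((cl$labels == 2) == truth))
  expect_gte(agree, 0.99)
  ## representatives belong to their clusters
  expect_equal(cl$labels[cl$representative], 1:2)
  ## k = 1: representative is the frame nearest the global centroid
  cl1 <- cluster_conformations(m, 1, seed = 7)
  X <- m$projections[, 1:2]
  d2 <- rowSums(sweep(X, 2, colMeans(X))^2)
  expect_equal(cl1$representative, which.min(d2))
  expect_error(cluster_conformations(m, 10000), "frame count")
})

test_that("Kabsch superposition is exact, symmetric and matches a numeric oracle", {
  set.seed(5)
  A <- matrix(rnorm(36), 12, 3)
  expect_equal(superpose_rmsd(A, A), 0)
  rt <- random_rigid(8)
  expect_lt(superpose_rmsd(apply_rigid(A, rt), A), 1e-9)
  ## symmetry
  B <- A + matrix(rnorm(36, sd = 0.3), 12, 3)
  expect_equal(superpose_rmsd(A, B), superpose_rmsd(B, A), tolerance = 1e-9)
  ## displaced-atom construction vs exhaustive numeric minimisation
  C <- A
  C[1, ] <- C[1, ] + c(2, 0, 0)
  ana <- superpose_rmsd(C, A)
  ## numeric oracle: minimise RMSD over Euler angles on centred sets
  Ac <- sweep(A, 2, colMeans(A))
  Cc <- sweep(C, 2, colMeans(C))
  obj <- function(par) {
    R <- amdtk:::rotation_about_axis(c(0, 0, 1), par[1]) %*%
      amdtk:::rotation_about_axis(c(0, 1, 0), par[2]) %*%
      amdtk:::rotation_about_axis(c(1, 0, 0), par[3])
    sqrt(mean(rowSums((Cc %*% t(R) - Ac)^2)))
  }
  num <- min(vapply(1:20, function(i) {
    set.seed(i)
    stats::optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))$value
  }, 0))
  expect_lte(ana, num + 1e-6)             # analytic fit is the optimum
  expect_equal(ana, num, tolerance = 1e-2)
  expect_error(superpose_rmsd(A[1:2, ], A[1:2, ]), "3 atoms")
  ## cross-check against the bio3d implementation
  expect_equal(ana,
               bio3d::rmsd(as.numeric(t(A)), as.numeric(t(C)), fit = TRUE),
               tolerance = 1e-3)
})

test_that("KLD is zero on identity, non-negative, and matches the Gaussian closed form", {
  set.seed(13)
  x <- rnorm(5000)
  expect_equal(kld_divergence(x, x), 0, tolerance = 1e-12)
  ## 200 random histogram pairs
  for (i in 1:200) {
    a <- rnorm(300, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    b <- rnorm(300, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    expect_gte(kld_divergence(a, b), 0)
  }
  ## mu-offset = sigma: KLD -> 1/2
  a <- rnorm(1e5)
  b <- rnorm(1e5, 1)
  expect_equal(kld_divergence(a, b), 0.5, tolerance = 0.05)
  expect_equal(kld_divergence(a, b, backend = "kde"), 0.5, tolerance = 0.08)
})

test_that("bin and KDE backends agree on the convergence verdict", {
  set.seed(33)
  a <- matrix(rnorm(20000), ncol = 1)
  b <- matrix(rnorm(20000), ncol = 1)
  kb <- kld_convergence(a, b, threshold = 0.025)
  kk <- kld_convergence(a, b, threshold = 0.025, backend = "kde")
  expect_false(is.na(attr(kb, "converged_at")))
  expect_false(is.na(attr(kk, "converged_at")))
  ## diverging pair: neither backend converges
  c2 <- matrix(rnorm(20000, 5), ncol = 1)
  kb2 <- kld_convergence(a, c2, threshold = 0.025)
  kk2 <- kld_convergence(a, c2, threshold = 0.025, backend = "kde")
  expect_true(is.na(attr(kb2, "converged_at")))
  expect_true(is.na(attr(kk2, "converged_at")))
})

test_that("convergence time is the first sustained sub-threshold window", {
  ## synthetic KLD behaviour via engineered samples is indirect; check the
  ## flag logic on runs whose late windows agree but early ones do not
  set.seed(41)
  n <- 30000
  a <- rnorm(n)
  b <- c(rnorm(n / 3, 3), rnorm(2 * n / 3))   # early mismatch, late overlap
  ks <- kld_convergence(matrix(a, ncol = 1), matrix(b, ncol = 1),
                        window_times = seq(0.1, 1, 0.1), threshold = 0.025)
  conv <- attr(ks, "converged_at")
  if (!is.na(conv)) {
    after <- ks$kld[ks$time >= conv]
    expect_true(all(after < 0.025))
    before <- ks$kld[ks$time < conv]
    expect_gt(before[length(before)], 0.025)
  } else {
    expect_gt(ks$kld[nrow(ks)], 0.025)
  }
})
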