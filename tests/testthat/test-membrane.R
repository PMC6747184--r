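test_that("electron density: uniformity, additivity, and a two-slab step", {
  ## uniform ideal gas of identical atoms is flat within counting noise
  set.seed(6)
  n <- 400; nf <- 50
  box <- c(20, 20, 40)
  coords <- array(runif(n * 3 * nf, -0.5, 0.5), c(n, 3, nf))
  for (j in 1:3) coords[, j, ] <- coords[, j, ] * box[j]
  top <- topology(data.frame(name = "AR", element = "O",
                             resid = seq_len(n), resname = "GAS",
                             role = "gas", stringsAsFactors = FALSE))
  tr <- trajectory(coords, box = box)
  prof <- electron_density_profile(tr, top, bin_width = 2)
  expected <- n * 8 / prod(box)
  expect_equal(mean(prof$gas), expected, tolerance = 0.05)
  expect_lt(stats::sd(prof$gas) / mean(prof$gas), 0.15)
  ## integral over the box recovers the total electron count
  expect_equal(sum(prof$gas * 2) * box[1] * box[2], n * 8, tolerance = 1e-6)

  ## two-slab construction: occupied half vs empty half, plus additivity
  sp <- membrane_spec(seed = 5, n_lipids_leaflet = 6, n_water = 30)
  sys <- make_membrane_system(sp, n_frames = 5)
  p2 <- electron_density_profile(sys$trajectory, sys$topology)
  grp <- setdiff(names(p2), c("z", "total"))
  expect_equal(rowSums(as.matrix(p2[, grp])), p2$total, tolerance = 1e-12)

  slab <- array(0, c(50, 3, 2))
  slab[, 1, ] <- runif(100, -10, 10); slab[, 2, ] <- runif(100, -10, 10)
  slab[, 3, ] <- runif(100, 0, 10)   # atoms only in upper half
  tops <- topology(data.frame(name = "X", element = "C", resid = 1:50,
                              resname = "SLB", role = "slab",
                              stringsAsFactors = FALSE))
  ps <- electron_density_profile(trajectory(slab, box = c(20, 20, 20)),
                                 tops, bin_width = 2)
  expect_true(all(ps$slab[ps$z < -1] == 0))
  expect_true(all(ps$slab[ps$z > 1] > 0))
})

test_that("S_CD closed forms: perpendicular and magic-angle orientations", {
  ## build one 5-carbon straight chain along z with known C-H directions:
  ## all-trans zigzag in the xz-plane gives C-H vectors perpendicular to z
  ch <- amdtk:::zigzag_chain(6)
  top <- topology(data.frame(name = paste0("C", 1:6), element = "C",
                             resid = 1, resname = "LIP", role = "chain",
                             stringsAsFactors = FALSE))
  tr <- trajectory(ch, box = c(50, 50, 50))
  prof <- scd_profile(tr, top)
  ## chain axis along z: theta = 90 deg, S_CD = -0.5, magnitude 0.5
  expect_equal(prof$scd, rep(-0.5, nrow(prof)), tolerance = 1e-10)
  expect_equal(prof$abs_scd, rep(0.5, nrow(prof)), tolerance = 1e-10)
  ## chain tilted to the magic angle with the zigzag plane spun uniformly
  ## about the chain axis: <P2> factorises to P2(cos magic) = 0
  magic <- acos(1 / sqrt(3))
  frames <- lapply(seq(0, 2 * pi, length.out = 73)[-73], function(ph) {
    R <- amdtk:::rotation_about_axis(c(0, 1, 0), magic) %*%
      amdtk:::rotation_about_axis(c(0, 0, 1), ph)
    ch %*% t(R)
  })
  arr <- array(unlist(frames), c(6, 3, length(frames)))
  prof_m <- scd_profile(trajectory(arr, box = c(50, 50, 50)), top)
  expect_lt(max(abs(prof_m$scd)), 1e-3)
})

test_that("generator-tuned order parameter is recovered per carbon", {
  sp <- membrane_spec(target_scd = 0.16, n_lipids_leaflet = 32, n_water = 0,
                      pore_radius = 0, seed = 19)
  sys <- make_membrane_system(sp, n_frames = 300)
  prof <- scd_profile(sys$trajectory, sys$topology)
  expect_true(all(abs(prof$abs_scd - 0.16) < 0.01))
  expect_true(all(prof$scd < 0))   # acyl convention: signed value negative
})

test_that("MSD flags ballistic motion and recovers Brownian D", {
  ## ballistic: x = v t
  nf <- 200
  coords <- array(0, c(5, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(0.05 * f, 5, 3)
  tr <- trajectory(coords, time = seq_len(nf), box = c(1e4, 1e4, 1e4))
  mb <- msd_diffusion(tr, 1:5, dims = 3)
  expect_true(attr(mb, "ballistic"))

  ## Brownian walk: D recovered within 10%, N = 1 consistent with N = 3
  sp <- membrane_spec(n_lipids_leaflet = 0, pore_radius = 0, n_water = 60,
                      D_water = 0.03, seed = 44)
  sys <- make_membrane_system(sp, n_frames = 5000, dt = 1)
  m3 <- msd_diffusion(sys$trajectory, "water", dims = 3, top = sys$topology)
  expect_false(attr(m3, "ballistic"))
  expect_equal(attr(m3, "D_raw"), 0.03, tolerance = 0.1)
  ## paper-style conversion: D = slope * 10/(2N) in 1e-5 cm^2/s
  expect_equal(attr(m3, "D"), 10 * attr(m3, "D_raw"), tolerance = 1e-12)
  m1 <- msd_diffusion(sys$trajectory, "water", dims = 1, top = sys$topology)
  expect_equal(attr(m1, "D_raw"), attr(m3, "D_raw"), tolerance = 0.15)
  ## MSD starts at zero lag ~ small and is non-negative
  expect_true(all(m3$msd >= 0))

  ## wrapped coordinates are rejected with an unwrap hint
  wrapped <- sys$trajectory
  wrapped$coords[1, 1, 10] <- wrapped$coords[1, 1, 9] + 40
  wrapped$box <- matrix(rep(c(60, 60, 70), each = 5000), 5000, 3)
  expect_error(msd_diffusion(wrapped, "water", top = sys$topology), "unwrap")
})

test_that("water grid density conserves counts and localises a static water", {
  ## single static water: one voxel of value 1
  coords <- array(c(3.2, -1.4, 0.7), c(1, 3, 4))
  top <- topology(data.frame(name = "OW", element = "O", resid = 1,
                             resname = "WAT", role = "water",
                             stringsAsFactors = FALSE))
  g <- water_grid_density(trajectory(coords, box = c(20, 20, 20)), top)
  expect_equal(sum(g$grid), 1)
  expect_equal(sum(g$grid > 0), 1)
  expect_equal(max(g$grid), 1)
  expect_error(water_grid_density(trajectory(coords, box = c(20, 20, 20)),
                                  top, spacing = 0), "positive")

  ## pore system: grid mass concentrates inside the pore radius
  sp <- membrane_spec(n_lipids_leaflet = 0, n_water = 150, pore_radius = 11,
                      D_water = 0, seed = 3, box = c(40, 40, 40),
                      pore_length = 30)
  sys <- make_membrane_system(sp, n_frames = 2)
  ## move all waters onto the pore axis region
  widx <- which(sys$topology$role == "water")
  set.seed(10)
  for (f in 1:2) {
    sys$trajectory$coords[widx, 1, f] <- runif(150, -5, 5)
    sys$trajectory$coords[widx, 2, f] <- runif(150, -5, 5)
    sys$trajectory$coords[widx, 3, f] <- runif(150, -14, 14)
  }
  g2 <- water_grid_density(sys$trajectory, sys$topology)
  expect_equal(sum(g2$grid), 150, tolerance = 1e-9)
  cx <- g2$origin[1] + (seq_len(dim(g2$grid)[1]) - 0.5) * g2$spacing
  cy <- g2$origin[2] + (seq_len(dim(g2$grid)[2]) - 0.5) * g2$spacing
  rad <- sqrt(outer(cx^2, cy^2, `+`))
  inside <- array(rep(rad <= 11, dim(g2$grid)[3]), dim(g2$grid))
  expect_equal(sum(g2$grid[inside]), 150, tolerance = 1e-9)
})

test_that("pore water count equals brute force and is isometry-invariant", {
  sp <- membrane_spec(n_lipids_leaflet = 0, n_water = 20, pore_radius = 11,
                      D_water = 0.5, seed = 27, box = c(40, 40, 40))
  sys <- make_membrane_system(sp, n_frames = 4)
  ## place 7 of the 20 waters just inside the shell of frame 1
  widx <- which(sys$topology$role == "water")
  pidx <- which(sys$topology$role == "pore")
  for (i in 1:7)
    sys$trajectory$coords[widx[i], , 1] <-
      sys$trajectory$coords[pidx[i * 3], , 1] + c(1.5, 0, 0)
  for (i in 8:20)
    sys$trajectory$coords[widx[i], , 1] <- c(0, 0, 100 + i)
  cnt <- pore_water_count(sys$trajectory, sys$topology)
  expect_equal(cnt[1], 7L)
  expect_equal(cnt, brute_force_shell_count(sys$trajectory, sys$topology))
  ## rigid rotation of every frame leaves counts unchanged
  rt <- random_rigid(15)
  cnt_rot <- pore_water_count(transform_trajectory(sys$trajectory, rt),
                              sys$topology)
  expect_equal(cnt_rot, cnt)
  expect_error(pore_water_count(sys$trajectory, sys$topology,
                                pore_selection = "nonexistent"), "no atoms")
})

test_that("pore radius profile matches the cylinder geometry", {
  sp <- membrane_spec(n_lipids_leaflet = 0, n_water = 0, pore_radius = 11,
                      pore_vdw = 1.5, seed = 1)
  sys <- make_membrane_system(sp, n_frames = 2)
  pr <- pore_radius_profile(sys$trajectory, sys$topology)
  mid <- which.min(abs(pr$z))
  expect_equal(pr$radius[mid], 9.5, tolerance = 0.25)   # grid resolution
  expect_false(any(pr$capped[abs(pr$z) < 10]))
  ## doubling the wall vdW radius shrinks the lumen by the same amount
  top2 <- sys$topology
  top2$vdw[top2$role == "pore"] <- 3.0
  pr2 <- pore_radius_profile(sys$trajectory, top2)
  expect_equal(pr$radius[mid] - pr2$radius[mid], 1.5, tolerance = 1e-9)
  ## funnel: radius grows monotonically along the widening section
  zs <- seq(-12, 12, by = 1.5)
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  wall <- do.call(rbind, lapply(zs, function(z) {
    r <- 6 + (z + 12) * 0.4
    cbind(r * cos(ang), r * sin(ang), z)
  }))
  ftop <- topology(data.frame(name = "PW", element = "C",
                              resid = seq_len(nrow(wall)), resname = "POR",
                              role = "pore", stringsAsFactors = FALSE))
  ftop$vdw <- 1.5
  ftr <- trajectory(wall, box = c(60, 60, 60))
  pf <- pore_radius_profile(ftr, ftop, z_step = 3)
  interior <- pf$z > -10 & pf$z < 10
  expect_true(all(diff(pf$radius[interior]) > 0))
})

test_that("helicity percentages follow the dihedral window", {
  ## ideal helix: interior residues 100% helical
  xyz <- build_backbone(12)
  dih <- compute_dihedrals(trajectory(xyz), bb_topology(12))
  hel <- percent_helicity(dih)
  expect_equal(as.numeric(hel), 100)
  ## all-extended chain: 0%
  ext <- build_backbone(12, phi = -140, psi = 140)
  dih_e <- compute_dihedrals(trajectory(ext), bb_topology(12))
  expect_equal(as.numeric(percent_helicity(dih_e)), 0)
  ## 50/50 frame mixture averages to ~50%
  arr <- array(NA_real_, c(36, 3, 40))
  for (f in 1:40) arr[, , f] <- if (f %% 2) xyz else ext
  dih_m <- compute_dihedrals(trajectory(arr), bb_topology(12))
  expect_equal(mean(percent_helicity(dih_m)), 50, tolerance = 1e-9)
  ## per-monomer split
  map <- rep(1:2, each = 6)
  hel2 <- percent_helicity(dih_m, monomer_map = map)
  expect_equal(ncol(hel2), 2)
})

test_that("bend angle: straight helix ~180, right angle construction, isometry", {
  sys <- make_two_state_helix_trajectory(
    peptide_spec(p_bent = 0, noise = 0, seed = 1), n_frames = 2)
  ba <- bend_angle(sys$trajectory, sys$topology)
  expect_gt(min(ba), 170)
  ## two straight arms at 90 degrees: residue "centres" on a right angle
  n <- 16
  com <- rbind(cbind(seq(8, 1), 0, 0), cbind(0, seq(1, 8), 0))
  arr <- array(t(com), c(3, n, 1))
  arr <- aperm(arr, c(2, 1, 3))
  topL <- topology(data.frame(name = "CA", element = "C", resid = 1:n,
                              resname = "ALA", role = "peptide",
                              stringsAsFactors = FALSE))
  ba90 <- bend_angle(trajectory(arr), topL,
                     n_term_residues = 1:5, c_term_residues = 12:16)
  expect_equal(as.numeric(ba90), 90, tolerance = 1)
  ## rigid rotation invariance
  rt <- random_rigid(3)
  ba_rot <- bend_angle(transform_trajectory(sys$trajectory, rt), sys$topology)
  expect_equal(ba_rot, ba, tolerance = 1e-6)
  ## collinear degenerate window: flagged NA, not an error
  degenerate <- array(0, c(3, 3, 1))
  topD <- topology(data.frame(name = "CA", element = "C", resid = 1:3,
                              resname = "ALA", role = "peptide",
                              stringsAsFactors = FALSE))
  baD <- bend_angle(trajectory(degenerate), topD,
                    n_term_residues = 1:2, c_term_residues = 2:3)
  expect_true(is.na(baD[1, 1]))
})

test_that("field conversions reproduce the printed equivalences", {
  ## 70 mV across 3.5 nm
  f1 <- field_convert(potential_V = 0.07, thickness_nm = 3.5)
  expect_equal(f1$field_V_per_nm, 0.02)
  ## efz = 0.080 kcal/(mol A e) -> 0.03 V/nm at two decimals
  f2 <- field_convert(efz = 0.080)
  expect_equal(round(f2$field_V_per_nm, 2), 0.03)
  ## zero field
  expect_equal(field_convert(efz = 0)$field_V_per_nm, 0)
  ## round trip: efz -> field -> efz
  f3 <- field_convert(potential_V = f2$field_V_per_nm * 3.5,
                      thickness_nm = 3.5)
  expect_equal(f3$efz, 0.080, tolerance = 1e-9)
  expect_error(field_convert(potential_V = 1, thickness_nm = 0), "nonzero")
  expect_error(field_convert(), "give either")
})
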