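# brute-force check that a VOI sphere is fully in-muscle and vessel-free
voi_is_clean <- function(voi, atlas) {
  lab <- atlas$muscles$label[atlas$muscles$muscle == voi$muscle &
                               atlas$muscles$side == voi$side]
  vox <- sphere_voxels(c(voi$x, voi$y, voi$z), voi$diameter_mm,
                       atlas$shape, atlas$spacing)
  all(atlas$labels[vox$lin] == lab) && !any(atlas$vessel[vox$lin])
}

test_that("the fixed VOI sits on the mid-bone plane at the cross-section centroid", {
  atlas <- test_atlas()
  # hamstrings have no internal vessel: centroid is feasible unadjusted
  v <- place_fixed_voi(atlas, "hamstrings", "L")
  lm <- atlas$landmarks[atlas$landmarks$muscle == "hamstrings" &
                          atlas$landmarks$side == "L", ]
  mid_z <- (lm$prox_z + lm$dist_z) / 2
  expect_lte(abs(v$z - mid_z), atlas$spacing)
  expect_false(v$adjusted)
  expect_true(voi_is_clean(v, atlas))
  # the deltoid plane sits 10% from the proximal humerus end
  vd <- place_fixed_voi(atlas, "deltoid", "R")
  target_z <- lm2 <- atlas$landmarks[atlas$landmarks$muscle == "deltoid" &
                                       atlas$landmarks$side == "R", ]
  target_z <- lm2$prox_z + 0.1 * (lm2$dist_z - lm2$prox_z)
  expect_lte(abs(vd$z - target_z), atlas$spacing)
  # the psoas plane passes through the lumbosacral landmark
  vp <- place_fixed_voi(atlas, "psoas", "L")
  lmp <- atlas$landmarks[atlas$landmarks$muscle == "psoas" &
                           atlas$landmarks$side == "L", ]
  expect_lte(abs(vp$z - lmp$point_z), atlas$spacing)
})

test_that("a vessel through the centroid pushes the fixed VOI the minimal clean distance", {
  atlas <- test_atlas()
  # the quadriceps carry a carved femoral rod near the cross-section centroid
  v <- place_fixed_voi(atlas, "quadriceps", "L")
  expect_true(v$adjusted)
  expect_true(voi_is_clean(v, atlas))
  # brute-force: no feasible center in the axial band is closer to the centroid
  lab <- atlas$muscles$label[atlas$muscles$muscle == "quadriceps" &
                               atlas$muscles$side == "L"]
  lm <- atlas$landmarks[atlas$landmarks$label == lab, ]
  mid_z <- (lm$prox_z + lm$dist_z) / 2
  lin <- which(atlas$labels == lab)
  ijk <- arrayInd(lin, atlas$shape)
  xyz <- (ijk - 0.5) * atlas$spacing
  slab <- abs(xyz[, 3] - mid_z) <= atlas$spacing / 2 + 1e-9
  centroid <- colMeans(xyz[slab, , drop = FALSE])
  chosen_d <- sum((c(v$x, v$y, v$z) - centroid)^2)
  for (r in which(abs(xyz[, 3] - mid_z) <= 0.1 * abs(lm$prox_z - lm$dist_z))) {
    cand <- xyz[r, ]
    d <- sum((cand - centroid)^2)
    if (d < chosen_d - 1e-9) {
      vox <- sphere_voxels(cand, v$diameter_mm, atlas$shape, atlas$spacing)
      clean <- all(atlas$labels[vox$lin] == lab) && !any(atlas$vessel[vox$lin])
      expect_false(clean)
    }
  }
})

test_that("hotspot placement recovers a noiseless focus to within one voxel", {
  atlas <- test_atlas()
  for (seed in 1:3) {
    ph <- hetero_phantom(atlas, seed, fwhm_mm = 6)
    s <- to_suv(ph)
    gt <- ph$ground_truth
    for (m in c("quadriceps", "psoas", "biceps")) {
      row <- which(gt$muscle == m & gt$side == "R")
      if (gt$true_pattern[row] != "unifocal") next
      v <- place_hotspot_voi(s, atlas, m, "R")
      ctr <- gt$centers[[row]][1, ]
      err <- sqrt(sum((c(v$x, v$y, v$z) - ctr)^2))
      expect_lte(err, atlas$spacing + 1e-9)
      expect_true(voi_is_clean(v, atlas))
    }
  }
})

test_that("a uniform muscle yields identical fixed and hotspot statistics", {
  atlas <- test_atlas()
  ph <- generate_phantom(atlas, subject_params(), pattern_spec("homogeneous"),
                         fwhm_mm = 0, noise_coef = 0, seed = 5)
  s <- to_suv(ph)
  for (m in c("hamstrings", "triceps")) {
    vf <- place_fixed_voi(atlas, m, "L")
    vh <- place_hotspot_voi(s, atlas, m, "L")
    sf <- suv_stats(s, c(vf$x, vf$y, vf$z), vf$diameter_mm)
    sh <- suv_stats(s, c(vh$x, vh$y, vh$z), vh$diameter_mm)
    expect_equal(sh$suv_max, sf$suv_max)
    expect_equal(sh$suv_mean, sf$suv_mean)
    expect_equal(sh$suv_peak, sf$suv_peak)
  }
})

test_that("consecutive-slice confirmation accepts plateaus and rejects spikes", {
  atlas <- test_atlas()
  lab <- atlas$muscles$label[atlas$muscles$muscle == "hamstrings" &
                               atlas$muscles$side == "L"]
  lin <- which(atlas$labels == lab)
  ijk <- arrayInd(lin, atlas$shape)
  base <- array(0, atlas$shape)
  base[lin] <- 1
  s_const <- as_suv(base, atlas$spacing)
  interior <- ijk[ijk[, 3] > min(ijk[, 3]) + 2 & ijk[, 3] < max(ijk[, 3]) - 2, ]
  cand <- interior[which.min(rowSums(sweep(interior, 2, colMeans(interior))^2)), ]
  expect_true(confirm_candidate(s_const, cand, atlas, "hamstrings", "L"))
  # isolated single-slice spike: rejected at tau = 0.8
  spike <- base
  spike[cand[1], cand[2], cand[3]] <- 50
  expect_false(confirm_candidate(as_suv(spike, atlas$spacing), cand,
                                 atlas, "hamstrings", "L"))
  # plateau spanning 5 slices: confirmed at its center
  plateau <- base
  sel <- abs(ijk[, 3] - cand[3]) <= 2 &
    (ijk[, 1] - cand[1])^2 + (ijk[, 2] - cand[2])^2 <= 4
  plateau[lin[sel]] <- 5
  expect_true(confirm_candidate(as_suv(plateau, atlas$spacing), cand,
                                atlas, "hamstrings", "L"))
})

test_that("a single-slice spike loses the hotspot to a broader confirmed focus", {
  atlas <- test_atlas()
  lab <- atlas$muscles$label[atlas$muscles$muscle == "hamstrings" &
                               atlas$muscles$side == "R"]
  lin <- which(atlas$labels == lab)
  ijk <- arrayInd(lin, atlas$shape)
  a <- array(0, atlas$shape)
  a[lin] <- 1
  zs <- sort(unique(ijk[, 3]))
  mid_xy <- round(colMeans(ijk[, 1:2, drop = FALSE]))
  # broad focus: 5-slice plateau of value 3 low in the muscle
  z_focus <- zs[8]
  sel <- abs(ijk[, 3] - z_focus) <= 2 &
    (ijk[, 1] - mid_xy[1])^2 + (ijk[, 2] - mid_xy[2])^2 <= 9
  a[lin[sel]] <- 3
  # hotter but single-slice artifact high in the muscle
  z_spike <- zs[30]
  spike_sel <- ijk[, 3] == z_spike &
    (ijk[, 1] - mid_xy[1])^2 + (ijk[, 2] - mid_xy[2])^2 <= 1
  a[lin[spike_sel]] <- 6
  v <- place_hotspot_voi(as_suv(a, atlas$spacing), atlas, "hamstrings", "R")
  expect_lte(abs(v$z - (z_focus - 0.5) * atlas$spacing), 3 * atlas$spacing)
  expect_gt(abs(v$z - (z_spike - 0.5) * atlas$spacing), 5 * atlas$spacing)
})

test_that("hotspot placement is deterministic", {
  atlas <- test_atlas()
  ph <- hetero_phantom(atlas, 17)
  s <- to_suv(ph)
  v1 <- place_hotspot_voi(s, atlas, "quadriceps", "L")
  v2 <- place_hotspot_voi(s, atlas, "quadriceps", "L")
  expect_identical(v1, v2)
})
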