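test_that("SUV conversion follows C * W / D and validates inputs", {
  v <- array(5, c(2, 2, 2))
  expect_equal(to_suv(v, dose_mbq = 350, weight_kg = 70, spacing = 4)$data,
               array(1, c(2, 2, 2)))
  expect_equal(to_suv(array(0, c(2, 2, 2)), 100, 70)$data, array(0, c(2, 2, 2)))
  expect_equal(to_suv(array(3.2, c(1, 1, 1)), 320, 80)$data[1], 0.8)
  expect_error(to_suv(v, 0, 70), "dose_mbq")
  expect_error(to_suv(v, 350, -1), "weight_kg")
})

test_that("SUV conversion is linear in activity and weight, inverse in dose", {
  withr::with_seed(7, {
    v <- array(runif(27, 0, 10), c(3, 3, 3))
    base <- to_suv(v, 300, 70)$data
    expect_equal(to_suv(3 * v, 300, 70)$data, 3 * base)
    expect_equal(to_suv(v, 300, 140)$data, 2 * base)
    expect_equal(to_suv(v, 600, 70)$data, base / 2)
  })
})

test_that("sphere membership is by voxel center, inclusive at the boundary", {
  shape <- c(9, 9, 9); sp <- 4
  ctr <- c(4.5, 4.5, 4.5) * sp # voxel (5,5,5) center is at 18 = 4.5*4
  ctr <- c(18, 18, 18)
  # diameter below the voxel pitch: just the center voxel
  one <- sphere_voxels(ctr, 3, shape, sp)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$i, one$j, one$k), c(5L, 5L, 5L))
  # 8 mm diameter on a 4 mm grid: center + 6 face neighbours
  seven <- sphere_voxels(ctr, 8, shape, sp)
  expect_equal(nrow(seven), 7L)
  expect_true(all(abs(seven$i - 5) + abs(seven$j - 5) + abs(seven$k - 5) <= 1))
  # translation equivariance by one voxel
  shifted <- sphere_voxels(ctr + c(sp, 0, 0), 8, shape, sp)
  expect_equal(shifted$i, seven$i + 1L)
  expect_equal(shifted$j, seven$j)
  expect_equal(shifted$k, seven$k)
  expect_error(sphere_voxels(c(-100, -100, -100), 8, shape, sp), "outside")
})

# independent brute-force oracle for the peak-sphere statistic
brute_peak <- function(a, sp, center, diameter, d_peak) {
  shape <- dim(a)
  cords <- as.matrix(expand.grid(i = 1:shape[1], j = 1:shape[2], k = 1:shape[3]))
  xyz <- (cords - 0.5) * sp
  d2c <- rowSums((xyz - matrix(center, nrow(xyz), 3, byrow = TRUE))^2)
  voi <- d2c <= (diameter / 2)^2 + 1e-9
  in_voi <- function(ijk) {
    if (any(ijk < 1L) || any(ijk > shape)) return(FALSE)
    voi[ijk[1] + (ijk[2] - 1) * shape[1] + (ijk[3] - 1) * shape[1] * shape[2]]
  }
  m <- ceiling(d_peak / 2 / sp)
  offs <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  offs <- offs[rowSums(offs^2) * sp^2 <= (d_peak / 2)^2 + 1e-9, , drop = FALSE]
  best <- -Inf; found <- FALSE
  for (v in which(voi)) {
    nb <- sweep(offs, 2, cords[v, ], `+`)
    if (all(apply(nb, 1, in_voi))) { # peak sphere entirely inside the VOI
      found <- TRUE
      best <- max(best, mean(a[nb]))
    }
  }
  if (found) best else {
    nb <- d2c <= (d_peak / 2)^2 + 1e-9
    mean(a[cords[voi & nb, , drop = FALSE]])
  }
}

test_that("suv_stats matches a brute-force enumeration oracle", {
  # the worked 3x3x3 case: hot center voxel, whole-grid VOI, 8 mm kernel
  a <- array(1, c(3, 3, 3)); a[2, 2, 2] <- 2
  s <- as_suv(a)
  st <- suv_stats(s, c(6, 6, 6), diameter = 24, d_peak = 8)
  expect_equal(st$suv_max, 2)
  expect_equal(st$n_vox, 27L)
  expect_equal(st$suv_peak, brute_peak(a, 4, c(6, 6, 6), 24, 8))
  expect_equal(st$suv_peak, 8 / 7)
  # randomized fields and VOIs
  withr::with_seed(42, {
    for (rep in 1:8) {
      a <- array(runif(7^3, 0, 4), c(7, 7, 7))
      s <- as_suv(a)
      ctr <- runif(3, 8, 20)
      dia <- sample(c(8, 12, 16, 20), 1)
      dpk <- sample(c(4, 8, 12), 1)
      st <- suv_stats(s, ctr, dia, d_peak = dpk)
      expect_equal(st$suv_peak, brute_peak(a, 4, ctr, dia, dpk), tolerance = 1e-12)
      expect_lte(st$suv_peak, st$suv_max + 1e-12)
    }
  })
})

test_that("degenerate peak kernels reduce to suv_max and constants are exact", {
  a <- array(2.5, c(4, 4, 4))
  s <- as_suv(a)
  st <- suv_stats(s, c(8, 8, 8), diameter = 10, d_peak = 1e-6)
  expect_equal(st$suv_max, 2.5)
  expect_equal(st$suv_mean, 2.5)
  expect_equal(st$suv_peak, 2.5)
  st12 <- suv_stats(s, c(8, 8, 8), diameter = 12, d_peak = 12)
  expect_equal(st12$suv_peak, 2.5)
})

test_that("suv_peak is non-increasing in the kernel diameter on a focal field", {
  atlas <- test_atlas()
  ph <- generate_phantom(
    atlas, subject_params(),
    pattern_spec("unifocal", radius_mm = 15,
                 clearance_mm = 10),
    fwhm_mm = 0, noise_coef = 0, seed = 3
  )
  s <- to_suv(ph)
  gt <- ph$ground_truth
  row <- which(gt$muscle == "quadriceps" & gt$side == "L")
  ctr <- gt$centers[[row]][1, ]
  peaks <- vapply(c(1e-6, 4, 8, 12, 16), function(dp) {
    suv_stats(s, ctr, diameter = 20, d_peak = dp)$suv_peak
  }, 1.0)
  expect_true(all(diff(peaks) <= 1e-9))
})
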