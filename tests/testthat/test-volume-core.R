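test_that("voxel grid maps indices and world coordinates both ways", {
  g <- voxel_grid(c(10, 12, 14), 0.5, origin_mm = c(1, 2, 3))
  p <- index_to_world(g, c(1, 1, 1))
  expect_equal(as.numeric(p), c(1, 2, 3))
  idx <- world_to_index(g, c(1.5, 2.5, 3.5))
  expect_equal(as.numeric(idx), c(2, 2, 2))
  expect_error(voxel_grid(c(4, 4, 4), -1), "positive")
})

test_that("resampling preserves identity, world volume, and round-trips", {
  g <- voxel_grid(c(60, 60, 60), 0.5)
  co <- mastoidplan:::grid_coords(g)
  cube <- binary_mask(g, co$x >= 5 & co$x <= 24.5 & co$y >= 5 &
                        co$y <= 24.5 & co$z >= 5 & co$z <= 24.5)
  expect_identical(resample_isotropic(cube, 0.5)$occupancy, cube$occupancy)
  expect_error(resample_isotropic(cube, 0), "positive")
  # analytic cube volume (20.5 mm edge of voxel centers spans ~21^3 voxels)
  down <- resample_isotropic(cube, 1.0)
  expect_lt(abs(mask_volume_mm3(down) - mask_volume_mm3(cube)) /
              mask_volume_mm3(cube), 0.05)
  # refine then coarsen recovers the original occupancy exactly
  fine <- resample_isotropic(cube, 0.25)
  back <- resample_isotropic(fine, 0.5)
  expect_identical(dim(back$occupancy), dim(cube$occupancy))
  expect_identical(back$occupancy, cube$occupancy)
})

test_that("scalar fields resample by trilinear interpolation", {
  g <- voxel_grid(c(21, 21, 21), 1)
  co <- mastoidplan:::grid_coords(g)
  f <- sdf_field(g, 2 * co$x + 3 * co$y - co$z) # linear: trilinear is exact
  out <- resample_isotropic(f, 0.5)
  co2 <- mastoidplan:::grid_coords(out$grid)
  expect_equal(out$values, 2 * co2$x + 3 * co2$y - co2$z, tolerance = 1e-12)
})

test_that("signed distance fields match the brute-force surface oracle", {
  set.seed(42)
  for (rep in 1:3) {
    g <- voxel_grid(c(20, 20, 20), 0.5)
    occ <- array(runif(20^3) < 0.15, dim = c(20, 20, 20))
    occ[1, 1, 1] <- TRUE # never empty
    m <- binary_mask(g, occ)
    sdf <- compute_sdf(m)
    bf <- brute_force_surface_distance(occ, 0.5)
    half_diag <- sqrt(3) * 0.5 / 2
    expect_lte(max(abs(abs(sdf$values) - bf)), half_diag + 1e-12)
    expect_true(all(sdf$values[occ] < 0))
    expect_true(all(sdf$values[!occ] > 0))
  }
})

test_that("SDF handles the unit-voxel and solid-ball anchor cases", {
  g <- voxel_grid(c(9, 9, 9), 1)
  occ <- array(FALSE, dim = c(9, 9, 9))
  occ[5, 5, 5] <- TRUE
  sdf <- compute_sdf(binary_mask(g, occ))
  expect_lt(abs(sdf$values[6, 5, 5] - 1), sqrt(3) / 2)
  expect_error(compute_sdf(binary_mask(g, array(FALSE, dim = c(9, 9, 9)))),
               "no surface")
  expect_error(compute_sdf(binary_mask(g, array(TRUE, dim = c(9, 9, 9)))),
               "no surface")
  b <- ball_mask(n = 25L, radius = 9)
  sdfb <- compute_sdf(b)
  center <- sdfb$values[13, 13, 13]
  expect_lt(abs(center - (-9)), 1)
})

test_that("the SDF satisfies the eikonal property away from the boundary", {
  b <- ball_mask(n = 31L, radius = 11)
  sdf <- compute_sdf(b)
  v <- sdf$values
  d <- dim(v)
  ix <- 3:(d[1] - 2)
  gx <- (v[ix + 1, ix, ix] - v[ix - 1, ix, ix]) / 2
  gy <- (v[ix, ix + 1, ix] - v[ix, ix - 1, ix]) / 2
  gz <- (v[ix, ix, ix + 1] - v[ix, ix, ix - 1]) / 2
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  far <- abs(v[ix, ix, ix]) > 2
  frac <- mean(gm[far] >= 0.8 & gm[far] <= 1.2)
  expect_gte(frac, 0.95)
})

test_that("segment SDF minima respect bounds, sign, and closed forms", {
  ph <- generate_phantom(phantom_spec())
  fn <- ph$structures[[1]] # straight tube radius 1.5 along S at (28, 14)
  # parallel segment at axis offset b: expect b - a
  d <- sdf_min_along_segment(fn$sdf, c(28, 24, 20), c(28, 24, 40))
  expect_lt(abs(d - (10 - 1.5)), 0.5)
  # far segment: all SDF values > 10 along a distant line
  far <- sdf_min_along_segment(fn$sdf, c(10, 45, 20), c(10, 45, 40))
  expect_gt(far, 10)
  # piercing segment: negative minimum
  pierce <- sdf_min_along_segment(fn$sdf, c(28, 5, 30), c(28, 25, 30))
  expect_lt(pierce, 0)
  expect_error(sdf_min_along_segment(fn$sdf, c(1, 1, 1), c(1, 1, 1)),
               "distinct")
  expect_error(sdf_min_along_segment(fn$sdf, c(-5, 30, 30), c(30, 30, 30)),
               "outside")
})

test_that("landmark rigid alignment recovers transforms and fixes reflections", {
  set.seed(7)
  pts <- matrix(runif(15, 0, 50), 5, 3)
  lm <- landmark_set(letters[1:5], pts)
  id <- rigid_align_landmarks(lm, lm)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_lt(id$rmse_mm, 1e-10)
  # known rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  R <- R2 %*% R
  b <- c(4, -2, 7)
  moved <- landmark_set(letters[1:5], sweep(pts %*% t(R), 2, b, "+"))
  fit <- rigid_align_landmarks(lm, moved)
  expect_lt(fit$rmse_mm, 1e-6)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  # composing with the inverse gives the identity
  inv <- invert_rigid(fit)
  round_trip <- apply_rigid(inv, apply_rigid(fit, pts))
  expect_equal(round_trip, pts, tolerance = 1e-9)
  # mirrored destination still yields a proper rotation
  mirrored <- landmark_set(letters[1:5], cbind(-pts[, 1], pts[, 2:3]))
  ref <- rigid_align_landmarks(lm, mirrored)
  expect_equal(det(ref$rotation), 1, tolerance = 1e-9)
  expect_error(rigid_align_landmarks(landmark_set("a", c(0, 0, 0)), lm),
               "at least 3")
  line <- landmark_set(letters[1:4], cbind(1:4, 2 * (1:4), 3 * (1:4)))
  expect_error(rigid_align_landmarks(line, line), "collinear")
})

test_that("NIfTI round trip preserves grid geometry and occupancy", {
  b <- ball_mask(n = 15L, spacing = 0.5, radius = 3)
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(b, f)
  back <- read_volume_nifti(f, "mask")
  expect_identical(back$occupancy, b$occupancy)
  expect_equal(back$grid$spacing_mm, 0.5, tolerance = 1e-6)
  expect_equal(back$grid$origin_mm, b$grid$origin_mm, tolerance = 1e-6)
  unlink(f)
})

test_that("landmark CSV round trip", {
  lm <- landmark_set(c("apex", "foramen", "ganglion"),
                     matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE))
  f <- tempfile(fileext = ".csv")
  write_landmarks_csv(lm, f)
  back <- read_landmarks_csv(f)
  expect_equal(back$names, lm$names)
  expect_equal(back$points_mm, lm$points_mm)
  unlink(f)
})
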