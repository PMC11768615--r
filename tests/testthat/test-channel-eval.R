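test_that("the surgical channel joins exterior, mill, and reachable cavities", {
  g <- voxel_grid(c(21, 21, 21), 1)
  co <- mastoidplan:::grid_coords(g)
  head <- binary_mask(g, co$x <= 15)
  bone <- binary_mask(g, co$x >= 10 & co$x <= 15) # full-width slab
  empty <- binary_mask(g, array(FALSE, dim = g$shape))
  # no breach: channel is the exterior only
  ch0 <- build_channel(empty, bone, head)
  expect_identical(ch0$channel$occupancy, ch0$external$occupancy)
  expect_equal(sum(ch0$internal$occupancy), 0)
  # full-thickness hole: the interior cavity joins the channel
  hole <- binary_mask(g, co$x >= 10 & co$x <= 15 &
                        abs(co$y - 10) <= 2 & abs(co$z - 10) <= 2)
  ch1 <- build_channel(hole, bone, head)
  expect_gt(sum(ch1$internal$occupancy), 0)
  interior <- co$x < 10
  expect_true(all(ch1$channel$occupancy[interior]))
  # components are pairwise disjoint and union to the channel
  expect_false(any(ch1$mill$occupancy & ch1$internal$occupancy))
  expect_false(any(ch1$mill$occupancy & ch1$external$occupancy))
  expect_false(any(ch1$internal$occupancy & ch1$external$occupancy))
  expect_identical(ch1$channel$occupancy,
                   ch1$mill$occupancy | ch1$internal$occupancy |
                     ch1$external$occupancy)
  # a sealed-off cavity stays out of the channel
  bone2occ <- (co$x >= 10 & co$x <= 15) |
    (abs(co$x - 5) <= 2 & abs(co$y - 15) <= 2 & abs(co$z - 15) <= 2)
  bone2occ <- bone2occ & !(abs(co$x - 5) <= 1 & abs(co$y - 15) <= 1 &
                             abs(co$z - 15) <= 1)
  bone2 <- binary_mask(g, bone2occ)
  ch2 <- build_channel(hole, bone2, head)
  sealed <- abs(co$x - 5) <= 1 & abs(co$y - 15) <= 1 & abs(co$z - 15) <= 1
  expect_false(any(ch2$channel$occupancy[sealed]))
  # mill outside bone is rejected
  expect_error(build_channel(binary_mask(g, co$x <= 3), bone, head),
               "outside the bone")
})

test_that("accessibility spans its closed-form anchors", {
  g <- voxel_grid(c(31, 31, 31), 1)
  full <- binary_mask(g, array(TRUE, dim = g$shape))
  none <- binary_mask(g, array(FALSE, dim = g$shape))
  mk_ch <- function(chan) structure(list(channel = chan, grid = g),
                                    class = "surgical_channel")
  tool <- tool_model(0.5)
  tgt <- rbind(c(15, 15, 15))
  expect_equal(as.numeric(accessibility(mk_ch(full), tgt, tool,
                                        n_directions = 64)), 1)
  expect_equal(as.numeric(accessibility(mk_ch(none), tgt, tool,
                                        n_directions = 64)), 0)
  expect_error(accessibility(mk_ch(full), tgt[0, , drop = FALSE], tool),
               "empty")
  expect_error(accessibility(mk_ch(full), tgt, tool, n_directions = 8),
               "at least 32")
})

test_that("cone accessibility matches the analytic solid-angle fraction", {
  g <- voxel_grid(c(81, 81, 81), 0.5)
  co <- mastoidplan:::grid_coords(g)
  apex <- c(4, 20, 20)
  dx <- co$x - apex[1]
  dr <- sqrt((co$y - apex[2])^2 + (co$z - apex[3])^2)
  cone <- binary_mask(g, dx > 0 & dr <= dx * tan(pi / 6))
  ch <- structure(list(channel = cone, grid = g), class = "surgical_channel")
  mu <- accessibility(ch, rbind(apex), tool_model(0.01),
                      n_directions = 1024, seed = 3)
  expect_lt(abs(as.numeric(mu) - (1 - cos(pi / 6))), 0.05)
})

test_that("adding channel voxels never decreases accessibility", {
  sc <- default_scene()
  g <- sc$ph$grid
  mill_all <- clip_to_bone(sc$max_area$union_mask, sc$ph$bone)
  ch_all <- build_channel(mill_all, sc$ph$bone, sc$ph$head_region)
  # a shrunken channel: remove half of the milled voxels
  idx <- mask_indices(mill_all)
  half <- binary_mask(g, array(FALSE, dim = g$shape))
  half$occupancy[idx[seq_len(floor(length(idx) / 2))]] <- TRUE
  ch_half <- build_channel(half, sc$ph$bone, sc$ph$head_region)
  tgts <- sc$kept_targets[1:5, , drop = FALSE]
  mu_all <- accessibility(ch_all, tgts, sc$tool, n_directions = 64, seed = 2)
  mu_half <- accessibility(ch_half, tgts, sc$tool, n_directions = 64,
                           seed = 2)
  expect_gte(as.numeric(mu_all) + 1e-12, as.numeric(mu_half))
  expect_true(as.numeric(mu_all) >= 0 && as.numeric(mu_all) <= 1)
})

test_that("injury is the weighted damaged-volume fraction", {
  g <- voxel_grid(c(21, 21, 21), 1)
  co <- mastoidplan:::grid_coords(g)
  bone <- binary_mask(g, co$x >= 10 & co$x <= 15)
  empty <- binary_mask(g, array(FALSE, dim = g$shape))
  tube <- binary_mask(g, (co$x - 8)^2 + (co$y - 10)^2 <= 4)
  s_tube <- critical_structure("scala_vestibuli", tube, "minimize_S",
                               lambda_weight = 0.5)
  expect_equal(injury(empty, bone, list(s_tube), 0.5), 0)
  # milling all of the bone with no S overlap: exactly lambda_bone
  expect_equal(injury(bone, bone, list(), 1), 1)
  mill_half_weight <- injury(bone, bone, list(s_tube), 0.5)
  ov <- sum(bone$occupancy & tube$occupancy) / sum(tube$occupancy)
  expect_equal(mill_half_weight, 0.5 + 0.5 * ov)
  # constructed overlap: mill exactly 1/8 of the tube
  tube_idx <- mask_indices(tube)
  mill <- binary_mask(g, array(FALSE, dim = g$shape))
  eighth <- tube_idx[seq_len(round(length(tube_idx) / 8))]
  mill$occupancy[eighth] <- TRUE
  bone_all <- binary_mask(g, array(TRUE, dim = g$shape))
  qi <- injury(mill, bone_all, list(s_tube), 0.5)
  frac_bone <- length(eighth) / length(bone_all$occupancy)
  frac_tube <- length(eighth) / length(tube_idx)
  expect_equal(qi, 0.5 * frac_bone + 0.5 * frac_tube, tolerance = 1e-12)
  # weight validation
  bad <- s_tube; bad$lambda_weight <- 0.3
  expect_error(injury(mill, bone_all, list(bad), 0.5), "sum to 1")
  expect_error(injury(mill, empty, list(s_tube), 0.5), "empty")
})

test_that("compactness matches closed forms and the exhaustive oracle", {
  # two adjacent voxels at distance d: ordered-pair sum is 2/d
  g2 <- voxel_grid(c(7, 3, 3), 1)
  occ <- array(FALSE, dim = g2$shape)
  occ[3, 2, 2] <- TRUE; occ[4, 2, 2] <- TRUE
  expect_equal(as.numeric(compactness(binary_mask(g2, occ),
                                      exhaustive = TRUE)), 2)
  # an obstacle (gap outside the mask) blocks the line of sight
  occ2 <- array(FALSE, dim = g2$shape)
  occ2[2, 2, 2] <- TRUE; occ2[6, 2, 2] <- TRUE
  expect_equal(as.numeric(compactness(binary_mask(g2, occ2),
                                      exhaustive = TRUE)), 0)
  # ball beats an equal-volume one-voxel rod, estimator tracks the oracle
  ball <- ball_mask(n = 17L, radius = 4, spacing = 1)
  nb <- sum(ball$occupancy)
  gr <- voxel_grid(c(nb + 2L, 3L, 3L), 1)
  rocc <- array(FALSE, dim = gr$shape)
  rocc[1 + seq_len(nb), 2, 2] <- TRUE
  rod <- binary_mask(gr, rocc)
  mu_ball <- as.numeric(compactness(ball, exhaustive = TRUE))
  mu_rod <- as.numeric(compactness(rod, exhaustive = TRUE))
  expect_gt(mu_ball, mu_rod)
  for (s in 1:10) {
    est <- as.numeric(compactness(ball, n_samples = 120, seed = s))
    expect_lt(abs(est - mu_ball) / mu_ball, 0.05)
  }
})

test_that("smoothness ranks circle above blob above star and is invariant", {
  circle <- polar_raster(function(th) 8)
  blob <- polar_raster(function(th) 8 * (0.95 + 0.08 * cos(3 * th)))
  star <- polar_raster(function(th) 8 * (0.75 + 0.25 * cos(8 * th)))
  ms_c <- boundary_smoothness(circle, pixel_mm = 0.25)
  ms_b <- boundary_smoothness(blob, pixel_mm = 0.25)
  ms_s <- boundary_smoothness(star, pixel_mm = 0.25)
  expect_lte(ms_c, 0)
  expect_gt(ms_c, ms_b)
  expect_gt(ms_b, ms_s)
  # translation leaves the tangent spectrum untouched
  shifted <- rbind(matrix(FALSE, 6, ncol(circle)),
                   circle[1:(nrow(circle) - 6), ])
  expect_lt(abs(boundary_smoothness(shifted, pixel_mm = 0.25) - ms_c), 1e-9)
  # uniform scaling: same raster, doubled pixel pitch
  expect_lt(abs(boundary_smoothness(circle, pixel_mm = 0.5) - ms_c), 1e-3)
  expect_error(boundary_smoothness(matrix(FALSE, 5, 5)), "empty")
})

test_that("constructability follows its printed formula", {
  expect_equal(constructability(7.3, 7.3, 0), -1)
  expect_equal(constructability(5, 10, -1), -0.5 * exp(-1))
  expect_error(constructability(1, 0, 0), "positive")
  # limit behavior: very rough boundaries push Q_c toward zero from below
  expect_gt(constructability(5, 10, -30), -1e-12)
  expect_lt(constructability(5, 10, -30), 0)
})

test_that("plan evaluation assembles consistent objective fields", {
  sc <- default_scene()
  nt <- length(sc$areas)
  cache <- precompute_cylinders(sc$areas, sc$tool, sc$ph$grid)
  mill <- clip_to_bone(reconstruct_milling(parameter_set(nt, 8), sc$areas,
                                           sc$tool, sc$ph$grid, cache),
                       sc$ph$bone)
  cfg <- eval_config(n_directions = 64L, compact_samples = 120L)
  ev <- evaluate_plan(mill, sc$areas, sc$ph, sc$kept_targets, sc$tool,
                      mu_gsc_ref = as.numeric(
                        compactness(mill, n_samples = 120L,
                                    seed = cfg$compact_seed)),
                      config = cfg)
  expect_equal(ev$Q_a, -ev$mu_a)
  expect_gte(ev$mu_a, 0); expect_lte(ev$mu_a, 1)
  expect_gte(ev$Q_i, 0)
  expect_lte(ev$mu_sa, 0)
  expect_equal(ev$Q_c, -(ev$mu_gsc / ev$mu_gsc_ref) * exp(ev$mu_sa))
})
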