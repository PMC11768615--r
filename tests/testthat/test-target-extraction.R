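test_that("surface normals agree with analytic sphere and box normals", {
  b <- ball_mask(n = 31L, radius = 12)
  t0 <- estimate_surface_normals(b)
  ctr <- rep(15, 3)
  radial <- sweep(t0$points_mm, 2, ctr)
  radial <- radial / sqrt(rowSums(radial^2))
  cosang <- rowSums(radial * t0$normals)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  expect_gte(mean(ang <= 10), 0.95)
  # axis-aligned box: face-center normal is exactly the face axis
  g <- voxel_grid(c(21, 21, 21), 1)
  co <- mastoidplan:::grid_coords(g)
  box <- binary_mask(g, co$x >= 5 & co$x <= 15 & co$y >= 5 & co$y <= 15 &
                       co$z >= 5 & co$z <= 15)
  tb <- estimate_surface_normals(box)
  face <- which(tb$points_mm[, 1] == 15 & tb$points_mm[, 2] == 10 &
                  tb$points_mm[, 3] == 10)
  expect_equal(as.numeric(tb$normals[face, ]), c(1, 0, 0), tolerance = 1e-9)
  # degenerate target
  one <- array(FALSE, dim = c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_error(estimate_surface_normals(binary_mask(voxel_grid(c(5, 5, 5), 1),
                                                    one)), "degenerate")
})

test_that("ellipsoid normals track the analytic gradient", {
  g <- voxel_grid(c(41, 41, 41), 1)
  co <- mastoidplan:::grid_coords(g)
  ax <- c(14, 9, 11); ctr <- rep(20, 3)
  ell <- binary_mask(g, ((co$x - ctr[1]) / ax[1])^2 +
                       ((co$y - ctr[2]) / ax[2])^2 +
                       ((co$z - ctr[3]) / ax[3])^2 <= 1)
  t0 <- estimate_surface_normals(ell)
  grad <- sweep(sweep(t0$points_mm, 2, ctr), 2, ax^2, "/")
  grad <- grad / sqrt(rowSums(grad^2))
  ang <- acos(pmin(1, pmax(-1, rowSums(grad * t0$normals)))) * 180 / pi
  expect_lte(median(ang), 15)
})

test_that("the orientation filter keeps entry-facing points", {
  b <- ball_mask(n = 31L, radius = 10)
  t0 <- estimate_surface_normals(b)
  # entries clustered on the +x side
  set.seed(3)
  entries <- cbind(40, runif(60, 5, 25), runif(60, 5, 25))
  t1 <- filter_orientation(t0, entries)
  expect_error(filter_orientation(t0, entries[0, , drop = FALSE]),
               "non-empty")
  expect_lte(nrow(t1$points_mm), nrow(t0$points_mm))
  # retained normals mostly face the mean entry direction
  mean_dir <- colMeans(entries) - rep(15, 3)
  mean_dir <- mean_dir / sqrt(sum(mean_dir^2))
  expect_gte(mean(t1$normals %*% mean_dir > 0), 0.8)
  # brute-force recount of r_t on the retained points
  pts <- t0$points_mm; nrm <- t0$normals
  r_t <- sapply(seq_len(nrow(pts)), function(i) {
    tk <- sweep(entries, 2, pts[i, ])
    sum((tk %*% nrm[i, ]) > 0)
  })
  keep <- r_t > mean(r_t) & r_t > 0.05 * nrow(entries)
  expect_equal(nrow(t1$points_mm), sum(keep))
  # back-facing point is excluded: its r_t must be low
  back <- which.min(pts[, 1]) # -x pole faces away from all entries
  expect_false(keep[back])
})

test_that("identical orientation counts leave no strict winners", {
  # symmetric configuration: all candidate points see the same entry count
  g <- voxel_grid(c(9, 9, 9), 1)
  occ <- array(FALSE, dim = c(9, 9, 9))
  occ[4:6, 4:6, 4:6] <- TRUE
  t0 <- estimate_surface_normals(binary_mask(g, occ))
  # a single entry far along +x: r_t identical for the whole +x face
  face <- t0$points_mm[, 1] == 5
  entries <- rbind(c(100, 4, 4))
  r_t <- sapply(seq_len(nrow(t0$points_mm)), function(i)
    sum((sweep(entries, 2, t0$points_mm[i, ]) %*% t0$normals[i, ]) > 0))
  expect_true(length(unique(r_t[face])) >= 1) # sanity on the fixture
  # the strict mean rule cannot keep anything when all counts are equal
  uniform <- rep(r_t[1], length(r_t))
  expect_false(any(uniform > mean(uniform)))
})

test_that("the accessibility filter matches the exhaustive oracle", {
  sc <- default_scene()
  t1 <- filter_orientation(sc$stages$t0, sc$entries)
  # no structures: T2 = T1
  t2_free <- filter_accessible(t1, sc$entries, list(), sc$tool)
  expect_equal(nrow(t2_free$points_mm), nrow(t1$points_mm))
  # with structures: agreement with exhaustive full-K feasibility on >= 95%
  t2 <- filter_accessible(t1, sc$entries, sc$ph$structures, sc$tool)
  intact <- split_structures(sc$ph$structures)$intact
  oracle <- sapply(seq_len(nrow(t1$points_mm)), function(i)
    any(trajectory_feasible(sc$entries, t1$points_mm[i, ], intact, sc$tool)))
  kept <- attr(t1, "voxel_index") %in% attr(t2, "voxel_index")
  expect_gte(mean(kept == oracle), 0.95)
  # subsampling pitch larger than the K extent: single representative
  tiny_tool <- tool_model(60)
  cell <- floor(sc$entries / (2 * tiny_tool$radius_mm))
  expect_equal(nrow(unique(cell)), 1L)
})

test_that("contour extraction orders the cap rim clockwise", {
  b <- ball_mask(n = 31L, radius = 12)
  t0 <- estimate_surface_normals(b)
  # accessible patch: spherical cap x - 15 >= 6 (half-angle alpha)
  sel <- t0$points_mm[, 1] - 15 >= 6
  t2 <- target_stage("T2", t0$points_mm[sel, , drop = FALSE],
                     normals = t0$normals[sel, , drop = FALSE])
  attr(t2, "voxel_index") <- attr(t0, "voxel_index")[sel]
  plane <- control_plane(c(40, 15, 15), normal_sign = 1, pixel_mm = 1,
                         half_extent_mm = 20)
  t3 <- extract_ordered_contour(t2, attr(t0, "voxel_index"), b$grid, plane)
  expect_gte(nrow(t3$points_mm), 3)
  # rim length close to 2 pi R sin(alpha) (voxel jaggedness inflates it)
  R <- 12; alpha <- acos(6 / R)
  rim <- t3$points_mm
  len <- sum(sqrt(rowSums((rim - rim[c(2:nrow(rim), 1), ])^2)))
  expect_lt(abs(len - 2 * pi * R * sin(alpha)) / (2 * pi * R * sin(alpha)),
            0.35)
  # clockwise ordering: projected polar angles monotone decreasing after
  # unwrapping
  uv <- plane_project_uv(plane, rim)
  ctr <- colMeans(uv)
  ang <- atan2(uv[, 2] - ctr[2], uv[, 1] - ctr[1])
  dif <- diff(ang)
  dif[dif > pi] <- dif[dif > pi] - 2 * pi
  expect_true(all(dif <= 0))
  # loop closes: first and last points are near each other on the rim
  gap <- sqrt(sum((rim[1, ] - rim[nrow(rim), ])^2))
  expect_lt(gap, 2 * sqrt(3) * b$grid$spacing_mm + 2)
})

test_that("contour downsampling walks the loop at the tool radius", {
  # synthetic circle of circumference 10 r
  tool <- tool_model(1.5)
  Rc <- 10 * tool$radius_mm / (2 * pi)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  loop <- cbind(10 + Rc * cos(th), 10 + Rc * sin(th), 0)
  t3 <- target_stage("T3", loop)
  t4 <- downsample_contour(t3, tool)
  expect_true(abs(nrow(t4$points_mm) - 10) <= 1)
  # spacing contract: consecutive arc gaps in [r, 2r) except the closing gap
  kept <- t4$points_mm
  gaps <- sqrt(rowSums((kept[-1, , drop = FALSE] -
                          kept[-nrow(kept), , drop = FALSE])^2))
  arc_factor <- 2 * Rc * sin(gaps / (2 * Rc)) # chord; arcs slightly longer
  expect_true(all(gaps >= tool$radius_mm * 0.9))
  expect_true(all(gaps <= 2 * tool$radius_mm))
  # r larger than the whole loop: single point
  big <- tool_model(20 * Rc)
  expect_equal(nrow(downsample_contour(t3, big)$points_mm), 1L)
})

test_that("stages nest and the phantom envelope holds", {
  sc <- default_scene()
  st <- sc$stages
  n <- sapply(st, function(s) nrow(s$points_mm))
  expect_true(n["t1"] <= n["t0"] && n["t2"] <= n["t1"] &&
                n["t3"] <= n["t2"] && n["t4"] <= n["t3"])
  # T1, T2 point sets are subsets of T0
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(st$t1$points_mm) %in% key(st$t0$points_mm)))
  expect_true(all(key(st$t2$points_mm) %in% key(st$t1$points_mm)))
  expect_true(all(key(st$t3$points_mm) %in% key(st$t2$points_mm)))
  expect_true(all(key(st$t4$points_mm) %in% key(st$t3$points_mm)))
  expect_gte(n["t4"], 10)
  expect_lte(n["t4"], 40)
  # every T4 point has at least one feasible entry under the full K
  intact <- split_structures(sc$ph$structures)$intact
  for (i in seq_len(n["t4"]))
    expect_true(any(trajectory_feasible(sc$entries, st$t4$points_mm[i, ],
                                        intact, sc$tool)))
})
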