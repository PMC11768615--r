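test_that("entry projection lands on the plane and resolves ties", {
  plane <- control_plane(c(40, 0, 0), normal_sign = 1, pixel_mm = 1,
                         half_extent_mm = 15)
  tool <- tool_model(1.5)
  t <- c(10, 0, 0)
  # entry already on the plane: g has the entry's in-plane coordinates
  k_on <- c(40, 3, -2)
  B <- project_entries(t, rbind(k_on), plane, tool)
  ij <- which(B$entry_map > 0, arr.ind = TRUE)
  uv <- mastoidplan:::plane_uv_of_cell(plane, ij)
  expect_equal(as.numeric(uv), c(3, -2))
  # two entries mapping to one cell: nearest-to-plane entry wins
  k_far <- c(25, 1.5, -1) # projects onto the same ray as a nearer entry
  k_near <- c(37, 2.7, -1.8)
  B2 <- project_entries(t, rbind(k_far, k_near), plane, tool)
  cells <- which(B2$entry_map > 0)
  winners <- B2$entry_map[cells]
  ij2 <- which(B2$entry_map > 0, arr.ind = TRUE)
  # both rays aim at the same neighborhood; wherever they collide the
  # nearer entry (row 2) must own the cell
  if (length(unique(winners)) == 1L) expect_equal(unique(winners), 2L)
  # parallel ray: skipped with a warning, all parallel -> error
  k_par <- c(10, 5, 5)
  expect_warning(project_entries(t, rbind(k_par, k_on), plane, tool),
                 "parallel")
  expect_warning(expect_error(project_entries(t, rbind(k_par), plane, tool)),
                 "parallel")
})

test_that("projected cone section area matches the analytic ellipse", {
  plane <- control_plane(c(40, 0, 0), normal_sign = 1, pixel_mm = 0.5,
                         half_extent_mm = 18)
  tool <- tool_model(0.5)
  t <- c(10, 0, 0)
  # cone of entries: ring of directions at half-angle 15 deg, radius at
  # the skull surface x = 30 is 20 tan(15 deg)
  set.seed(2)
  n <- 4000
  phi <- runif(n, 0, 2 * pi)
  rad <- sqrt(runif(n)) * 20 * tan(15 * pi / 180)
  ks <- cbind(30, rad * cos(phi), rad * sin(phi))
  B <- project_entries(t, ks, plane, tool)
  # at the plane (30 mm from apex) the disk radius is 30 tan(15 deg)
  a_px <- sum(B$raster) * plane$pixel_mm^2
  a_true <- pi * (30 * tan(15 * pi / 180))^2
  expect_lt(abs(a_px - a_true) / a_true, 0.1)
})

test_that("morphological closing is extensive and connects sparse areas", {
  tool <- tool_model(1.5)
  # solid disk: closing leaves it unchanged
  n <- 25L
  cc <- 13
  disk <- outer(1:n, 1:n, function(i, j) (i - cc)^2 + (j - cc)^2 <= 64)
  expect_identical(close_area(disk, tool, 1), disk)
  # two pixels one apart: gap filled
  two <- matrix(FALSE, 9, 9)
  two[4, 5] <- TRUE; two[6, 5] <- TRUE
  closed <- close_area(two, tool, 1)
  expect_true(closed[5, 5])
  expect_true(all(closed[two]))
  # the phantom's projected entry areas close into one connected component
  sc <- default_scene()
  n_comp <- function(cl) {
    nr <- nrow(cl)
    lab <- matrix(0L, nr, ncol(cl))
    cur <- 0L
    for (s0 in which(cl)) {
      if (lab[s0] > 0L) next
      cur <- cur + 1L
      queue <- s0
      lab[s0] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        i <- (v - 1) %% nr + 1; j <- (v - 1) %/% nr + 1
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(cl)) {
            w <- ii + (jj - 1) * nr
            if (cl[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
          }
        }
      }
    }
    cur
  }
  for (B in sc$areas[seq(1, length(sc$areas), by = 6)])
    expect_equal(n_comp(B$raster), 1L)
})

test_that("the control function interpolates knots periodically in (0, 1]", {
  cf1 <- control_function(rep(1, 8))
  th <- seq(0.01, 2 * pi, length.out = 200)
  expect_true(all(abs(evaluate_sigma(cf1, th) - 1) < 1e-12))
  # knot interpolation
  set.seed(4)
  sig <- runif(8, 0.3, 1)
  cf <- control_function(sig)
  expect_equal(evaluate_sigma(cf, cf$theta), sig, tolerance = 1e-9)
  # periodicity and clipping on an alternating pattern
  alt <- control_function(rep(c(0.4, 0.9), 4))
  v1 <- evaluate_sigma(alt, th)
  v2 <- evaluate_sigma(alt, th + 2 * pi)
  expect_equal(v1, v2, tolerance = 1e-9)
  expect_true(all(v1 >= 1e-3 & v1 <= 1))
  expect_error(control_function(c(0.5, 0, 0.5, 1, 1, 1, 1, 1)), "\\(0, 1\\]")
})

test_that("deformation is the identity at sigma = 1 and scales disks", {
  B <- disk_area_function(radius_px = 12L)
  id <- deform_area(B, control_function(rep(1, 8)))
  expect_identical(id$raster, B$raster)
  half <- deform_area(B, control_function(rep(0.5, 8)))
  ratio <- sum(half$raster) / sum(B$raster)
  expect_lt(abs(ratio - 0.25), 0.02)
  # subset restriction on arbitrary rasters and control functions
  set.seed(10)
  for (rep in 1:5) {
    r <- B
    r$raster <- B$raster & matrix(runif(length(B$raster)) < 0.7,
                                  nrow(B$raster))
    cf <- control_function(runif(8, 0.2, 1))
    dd <- deform_area(r, cf)
    expect_false(any(dd$raster & !r$raster))
  }
})

test_that("reconstruction reproduces the maximum area at all-ones", {
  sc <- default_scene()
  nt <- length(sc$areas)
  cache <- precompute_cylinders(sc$areas, sc$tool, sc$ph$grid)
  mill1 <- reconstruct_milling(parameter_set(nt, 8), sc$areas, sc$tool,
                               sc$ph$grid, cache)
  inter <- sum(mill1$occupancy & sc$max_area$union_mask$occupancy)
  dice <- 2 * inter / (sum(mill1$occupancy) +
                         sum(sc$max_area$union_mask$occupancy))
  expect_gte(dice, 0.98)
  # halving every parameter gives a strict voxel subset
  mill05 <- reconstruct_milling(parameter_set(nt, 8, 0.5), sc$areas,
                                sc$tool, sc$ph$grid, cache)
  expect_false(any(mill05$occupancy & !mill1$occupancy))
  expect_lt(sum(mill05$occupancy), sum(mill1$occupancy))
  expect_error(reconstruct_milling(parameter_set(2, 8), sc$areas, sc$tool,
                                   sc$ph$grid, cache), "match")
})

test_that("one surviving cell reconstructs exactly one cylinder", {
  plane <- control_plane(c(40, 0, 0), normal_sign = 1, pixel_mm = 1,
                         half_extent_mm = 10)
  tool <- tool_model(1.5)
  g <- voxel_grid(c(61, 61, 61), 1, origin_mm = c(0, -30, -30))
  t <- c(10, 0, 0)
  k <- c(40, 2, 1)
  B <- project_entries(t, rbind(k), plane, tool)
  mill <- reconstruct_milling(parameter_set(1, 8), list(B), tool, g)
  ref <- rasterize_cylinder(k, t, tool, g)
  expect_identical(mill$occupancy, ref$occupancy)
})

test_that("elementwise-larger parameters give supersets on the phantom", {
  sc <- default_scene()
  nt <- length(sc$areas)
  cache <- precompute_cylinders(sc$areas, sc$tool, sc$ph$grid)
  set.seed(21)
  p_small <- matrix(runif(nt * 8, 0.3, 0.7), nt, 8)
  p_big <- pmin(1, p_small + 0.3)
  m_small <- reconstruct_milling(parameter_set(nt, 8, p_small), sc$areas,
                                 sc$tool, sc$ph$grid, cache)
  m_big <- reconstruct_milling(parameter_set(nt, 8, p_big), sc$areas,
                               sc$tool, sc$ph$grid, cache)
  extra <- sum(m_small$occupancy & !m_big$occupancy)
  # contractivity on convex areas: violations only from polar raster
  # rounding, and they must be a negligible sliver
  expect_lte(extra, 0.01 * sum(m_small$occupancy))
})
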