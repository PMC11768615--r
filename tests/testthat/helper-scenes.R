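# Shared fixtures: all built in code, memoized so expensive scene stages are
# computed once per test session.

# brute-force nearest-surface-voxel distance oracle (chunked all-pairs);
# surface voxels are occupied voxels with a 6-adjacent background voxel
# inside the grid (a mask clipped by the grid edge has no surface there)
brute_force_surface_distance <- function(occ, spacing) {
  d <- dim(occ)
  has_bg_neighbor <- array(FALSE, dim = d)
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    src <- lapply(d, seq_len); dst <- src
    sel <- src[[ax]] + by
    ok <- sel >= 1 & sel <= d[ax]
    dst[[ax]] <- which(ok); src[[ax]] <- sel[ok]
    nb <- array(FALSE, dim = d)
    nb[dst[[1]], dst[[2]], dst[[3]]] <- !occ[src[[1]], src[[2]], src[[3]]]
    has_bg_neighbor <- has_bg_neighbor | nb
  }
  surf <- occ & has_bg_neighbor
  sidx <- which(surf, arr.ind = TRUE)
  allidx <- which(array(TRUE, dim = d), arr.ind = TRUE)
  out <- numeric(nrow(allidx))
  s2 <- rowSums(sidx^2)
  chunk <- 2000L
  for (st in seq(1L, nrow(allidx), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(allidx))
    blk <- allidx[st:en, , drop = FALSE]
    D2 <- outer(rowSums(blk^2), s2, "+") - 2 * blk %*% t(sidx)
    out[st:en] <- sqrt(pmax(0, apply(D2, 1, min))) * spacing
  }
  array(out, dim = d)
}

# solid ball mask
ball_mask <- function(n = 21L, spacing = 1, radius = 8, center = NULL) {
  g <- voxel_grid(c(n, n, n), spacing)
  if (is.null(center)) center <- rep((n - 1) / 2 * spacing, 3)
  co <- mastoidplan:::grid_coords(g)
  binary_mask(g, (co$x - center[1])^2 + (co$y - center[2])^2 +
                (co$z - center[3])^2 <= radius^2)
}

# flat bone slab along +R with a free face at x = x_hi
slab_mask <- function(n = 41L, spacing = 1, x_lo = 25, x_hi = 35) {
  g <- voxel_grid(c(n, n, n), spacing)
  co <- mastoidplan:::grid_coords(g)
  binary_mask(g, co$x >= x_lo & co$x <= x_hi)
}

# centered-disk area function on a synthetic control plane (mass center at
# the disk center by construction)
disk_area_function <- function(radius_px = 12L, pixel_mm = 1) {
  plane <- control_plane(c(0, 0, 0), normal_sign = 1, pixel_mm = pixel_mm,
                         half_extent_mm = (radius_px + 4) * pixel_mm)
  n <- plane$n_u
  cc <- (n + 1) / 2
  raster <- outer(seq_len(n), seq_len(n),
                  function(i, j) (i - cc)^2 + (j - cc)^2 <= radius_px^2)
  structure(list(plane = plane, raster = raster,
                 entry_map = matrix(0L, n, n),
                 mass_center = as.numeric(plane_uv_of_cell_pub(plane,
                                                               c(cc, cc))),
                 target = c(-10, 0, 0), entries = matrix(0, 0, 3)),
            class = "area_function")
}

plane_uv_of_cell_pub <- function(plane, ij) {
  mastoidplan:::plane_uv_of_cell(plane, ij)
}

# binary raster of a polar shape rho(theta), for smoothness fixtures
polar_raster <- function(rho_fun, n = 101L, pixel = 0.25) {
  cc <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- (i - cc) * pixel
    dy <- (j - cc) * pixel
    m[i, j] <- sqrt(dx^2 + dy^2) <= rho_fun(atan2(dy, dx))
  }
  m
}

# memoized default phantom scene with all planning stages precomputed
default_scene <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ph <- generate_phantom(phantom_spec())
    tool <- tool_model(1.5)
    ctr <- colMeans(mask_points(ph$target))
    entries <- find_entry_candidates(ph$bone, ctr, c(-1, 0, 0), 12)
    plane <- default_control_plane(entries, ctr, ph$grid, tool)
    stages <- extract_targets(ph$target, entries, ph$structures, tool, plane)
    max_area <- generate_max_area(stages$t4$points_mm, entries,
                                  ph$structures, tool, ph$grid)
    areas <- build_area_functions(max_area, plane, tool)
    cache <<- list(ph = ph, tool = tool, centroid = ctr, entries = entries,
                   plane = plane, stages = stages, max_area = max_area,
                   areas = areas,
                   kept_targets = stages$t4$points_mm[max_area$target_rows, ,
                                                      drop = FALSE])
    cache
  }
})
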