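#' Isotropic voxel grid in RAS millimetres
#'
#' The common lattice shared by every mask and field in a planning scene.
#' World coordinates follow the voxel-center convention: the world position
#' of (1-based) voxel index `i` is `origin + (i - 1) * spacing`. Axis order
#' is fixed as (R, A, S).
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing_mm positive scalar, isotropic voxel edge length in mm.
#' @param origin_mm numeric vector of length 3, world position (RAS mm) of
#'   the first voxel center.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), length(origin_mm) == 3)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a positive scalar")
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d @ %.3g mm, origin (%.3g, %.3g, %.3g) RAS>\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

grids_compatible <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

#' Binary occupancy mask on a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @param occupancy logical array with `dim` equal to `grid$shape`, or a
#'   logical vector of matching length.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, occupancy) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- array(as.logical(occupancy), dim = grid$shape)
  if (length(occ) != prod(grid$shape))
    stop("occupancy length does not match grid shape")
  structure(list(grid = grid, occupancy = occ), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d/%d voxels occupied (%.2f mm^3 each)>\n",
              sum(x$occupancy), length(x$occupancy), x$grid$spacing_mm^3))
  invisible(x)
}

#' Signed distance field on a voxel grid
#'
#' Values in mm, negative strictly inside the generating structure, positive
#' strictly outside, zero crossing at the mask boundary.
#'
#' @param grid a [voxel_grid()].
#' @param values numeric array of distances (mm), `dim` equal to the grid shape.
#' @return An object of class `sdf_field`.
#' @export
sdf_field <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  vals <- array(as.numeric(values), dim = grid$shape)
  structure(list(grid = grid, values = vals), class = "sdf_field")
}

#' Convert 1-based voxel indices to RAS world coordinates (mm)
#'
#' @param grid a [voxel_grid()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices, or a vector of
#'   length 3.
#' @return numeric matrix (n x 3) of world coordinates.
#' @export
index_to_world <- function(grid, idx) {
  idx <- rbind(idx)
  sweep((idx - 1) * grid$spacing_mm, 2, grid$origin_mm, "+")
}

#' Convert RAS world coordinates (mm) to continuous 1-based voxel indices
#'
#' @param grid a [voxel_grid()].
#' @param pts numeric matrix (n x 3) of world coordinates, or a 3-vector.
#' @return numeric matrix (n x 3) of continuous voxel indices.
#' @export
world_to_index <- function(grid, pts) {
  pts <- rbind(pts)
  sweep(pts, 2, grid$origin_mm, "-") / grid$spacing_mm + 1
}

#' Linear (column-major) voxel indices of occupied voxels
#' @param mask a [binary_mask()].
#' @return integer vector of 1-based linear indices.
#' @export
mask_indices <- function(mask) which(mask$occupancy)

#' World coordinates of occupied voxel centers
#' @param mask a [binary_mask()].
#' @return numeric matrix (n x 3), RAS mm.
#' @export
mask_points <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  index_to_world(mask$grid, idx)
}

#' Volume of a mask in cubic millimetres
#' @param mask a [binary_mask()].
#' @return scalar, occupied voxel count times voxel volume.
#' @export
mask_volume_mm3 <- function(mask) sum(mask$occupancy) * mask$grid$spacing_mm^3

#' Resample a mask or scalar field to a new isotropic spacing
#'
#' The output grid covers the same world extent (voxel centers of the new
#' grid span the old center hull). Binary masks are resampled by
#' nearest-neighbor lookup, scalar fields by trilinear interpolation, so
#' world positions of content are preserved within one output voxel.
#'
#' @param volume a [binary_mask()] or [sdf_field()].
#' @param new_spacing_mm positive scalar, target spacing in mm.
#' @return An object of the same class as `volume` on the resampled grid.
#' @export
resample_isotropic <- function(volume, new_spacing_mm) {
  if (!is.numeric(new_spacing_mm) || length(new_spacing_mm) != 1L ||
      new_spacing_mm <= 0)
    stop("new_spacing_mm must be a positive scalar")
  g <- volume$grid
  if (isTRUE(all.equal(new_spacing_mm, g$spacing_mm))) return(volume)
  extent <- (g$shape - 1L) * g$spacing_mm
  new_shape <- pmax(1L, as.integer(floor(extent / new_spacing_mm)) + 1L)
  ng <- voxel_grid(new_shape, new_spacing_mm, g$origin_mm)
  # continuous source indices of every output voxel center
  ax <- lapply(1:3, function(a) {
    (seq_len(new_shape[a]) - 1) * new_spacing_mm / g$spacing_mm + 1
  })
  if (inherits(volume, "binary_mask")) {
    ri <- lapply(1:3, function(a) pmin(g$shape[a], pmax(1L, round(ax[[a]]))))
    occ <- volume$occupancy[ri[[1]], ri[[2]], ri[[3]], drop = FALSE]
    binary_mask(ng, occ)
  } else if (inherits(volume, "sdf_field")) {
    vals <- trilinear_grid_sample(volume$values, ax[[1]], ax[[2]], ax[[3]])
    sdf_field(ng, vals)
  } else stop("unsupported volume type")
}

# trilinear resampling of a 3-D array onto the tensor grid of continuous
# 1-based indices (xi, yi, zi): 8-corner weighted sum over the outer product
trilinear_grid_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  x0 <- pmin(d[1] - 1L, pmax(1L, floor(xi))); fx <- xi - x0
  y0 <- pmin(d[2] - 1L, pmax(1L, floor(yi))); fy <- yi - y0
  z0 <- pmin(d[3] - 1L, pmax(1L, floor(zi))); fz <- zi - z0
  fx <- pmin(1, pmax(0, fx)); fy <- pmin(1, pmax(0, fy)); fz <- pmin(1, pmax(0, fz))
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  out <- array(0, dim = c(nx, ny, nz))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- outer(outer(if (dx == 0) 1 - fx else fx,
                     if (dy == 0) 1 - fy else fy), if (dz == 0) 1 - fz else fz)
    out <- out + arr[x0 + dx, y0 + dy, z0 + dz, drop = FALSE] * w
  }
  out
}

#' Pad a mask's grid with background voxels on every side
#'
#' Planning grids are padded by at least `r + max(d_risk)` mm so that segment
#' distance queries never leave the grid bounds.
#'
#' @param mask a [binary_mask()].
#' @param pad_mm non-negative padding in mm (rounded up to whole voxels).
#' @return A [binary_mask()] on the enlarged grid.
#' @export
pad_mask <- function(mask, pad_mm) {
  g <- mask$grid
  nv <- as.integer(ceiling(pad_mm / g$spacing_mm))
  if (nv <= 0L) return(mask)
  ns <- g$shape + 2L * nv
  ng <- voxel_grid(ns, g$spacing_mm, g$origin_mm - nv * g$spacing_mm)
  occ <- array(FALSE, dim = ns)
  occ[nv + seq_len(g$shape[1]), nv + seq_len(g$shape[2]),
      nv + seq_len(g$shape[3])] <- mask$occupancy
  binary_mask(ng, occ)
}
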