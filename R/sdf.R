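#' Signed distance field of a binary mask
#'
#' Exact Euclidean distance transform (separable lower-envelope algorithm)
#' of both the mask and its complement, combined with the half-voxel
#' boundary convention: a background voxel carries `d_out - spacing/2`
#' (strictly positive), an occupied voxel carries `-(d_in - spacing/2)`
#' (strictly negative), where `d_out`/`d_in` are center-to-center distances
#' to the nearest occupied/background voxel. The magnitude therefore tracks
#' the distance to the nearest surface voxel within half a voxel diagonal,
#' and the zero crossing sits on the voxel faces separating inside from
#' outside.
#'
#' @param mask a [binary_mask()]; must be neither empty nor full.
#' @return An [sdf_field()] in mm on the same grid.
#' @export
compute_sdf <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n_occ <- sum(mask$occupancy)
  if (n_occ == 0L || n_occ == length(mask$occupancy))
    stop("no surface: mask is empty or full, distance undefined")
  vals <- cpp_sdf3d(as.logical(mask$occupancy), mask$grid$shape,
                    mask$grid$spacing_mm)
  sdf_field(mask$grid, vals)
}

#' Unsigned distance to a voxel seed set
#'
#' @param seed logical array (or [binary_mask()]) marking the seed voxels.
#' @param grid the [voxel_grid()] (ignored when `seed` is a mask).
#' @return numeric array of center-to-center distances in mm.
#' @keywords internal
distance_to_set <- function(seed, grid = NULL) {
  if (inherits(seed, "binary_mask")) {
    grid <- seed$grid
    seed <- seed$occupancy
  }
  array(cpp_edt3d(as.logical(seed), grid$shape, grid$spacing_mm),
        dim = grid$shape)
}

#' Sample a signed distance field at world points
#'
#' @param sdf an [sdf_field()].
#' @param pts numeric matrix (n x 3) of RAS mm points (or a 3-vector).
#' @param mode `"trilinear"` (default) or `"nearest"` voxel lookup.
#' @return numeric vector of interpolated distances (mm).
#' @export
sdf_at <- function(sdf, pts, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  pts <- rbind(pts)
  # degenerate segments of zero length sample a single point
  cpp_segment_min(sdf$values, sdf$grid$shape, sdf$grid$origin_mm,
                  sdf$grid$spacing_mm, pts, pts,
                  step_mm = sdf$grid$spacing_mm, nearest = mode == "nearest")
}

#' Minimum signed distance from a structure to a segment
#'
#' Samples the SDF at points spaced at most `step_mm` along the segment
#' `[p0, p1]` and returns the minimum, i.e. the (signed) clearance between
#' the structure and the tool trajectory. Equals the true segment-to-
#' structure distance within `step_mm` plus interpolation error.
#'
#' @param sdf an [sdf_field()] of the structure.
#' @param p0,p1 distinct RAS mm endpoints; both must lie inside the grid
#'   bounds (pad the grid beforehand, see [pad_mask()]).
#' @param step_mm sampling step; defaults to half the voxel spacing, which
#'   keeps the segment-sampling error below the voxelization error.
#' @param mode `"trilinear"` (default) or `"nearest"` voxel lookup.
#' @return scalar minimum distance in mm (negative if the segment pierces
#'   the structure).
#' @export
sdf_min_along_segment <- function(sdf, p0, p1,
                                  step_mm = sdf$grid$spacing_mm / 2,
                                  mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (isTRUE(all.equal(as.numeric(p0), as.numeric(p1))))
    stop("p0 and p1 must be distinct")
  cpp_segment_min(sdf$values, sdf$grid$shape, sdf$grid$origin_mm,
                  sdf$grid$spacing_mm, rbind(p0), rbind(p1),
                  step_mm = step_mm, nearest = mode == "nearest")[1]
}

#' Minimum SDF along many segments at once
#'
#' Vectorized form of [sdf_min_along_segment()] used by the feasibility
#' sweep over entry candidates.
#'
#' @param sdf an [sdf_field()].
#' @param p0,p1 numeric matrices (n x 3) of segment endpoints, RAS mm.
#' @param step_mm sampling step in mm.
#' @param mode interpolation mode.
#' @return numeric vector of per-segment minima (mm).
#' @export
sdf_min_along_segments <- function(sdf, p0, p1,
                                   step_mm = sdf$grid$spacing_mm / 2,
                                   mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  cpp_segment_min(sdf$values, sdf$grid$shape, sdf$grid$origin_mm,
                  sdf$grid$spacing_mm, rbind(p0), rbind(p1),
                  step_mm = step_mm, nearest = mode == "nearest")
}
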