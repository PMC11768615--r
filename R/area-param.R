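#' Control plane for entry-area parameterization
#'
#' A 2-D raster plane parallel to the anatomical A-S plane (normal along
#' +/-R, on the approach side of the skull). Feasible entries are projected
#' onto it along the target-to-entry rays, turning the irregular skull
#' surface into a flat area function per target. In-plane axes are
#' orthonormal with `normal = u x v`.
#'
#' @param origin_mm RAS mm point on the plane (raster center).
#' @param normal_sign +1 or -1: plane normal along +R or -R (the approach
#'   side).
#' @param pixel_mm in-plane raster pitch (default: planning voxel spacing).
#' @param half_extent_mm raster half-width in mm (same for u and v).
#' @return An object of class `control_plane` with raster geometry
#'   (`n_u`, `n_v`, cell-center uv coordinates).
#' @export
control_plane <- function(origin_mm, normal_sign = 1, pixel_mm = 1,
                          half_extent_mm = 20) {
  stopifnot(normal_sign %in% c(-1, 1), pixel_mm > 0, half_extent_mm > 0)
  # axes span A-S; order chosen so that u x v = normal
  if (normal_sign > 0) {
    u_axis <- c(0, 1, 0); v_axis <- c(0, 0, 1)
  } else {
    u_axis <- c(0, 0, 1); v_axis <- c(0, 1, 0)
  }
  n_half <- ceiling(half_extent_mm / pixel_mm)
  n <- 2L * as.integer(n_half) + 1L
  uv0 <- -n_half * pixel_mm
  structure(list(origin_mm = as.numeric(origin_mm),
                 u_axis = u_axis, v_axis = v_axis,
                 normal = c(normal_sign, 0, 0),
                 pixel_mm = pixel_mm, n_u = n, n_v = n,
                 uv0 = c(uv0, uv0)),
            class = "control_plane")
}

#' Project world points into plane (u, v) coordinates
#' @param plane a [control_plane()].
#' @param pts numeric matrix (n x 3), RAS mm.
#' @return numeric matrix (n x 2) of in-plane coordinates (mm).
#' @export
plane_project_uv <- function(plane, pts) {
  pts <- rbind(pts)
  rel <- sweep(pts, 2, plane$origin_mm)
  cbind(rel %*% plane$u_axis, rel %*% plane$v_axis)
}

plane_cell_of_uv <- function(plane, uv) {
  uv <- rbind(uv)
  cbind(round((uv[, 1] - plane$uv0[1]) / plane$pixel_mm) + 1L,
        round((uv[, 2] - plane$uv0[2]) / plane$pixel_mm) + 1L)
}

plane_uv_of_cell <- function(plane, ij) {
  ij <- rbind(ij)
  cbind(plane$uv0[1] + (ij[, 1] - 1L) * plane$pixel_mm,
        plane$uv0[2] + (ij[, 2] - 1L) * plane$pixel_mm)
}

#' Entry-selection area function of one target on the control plane
#'
#' Each feasible entry k of target t is extended along the ray t->k to its
#' intersection g with the control plane; the raster cell containing g is
#' set and remembers its originating entry (nearest-to-plane entry wins
#' ties). The raster is then closed with a disk of the tool radius
#' ([close_area()]) so the area forms one connected component; cells added
#' by the closing inherit the entry of the nearest originally-mapped cell.
#' The polar mass center is computed once here and stays frozen through
#' every later deformation.
#'
#' @param t target point, RAS mm.
#' @param k_t feasible entry matrix (n x 3) for this target.
#' @param plane a [control_plane()].
#' @param tool a [tool_model()] (closing kernel size).
#' @return An object of class `area_function`: `plane`, `raster` (logical
#'   n_u x n_v), `entry_map` (integer raster of rows into `entries`),
#'   `mass_center` (uv), `target`, `entries`.
#' @export
project_entries <- function(t, k_t, plane, tool) {
  k_t <- rbind(k_t)
  t <- as.numeric(t)
  nrm <- plane$normal
  denom <- (sweep(k_t, 2, t) %*% nrm)[, 1]
  off <- sum((plane$origin_mm - t) * nrm)
  ok <- abs(denom) > 1e-6
  if (any(!ok))
    warning(sprintf("%d entry ray(s) parallel to the control plane; skipped",
                    sum(!ok)))
  if (!any(ok)) stop("empty area function: no entry projects onto the plane")
  s <- off / denom[ok]
  g <- sweep(sweep(k_t[ok, , drop = FALSE], 2, t), 1, s, "*")
  g <- sweep(g, 2, t, "+")
  uv <- plane_project_uv(plane, g)
  ij <- plane_cell_of_uv(plane, uv)
  inb <- ij[, 1] >= 1 & ij[, 1] <= plane$n_u & ij[, 2] >= 1 &
    ij[, 2] <= plane$n_v
  if (!any(inb)) stop("empty area function: projections fall off the raster")
  ij <- ij[inb, , drop = FALSE]
  rows <- which(ok)[inb]
  # distance from entry to plane decides ties (nearest wins)
  dist_plane <- abs((sweep(k_t[rows, , drop = FALSE], 2,
                           plane$origin_mm) %*% nrm)[, 1])
  raster <- matrix(FALSE, plane$n_u, plane$n_v)
  entry_map <- matrix(0L, plane$n_u, plane$n_v)
  best <- matrix(Inf, plane$n_u, plane$n_v)
  for (q in seq_len(nrow(ij))) {
    i <- ij[q, 1]; j <- ij[q, 2]
    raster[i, j] <- TRUE
    if (dist_plane[q] < best[i, j]) {
      best[i, j] <- dist_plane[q]
      entry_map[i, j] <- rows[q]
    }
  }
  closed <- close_area(raster, tool, plane$pixel_mm)
  # closing-added cells inherit the entry of the nearest mapped cell
  add <- which(closed & !raster, arr.ind = TRUE)
  if (nrow(add) > 0) {
    src <- which(raster, arr.ind = TRUE)
    for (q in seq_len(nrow(add))) {
      d2 <- (src[, 1] - add[q, 1])^2 + (src[, 2] - add[q, 2])^2
      w <- src[which.min(d2), , drop = FALSE]
      entry_map[add[q, 1], add[q, 2]] <- entry_map[w[1], w[2]]
    }
  }
  occ <- which(closed, arr.ind = TRUE)
  uv_occ <- plane_uv_of_cell(plane, occ)
  structure(list(plane = plane, raster = closed, entry_map = entry_map,
                 mass_center = colMeans(uv_occ), target = t,
                 entries = k_t),
            class = "area_function")
}

#' Morphological closing of a plane raster with a disk of the tool radius
#'
#' Dilation followed by erosion with a disk structuring element of radius
#' `r` (in pixels, rounded up), computed on a padded copy so the result is
#' always a superset of the input.
#'
#' @param raster logical matrix.
#' @param tool a [tool_model()].
#' @param pixel_mm raster pitch in mm.
#' @return logical matrix of the same shape.
#' @export
close_area <- function(raster, tool, pixel_mm) {
  rp <- as.integer(ceiling(tool$radius_mm / pixel_mm))
  if (rp <= 0L) return(raster)
  # pixel-coverage disk: cells the radius-rp disk touches; the half-pixel
  # margin lets the closing bridge sub-kernel gaps despite digitization
  offs <- as.matrix(expand.grid(-rp:rp, -rp:rp))
  offs <- offs[rowSums(offs^2) <= (rp + 0.5)^2, , drop = FALSE]
  pad <- rp + 1L
  big <- matrix(FALSE, nrow(raster) + 2L * pad, ncol(raster) + 2L * pad)
  big[pad + seq_len(nrow(raster)), pad + seq_len(ncol(raster))] <- raster
  dil <- matrix(FALSE, nrow(big), ncol(big))
  idx <- which(big, arr.ind = TRUE)
  for (q in seq_len(nrow(offs))) {
    sh <- cbind(idx[, 1] + offs[q, 1], idx[, 2] + offs[q, 2])
    dil[sh] <- TRUE
  }
  ero <- matrix(TRUE, nrow(big), ncol(big))
  idx0 <- which(!dil, arr.ind = TRUE)
  for (q in seq_len(nrow(offs))) {
    sh <- cbind(idx0[, 1] + offs[q, 1], idx0[, 2] + offs[q, 2])
    ok <- sh[, 1] >= 1 & sh[, 1] <= nrow(big) & sh[, 2] >= 1 &
      sh[, 2] <= ncol(big)
    ero[sh[ok, , drop = FALSE]] <- FALSE
  }
  out <- ero[pad + seq_len(nrow(raster)), pad + seq_len(ncol(raster))]
  out | raster
}

#' Periodic polar control function
#'
#' N control points `(theta_i = i/N * 2*pi, sigma_i)` with `sigma` in
#' `(0, 1]`, interpolated by a periodic cubic spline; evaluations are
#' clipped into `[1e-3, 1]` so the radial scaling stays strictly positive.
#'
#' @param sigma numeric vector of N knot values in `(0, 1]`.
#' @return An object of class `control_function`.
#' @export
control_function <- function(sigma) {
  sigma <- as.numeric(sigma)
  n <- length(sigma)
  if (n < 3L) stop("need at least 3 control points")
  if (any(sigma <= 0 | sigma > 1)) stop("sigma values must lie in (0, 1]")
  theta <- (seq_len(n) / n) * 2 * pi
  structure(list(n_points = n, theta = theta, sigma = sigma),
            class = "control_function")
}

#' Evaluate the control function at polar angles
#'
#' @param cf a [control_function()].
#' @param theta angles in radians (any real; evaluated 2*pi-periodically).
#' @return numeric vector of radial scale factors in `[1e-3, 1]`.
#' @export
evaluate_sigma <- function(cf, theta) {
  x <- c(cf$theta, cf$theta[1] + 2 * pi)
  y <- c(cf$sigma, cf$sigma[1])
  f <- stats::splinefun(x, y, method = "periodic")
  pmin(1, pmax(1e-3, f(theta)))
}

#' Radially deform an area function by its control function
#'
#' Each occupied cell's polar coordinates (rho, theta) about the frozen
#' mass center are looked up at (rho / sigma(theta), theta): the cell is
#' kept iff that source cell is occupied in the undeformed raster. The
#' second factor of the deformation (the subset restriction) is automatic:
#' only cells already occupied are considered, so the output is always a
#' subset of the input.
#'
#' @param B an [project_entries()] area function.
#' @param cf a [control_function()].
#' @return A deformed `area_function` (raster subset of `B$raster`).
#' @export
deform_area <- function(B, cf) {
  occ <- which(B$raster, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("area function is empty")
  uv <- plane_uv_of_cell(B$plane, occ)
  du <- uv[, 1] - B$mass_center[1]
  dv <- uv[, 2] - B$mass_center[2]
  rho <- sqrt(du^2 + dv^2)
  theta <- atan2(dv, du) %% (2 * pi)
  sig <- evaluate_sigma(cf, theta)
  src_uv <- cbind(B$mass_center[1] + du / sig, B$mass_center[2] + dv / sig)
  src_ij <- plane_cell_of_uv(B$plane, src_uv)
  inb <- src_ij[, 1] >= 1 & src_ij[, 1] <= B$plane$n_u &
    src_ij[, 2] >= 1 & src_ij[, 2] <= B$plane$n_v
  keep <- logical(nrow(occ))
  keep[inb] <- B$raster[src_ij[inb, , drop = FALSE]]
  out <- B
  raster <- matrix(FALSE, B$plane$n_u, B$plane$n_v)
  raster[occ[keep, , drop = FALSE]] <- TRUE
  out$raster <- raster
  out
}

#' Parameter set governing the whole milling volume
#'
#' One row of N control-point values per retained target, each in
#' `(0, 1]`; the all-ones matrix reproduces the maximum milling area.
#'
#' @param n_targets,n_points matrix dimensions.
#' @param values optional numeric matrix; defaults to all ones.
#' @return numeric matrix of class `parameter_set`.
#' @export
parameter_set <- function(n_targets, n_points = 8L, values = NULL) {
  if (is.null(values)) values <- matrix(1, n_targets, n_points)
  values <- matrix(values, n_targets, n_points)
  if (any(values <= 0 | values > 1)) stop("parameters must lie in (0, 1]")
  class(values) <- c("parameter_set", class(values))
  values
}

#' Precompute per-entry cylinder voxel indices for fast reconstruction
#'
#' @param areas list of `area_function` (one per target).
#' @param tool a [tool_model()].
#' @param grid the planning [voxel_grid()].
#' @return list (per target) of lists: unique entry rows used by the area's
#'   cells and their cylinder voxel-index vectors.
#' @export
precompute_cylinders <- function(areas, tool, grid) {
  lapply(areas, function(B) {
    rows <- sort(unique(B$entry_map[B$raster & B$entry_map > 0L]))
    cyl <- lapply(rows, function(r)
      rasterize_cylinder_indices(B$entries[r, ], B$target, tool, grid))
    list(rows = rows, cylinders = cyl)
  })
}

#' Reconstruct the milling volume from a parameter set
#'
#' Per target: build the control function from the parameter row, deform
#' the area function, and union the tool cylinders of every surviving
#' raster cell's originating entry; the result is the voxel union across
#' targets. With all parameters at 1 this reproduces the maximum milling
#' area up to projection/closing discretization.
#'
#' @param params a [parameter_set()] (rows = targets).
#' @param areas list of `area_function`, one per parameter row.
#' @param tool a [tool_model()].
#' @param grid the planning [voxel_grid()].
#' @param cache optional [precompute_cylinders()] output for speed.
#' @return A [binary_mask()] of the milling volume.
#' @export
reconstruct_milling <- function(params, areas, tool, grid, cache = NULL) {
  if (nrow(params) != length(areas))
    stop("parameter rows must match the number of areas")
  if (is.null(cache)) cache <- precompute_cylinders(areas, tool, grid)
  occ <- array(FALSE, dim = grid$shape)
  any_cell <- FALSE
  for (i in seq_along(areas)) {
    B <- deform_area(areas[[i]], control_function(params[i, ]))
    rows <- unique(B$entry_map[B$raster & B$entry_map > 0L])
    if (length(rows) == 0L) next
    any_cell <- TRUE
    sel <- match(rows, cache[[i]]$rows)
    occ[unlist(cache[[i]]$cylinders[sel], use.names = FALSE)] <- TRUE
  }
  if (!any_cell) stop("plan vanished: every area deformed to empty")
  binary_mask(grid, occ)
}

#' Build per-target area functions from a maximum milling area
#'
#' @param max_area a [generate_max_area()] result.
#' @param plane a [control_plane()].
#' @param tool a [tool_model()].
#' @return list of `area_function`, one per retained target.
#' @export
build_area_functions <- function(max_area, plane, tool) {
  lapply(max_area$per_target, function(pt)
    project_entries(pt$target, pt$entries, plane, tool))
}

#' Default control-plane placement for a planning scene
#'
#' The plane sits at the entry surface (median entry R level), normal
#' along +/-R on the approach side, origin at the target centroid
#' projected onto that level, pitch equal to the planning voxel spacing,
#' sized to cover the projected entries with a tool-radius margin.
#'
#' @param entries entry candidate matrix (n x 3).
#' @param target_centroid RAS mm centroid of the target points.
#' @param grid the planning [voxel_grid()].
#' @param tool a [tool_model()].
#' @return A [control_plane()].
#' @export
default_control_plane <- function(entries, target_centroid, grid, tool) {
  x0 <- stats::median(entries[, 1])
  sgn <- if (x0 >= target_centroid[1]) 1 else -1
  origin <- c(x0, target_centroid[2], target_centroid[3])
  half <- max(abs(sweep(entries[, 2:3, drop = FALSE], 2,
                        origin[2:3]))) + 4 * tool$radius_mm
  control_plane(origin, normal_sign = sgn, pixel_mm = grid$spacing_mm,
                half_extent_mm = half)
}
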