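#' Cylindrical surgical tool model
#'
#' The single tool dimension `r` is used everywhere: as the milling-cylinder
#' radius, the contour downsampling interval, and the closing-kernel size.
#'
#' @param radius_mm positive cylinder radius in mm.
#' @return An object of class `tool_model`.
#' @export
tool_model <- function(radius_mm = 1.5) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    stop("radius_mm must be a positive scalar")
  structure(list(radius_mm = radius_mm), class = "tool_model")
}

#' Entry-point candidates on the outer skull surface
#'
#' Returns outer-surface bone voxels that (a) project within
#' `max_offset_mm` of the target centroid on the plane orthogonal to the
#' approach axis and (b) face the approach side, i.e. whose outward surface
#' normal (gradient of the bone SDF) has positive dot product with
#' `-approach_axis`. Order is deterministic (column-major voxel index).
#'
#' @param bone a [binary_mask()] of the skull.
#' @param target_centroid RAS mm centroid of the surgical target.
#' @param approach_axis unit 3-vector pointing from the entries toward the
#'   target (the tool's travel direction).
#' @param max_offset_mm radius of the candidate disk around the centroid's
#'   projection.
#' @param bone_sdf optional precomputed [compute_sdf()] of `bone`.
#' @return numeric matrix (n x 3) of entry world coordinates, with the
#'   originating linear voxel indices as attribute `"voxel_index"`.
#' @export
find_entry_candidates <- function(bone, target_centroid, approach_axis,
                                  max_offset_mm, bone_sdf = NULL) {
  stopifnot(inherits(bone, "binary_mask"))
  if (!any(bone$occupancy)) stop("bone mask is empty")
  axis <- approach_axis / sqrt(sum(approach_axis^2))
  occ <- bone$occupancy
  surf <- occ & !erode6(occ)
  idx <- which(surf, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no entry candidates")
  pts <- index_to_world(bone$grid, idx)
  if (is.null(bone_sdf)) bone_sdf <- compute_sdf(bone)
  nrm <- sdf_gradient_at(bone_sdf, idx)
  facing <- (nrm %*% (-axis))[, 1] > 0
  rel <- sweep(pts, 2, as.numeric(target_centroid))
  along <- rel %*% axis
  perp <- rel - along %*% t(axis)
  offset <- sqrt(rowSums(perp^2))
  keep <- facing & offset <= max_offset_mm + 1e-9
  if (!any(keep)) stop("no entry candidates")
  lin <- which(surf)
  out <- pts[keep, , drop = FALSE]
  attr(out, "voxel_index") <- lin[keep]
  out
}

# 6-neighborhood erosion of a logical array (border voxels treated exposed)
erode6 <- function(occ) {
  d <- dim(occ)
  out <- occ
  shift <- function(a, ax, by) {
    res <- array(FALSE, dim = d)
    src <- lapply(d, seq_len); dst <- src
    src[[ax]] <- seq_len(d[ax]) - by
    ok <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
    dst[[ax]] <- which(ok); src[[ax]] <- src[[ax]][ok]
    res[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(occ, ax, by)
  out
}

# separable 1-2-1 smoothing of a 3-D array (borders clamped)
smooth_121 <- function(v) {
  d <- dim(v)
  for (a in 1:3) {
    idx <- seq_len(d[a])
    shift <- function(arr, by) {
      gi <- pmin(d[a], pmax(1L, idx + by))
      if (a == 1) arr[gi, , , drop = FALSE]
      else if (a == 2) arr[, gi, , drop = FALSE]
      else arr[, , gi, drop = FALSE]
    }
    v <- (shift(v, -1L) + 2 * v + shift(v, 1L)) / 4
  }
  v
}

# Gradient of an SDF at integer voxel indices, normalized. The field is
# 1-2-1 smoothed per axis before the central difference, which suppresses
# the voxel staircase that a bare difference picks up on rasterized
# surfaces (sphere-normal error stays below ~10 degrees at 1 mm voxels).
sdf_gradient_at <- function(sdf, idx) {
  v <- smooth_121(sdf$values)
  d <- dim(v)
  g <- matrix(0, nrow(idx), 3)
  for (a in 1:3) {
    up <- idx; up[, a] <- pmin(d[a], idx[, a] + 1L)
    dn <- idx; dn[, a] <- pmax(1L, idx[, a] - 1L)
    g[, a] <- (v[up] - v[dn]) /
      ((up[, a] - dn[, a]) * sdf$grid$spacing_mm)
  }
  n <- sqrt(rowSums(g^2))
  n[n == 0] <- 1
  g / n
}

#' Is a straight tool trajectory safe for every intact structure?
#'
#' A trajectory from entry `k` to target `t` is feasible iff for every
#' intact structure `i` the minimum (SDF-interpolated) distance from the
#' structure to the segment exceeds `r + d_risk_i`, i.e. the capsule of
#' radius `r + d_risk_i` about the segment misses the structure.
#'
#' @param k entry point(s): 3-vector or (n x 3) matrix, RAS mm.
#' @param t target point, RAS mm.
#' @param structures list of [critical_structure()] with role `intact_H`.
#' @param tool a [tool_model()].
#' @param step_mm SDF sampling step along the segment.
#' @return logical vector (length n): feasibility per entry.
#' @export
trajectory_feasible <- function(k, t, structures, tool,
                                step_mm = NULL) {
  k <- rbind(k)
  t <- as.numeric(t)
  if (any(apply(k, 1, function(p) isTRUE(all.equal(p, t)))))
    stop("entry and target coincide")
  for (s in structures)
    if (s$role != "intact_H") stop("structures must all have role intact_H")
  ok <- rep(TRUE, nrow(k))
  tm <- matrix(t, nrow(k), 3, byrow = TRUE)
  for (s in structures) {
    if (!any(ok)) break
    step <- if (is.null(step_mm)) s$sdf$grid$spacing_mm / 2 else step_mm
    mins <- sdf_min_along_segments(s$sdf, k[ok, , drop = FALSE],
                                   tm[ok, , drop = FALSE], step_mm = step)
    ok[ok] <- mins > tool$radius_mm + s$d_risk_mm
  }
  ok
}

#' Rasterize the open finite tool cylinder between an entry and a target
#'
#' A voxel is occupied iff its center lies within `r` of the line through
#' `k` and `t` and strictly between the end planes through `k` and `t`
#' orthogonal to the axis (caps excluded).
#'
#' @param k,t distinct RAS mm endpoints.
#' @param tool a [tool_model()].
#' @param grid the target [voxel_grid()].
#' @return A [binary_mask()].
#' @export
rasterize_cylinder <- function(k, t, tool, grid) {
  idx <- rasterize_cylinder_indices(k, t, tool, grid)
  occ <- array(FALSE, dim = grid$shape)
  occ[idx] <- TRUE
  binary_mask(grid, occ)
}

#' @rdname rasterize_cylinder
#' @return `rasterize_cylinder_indices()` returns the 1-based linear voxel
#'   indices only (the form the planner accumulates).
#' @export
rasterize_cylinder_indices <- function(k, t, tool, grid) {
  if (isTRUE(all.equal(as.numeric(k), as.numeric(t))))
    stop("entry and target coincide")
  cpp_rasterize_cylinder(grid$shape, grid$origin_mm, grid$spacing_mm,
                         as.numeric(k), as.numeric(t), tool$radius_mm)
}

#' Early-termination configuration for the entry traversal
#'
#' Traversal of the entry candidates for one target stops once the relative
#' volume contribution of newly traversed entries stays below `threshold`
#' for `window` consecutive entries.
#'
#' @param threshold relative-gain threshold (default 5e-4).
#' @param window number of consecutive sub-threshold entries required
#'   (default 25).
#' @param enabled logical; disable for exhaustive traversal.
#' @return An object of class `termination_config`.
#' @export
termination_config <- function(threshold = 5e-4, window = 25L,
                               enabled = TRUE) {
  structure(list(threshold = threshold, window = as.integer(window),
                 enabled = isTRUE(enabled)), class = "termination_config")
}

#' Relative volume gain of a newly traversed entry
#'
#' `G = (new - prev) * voxel_volume / (|kt| * pi * r^2)`: the volume the new
#' entry's cylinder added to the accumulating per-target mask, normalized by
#' the analytic cylinder volume.
#'
#' @param prev_mask_voxels,new_mask_voxels occupied-voxel counts before and
#'   after adding the entry's cylinder (`new >= prev`).
#' @param k,t entry and target, RAS mm.
#' @param tool a [tool_model()].
#' @param voxel_volume voxel volume in cubic mm.
#' @return scalar gain `G`.
#' @export
early_termination_gain <- function(prev_mask_voxels, new_mask_voxels, k, t,
                                   tool, voxel_volume) {
  stopifnot(new_mask_voxels >= prev_mask_voxels)
  len <- sqrt(sum((as.numeric(t) - as.numeric(k))^2))
  (new_mask_voxels - prev_mask_voxels) * voxel_volume /
    (len * pi * tool$radius_mm^2)
}

# deterministic near-to-far entry sweep: start from the entry closest to
# the approach line through the target centroid, then order by increasing
# distance from that seed entry (ties by original index)
entry_sweep_order <- function(entries, target_centroid) {
  c0 <- colMeans(entries)
  axis <- c0 - as.numeric(target_centroid)
  axis <- axis / sqrt(sum(axis^2))
  rel <- sweep(entries, 2, as.numeric(target_centroid))
  perp <- rel - (rel %*% axis) %*% t(axis)
  seed <- which.min(rowSums(perp^2))
  d2 <- rowSums(sweep(entries, 2, entries[seed, ])^2)
  order(d2, seq_len(nrow(entries)))
}

#' Generate the maximum permissible milling area
#'
#' For each target point, traverses the entry candidates in a deterministic
#' near-to-far sweep, accumulates the cylinders of feasible trajectories
#' into the per-target milling mask, and applies early termination on the
#' relative volume gain. The union over targets is the maximum milling
#' area: every occupied voxel lies inside at least one feasibility-checked
#' tool cylinder. Targets with no feasible entry are dropped with a
#' warning; if no target survives, an error is raised.
#'
#' @param targets numeric matrix (m x 3) of effective target points (the
#'   ordered downsampled boundary), RAS mm.
#' @param entries numeric matrix (n x 3) of entry candidates, RAS mm.
#' @param structures list of [critical_structure()]; only `intact_H`
#'   members constrain feasibility.
#' @param tool a [tool_model()].
#' @param grid the planning [voxel_grid()].
#' @param termination a [termination_config()].
#' @return An object of class `max_milling_area`: `per_target` (list of
#'   `target`, `entries` K(t), `voxel_idx`), `union_mask`, `dropped`
#'   (indices of excluded targets), `grid`, `tool`.
#' @export
generate_max_area <- function(targets, entries, structures, tool, grid,
                              termination = termination_config()) {
  targets <- rbind(targets)
  entries <- rbind(entries)
  intact <- split_structures(structures)$intact
  voxvol <- grid$spacing_mm^3
  centroid <- colMeans(targets)
  ord <- entry_sweep_order(entries, centroid)
  per_target <- vector("list", nrow(targets))
  dropped <- integer(0)
  occ <- array(FALSE, dim = grid$shape) # reused accumulator per target
  for (ti in seq_len(nrow(targets))) {
    t <- targets[ti, ]
    occ[] <- FALSE
    nvox <- 0L
    kept <- integer(0)
    idx_all <- list()
    below <- 0L
    for (ei in ord) {
      k <- entries[ei, ]
      if (!trajectory_feasible(k, t, intact, tool)) next
      cyl <- rasterize_cylinder_indices(k, t, tool, grid)
      new_idx <- cyl[!occ[cyl]]
      occ[new_idx] <- TRUE
      gain <- early_termination_gain(nvox, nvox + length(new_idx), k, t,
                                     tool, voxvol)
      nvox <- nvox + length(new_idx)
      kept <- c(kept, ei)
      idx_all <- c(idx_all, list(new_idx))
      if (termination$enabled) {
        below <- if (gain < termination$threshold) below + 1L else 0L
        if (below >= termination$window) break
      }
    }
    if (length(kept) == 0L) {
      dropped <- c(dropped, ti)
      warning(sprintf("target %d has no feasible entry; excluded", ti))
      next
    }
    per_target[[ti]] <- list(target = t,
                             entries = entries[kept, , drop = FALSE],
                             entry_rows = kept,
                             voxel_idx = sort(unlist(idx_all)))
  }
  survivors <- setdiff(seq_len(nrow(targets)), dropped)
  if (length(survivors) == 0L)
    stop("no target has a feasible entry; the plan is infeasible")
  occ[] <- FALSE
  for (ti in survivors) occ[per_target[[ti]]$voxel_idx] <- TRUE
  structure(list(per_target = per_target[survivors],
                 target_rows = survivors,
                 union_mask = binary_mask(grid, occ),
                 dropped = dropped, grid = grid, tool = tool),
            class = "max_milling_area")
}

#' @export
print.max_milling_area <- function(x, ...) {
  cat(sprintf("<max_milling_area: %d targets, %.0f mm^3 union, %d dropped>\n",
              length(x$per_target), mask_volume_mm3(x$union_mask),
              length(x$dropped)))
  invisible(x)
}
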