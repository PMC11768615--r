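#' Staged effective-target point set
#'
#' Stages of the target reduction: `T0` all surface voxels, `T1` after the
#' orientation filter, `T2` after the accessibility filter, `T3` the
#' ordered boundary contour, `T4` the arc-length-downsampled contour that
#' the optimizer receives. Later stages are subsets of earlier ones.
#'
#' @param stage one of `"T0"`..`"T4"`.
#' @param points_mm numeric matrix (n x 3), RAS mm (ordered for T3/T4).
#' @param normals optional unit normal matrix (n x 3).
#' @param r_counts optional per-point feasible-entry counts (stage T1).
#' @return An object of class `target_stage`.
#' @export
target_stage <- function(stage, points_mm, normals = NULL, r_counts = NULL) {
  structure(list(stage = stage, points_mm = rbind(points_mm),
                 normals = if (!is.null(normals)) rbind(normals),
                 r_counts = r_counts),
            class = "target_stage")
}

#' @export
print.target_stage <- function(x, ...) {
  cat(sprintf("<target_stage %s: %d points>\n", x$stage, nrow(x$points_mm)))
  invisible(x)
}

#' Outward surface normals of the target mask
#'
#' Surface voxels are occupied voxels with at least one background
#' 6-neighbor; their outward unit normal is the normalized central-
#' difference gradient of the target's signed distance field (positive
#' outside), which is robust on voxelized surfaces.
#'
#' @param target a [binary_mask()] with a non-degenerate surface.
#' @return A `target_stage` `"T0"` with `points_mm` and `normals`, plus the
#'   surface linear voxel indices as attribute `"voxel_index"`.
#' @export
estimate_surface_normals <- function(target) {
  stopifnot(inherits(target, "binary_mask"))
  if (sum(target$occupancy) < 2L)
    stop("target surface is degenerate (fewer than 2 voxels)")
  occ <- target$occupancy
  surf <- occ & !erode6(occ)
  idx <- which(surf, arr.ind = TRUE)
  sdf <- compute_sdf(target)
  nrm <- sdf_gradient_at(sdf, idx)
  st <- target_stage("T0", index_to_world(target$grid, idx), normals = nrm)
  attr(st, "voxel_index") <- which(surf)
  st
}

#' Orientation filter: keep surface points facing the entries
#'
#' For each surface point t, counts the entries k whose trajectory makes an
#' angle below pi/2 with the outward normal (`theta(t,k) = acos(n_t . tk)`),
#' recorded as `r_t`. A point is retained iff `r_t > mean(r)` (strict) and
#' `r_t > 0.05 * |K|`.
#'
#' @param t0 a `target_stage` `"T0"` from [estimate_surface_normals()].
#' @param entries numeric matrix (m x 3) of entry candidates.
#' @return A `target_stage` `"T1"` (with `r_counts`).
#' @export
filter_orientation <- function(t0, entries) {
  entries <- rbind(entries)
  if (nrow(entries) == 0L) stop("entries must be non-empty")
  pts <- t0$points_mm
  nrm <- t0$normals
  # theta < pi/2  <=>  n_t . (k - t) > 0; no normalization needed for sign
  A <- entries %*% t(nrm)                       # m x n: k . n_t
  b <- rowSums(pts * nrm)                       # n: t . n_t
  r_t <- colSums(A > matrix(b, nrow(entries), nrow(pts), byrow = TRUE))
  keep <- r_t > mean(r_t) & r_t > 0.05 * nrow(entries)
  if (!any(keep))
    stop("orientation filter removed every target point")
  st <- target_stage("T1", pts[keep, , drop = FALSE],
                     normals = nrm[keep, , drop = FALSE],
                     r_counts = r_t[keep])
  attr(st, "voxel_index") <- attr(t0, "voxel_index")[keep]
  st
}

#' Accessibility filter: keep points with at least one safe trajectory
#'
#' Entries are subsampled on a world-space grid of pitch `2r` (one
#' deterministic representative per cell: lowest index), and each point is
#' kept iff any subsampled entry passes [trajectory_feasible()]; the
#' per-point search stops at the first success.
#'
#' @param t1 a `target_stage` `"T1"`.
#' @param entries numeric matrix (m x 3) of entry candidates.
#' @param structures list of [critical_structure()] (intact members used).
#' @param tool a [tool_model()].
#' @return A `target_stage` `"T2"`.
#' @export
filter_accessible <- function(t1, entries, structures, tool) {
  entries <- rbind(entries)
  intact <- split_structures(structures)$intact
  cell <- floor(sweep(entries, 2, c(0, 0, 0)) / (2 * tool$radius_mm))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  rep_idx <- which(!duplicated(key))          # lowest index per cell
  sub <- entries[rep_idx, , drop = FALSE]
  keep <- logical(nrow(t1$points_mm))
  for (i in seq_len(nrow(t1$points_mm))) {
    t <- t1$points_mm[i, ]
    for (j in seq_len(nrow(sub))) {
      if (trajectory_feasible(sub[j, ], t, intact, tool)) {
        keep[i] <- TRUE
        break
      }
    }
  }
  st <- target_stage("T2", t1$points_mm[keep, , drop = FALSE],
                     normals = t1$normals[keep, , drop = FALSE])
  attr(st, "voxel_index") <- attr(t1, "voxel_index")[keep]
  st
}

# connected components of a voxel index set (rows of arr.ind), 26-connected
voxel_components <- function(idx, shape) {
  n <- nrow(idx)
  lin <- idx[, 1] + (idx[, 2] - 1L) * shape[1] +
    (idx[, 3] - 1L) * shape[1] * shape[2]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = lookup)
  comp <- integer(n)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(idx[v, ]), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 &
        nb[, 2] <= shape[2] & nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nl <- nb[ok, 1] + (nb[ok, 2] - 1) * shape[1] +
        (nb[ok, 3] - 1) * shape[1] * shape[2]
      for (l in nl) {
        j <- mget(as.character(l), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Ordered boundary contour of the accessible target patch
#'
#' Boundary points of T2 (points with at least one surface neighbor not in
#' T2), ordered clockwise by the polar angle of their projection onto the
#' control plane about the projected centroid. Clockwise is defined looking
#' along the plane normal (the +approach direction). If T2 is fragmented,
#' the largest 26-connected component is used with a warning.
#'
#' @param t2 a `target_stage` `"T2"` (with `"voxel_index"` attribute).
#' @param surface_index linear voxel indices of the full target surface
#'   (stage T0 attribute).
#' @param grid the [voxel_grid()] of the target mask.
#' @param plane a [control_plane()] used for the angular ordering.
#' @return A `target_stage` `"T3"` ordered as a closed loop.
#' @export
extract_ordered_contour <- function(t2, surface_index, grid, plane) {
  t2_lin <- attr(t2, "voxel_index")
  idx <- arrayInd(t2_lin, grid$shape)
  comp <- voxel_components(idx, grid$shape)
  if (max(comp) > 1L) {
    warning("accessible target patch is fragmented; using largest component")
    main <- which.max(tabulate(comp))
    sel <- comp == main
    idx <- idx[sel, , drop = FALSE]
    t2_lin <- t2_lin[sel]
  }
  in_t2 <- logical(prod(grid$shape)); in_t2[t2_lin] <- TRUE
  in_surf <- logical(prod(grid$shape)); in_surf[surface_index] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  boundary <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    nb <- sweep(offs, 2, as.numeric(idx[i, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid$shape[1] & nb[, 2] >= 1 &
      nb[, 2] <= grid$shape[2] & nb[, 3] >= 1 & nb[, 3] <= grid$shape[3]
    nl <- nb[ok, 1] + (nb[ok, 2] - 1) * grid$shape[1] +
      (nb[ok, 3] - 1) * grid$shape[1] * grid$shape[2]
    boundary[i] <- any(in_surf[nl] & !in_t2[nl])
  }
  if (sum(boundary) < 3L)
    stop("fewer than 3 boundary points; contour undefined")
  bidx <- idx[boundary, , drop = FALSE]
  pts <- index_to_world(grid, bidx)
  uv <- plane_project_uv(plane, pts)
  ctr <- colMeans(uv)
  ang <- atan2(uv[, 2] - ctr[2], uv[, 1] - ctr[1])
  ord <- order(-ang)    # decreasing angle = clockwise seen along the normal
  target_stage("T3", pts[ord, , drop = FALSE])
}

#' Downsample the ordered contour at the tool-radius interval
#'
#' Greedy arc-length walk along the closed loop: the first point is always
#' kept, and a point is emitted whenever the cumulative arc length since
#' the last emitted point reaches `r`, guaranteeing partial overlap between
#' adjacent access trajectories.
#'
#' @param t3 a `target_stage` `"T3"` (ordered loop).
#' @param tool a [tool_model()].
#' @return A `target_stage` `"T4"`.
#' @export
downsample_contour <- function(t3, tool) {
  pts <- t3$points_mm
  n <- nrow(pts)
  r <- tool$radius_mm
  keep <- 1L
  acc <- 0
  for (i in seq_len(n)[-1]) {
    acc <- acc + sqrt(sum((pts[i, ] - pts[i - 1L, ])^2))
    if (acc >= r) {
      keep <- c(keep, i)
      acc <- 0
    }
  }
  target_stage("T4", pts[keep, , drop = FALSE])
}

#' Run the full target-reduction chain T0 -> T4
#'
#' @param target the target [binary_mask()].
#' @param entries entry candidate matrix from [find_entry_candidates()].
#' @param structures list of [critical_structure()].
#' @param tool a [tool_model()].
#' @param plane a [control_plane()] for the contour ordering.
#' @return list of stages `t0`..`t4`.
#' @export
extract_targets <- function(target, entries, structures, tool, plane) {
  t0 <- estimate_surface_normals(target)
  t1 <- filter_orientation(t0, entries)
  t2 <- filter_accessible(t1, entries, structures, tool)
  t3 <- extract_ordered_contour(t2, attr(t0, "voxel_index"), target$grid,
                                plane)
  t4 <- downsample_contour(t3, tool)
  list(t0 = t0, t1 = t1, t2 = t2, t3 = t3, t4 = t4)
}

#' Export target stages as a tidy data frame
#' @param stages list of `target_stage` objects (as from
#'   [extract_targets()]).
#' @return data frame with columns `stage, idx, r_mm, a_mm, s_mm`.
#' @export
stages_to_df <- function(stages) {
  do.call(rbind, lapply(stages, function(st) {
    data.frame(stage = st$stage, idx = seq_len(nrow(st$points_mm)),
               r_mm = st$points_mm[, 1], a_mm = st$points_mm[, 2],
               s_mm = st$points_mm[, 3])
  }))
}
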