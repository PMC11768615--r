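#' Read a volume from NIfTI-1 into a mask or scalar field
#'
#' The affine must be axis-aligned in RAS (off-diagonal direction cosines
#' below `tol`) with isotropic spacing; otherwise an error names the
#' offending axis. Only such volumes can be placed on the package's
#' axis-aligned voxel lattice.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind `"mask"` (non-zero voxels occupied) or `"field"` (scalar mm).
#' @param tol tolerance on off-diagonal direction cosines.
#' @return A [binary_mask()] or [sdf_field()].
#' @export
read_volume_nifti <- function(path, kind = c("mask", "field"), tol = 1e-3) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  dir <- aff[1:3, 1:3]
  sp <- sqrt(colSums(dir^2))
  cos <- sweep(dir, 2, sp, "/")
  for (a in 1:3) {
    off <- abs(cos[, a]); off[a] <- 0
    if (any(off > tol))
      stop(sprintf("NIfTI affine is not axis-aligned on axis %d (%s)",
                   a, c("R", "A", "S")[a]))
    if (cos[a, a] < 0)
      stop(sprintf("NIfTI axis %d (%s) is flipped; expected +RAS orientation",
                   a, c("R", "A", "S")[a]))
  }
  if (diff(range(sp)) > tol * mean(sp))
    stop("NIfTI spacing is anisotropic; resample to isotropic spacing first")
  grid <- voxel_grid(dim(img)[1:3], mean(sp), aff[1:3, 4])
  arr <- as.array(img)
  if (kind == "mask") binary_mask(grid, arr != 0) else sdf_field(grid, arr)
}

#' Write a mask or scalar field to NIfTI-1
#'
#' @param volume a [binary_mask()] or [sdf_field()].
#' @param path output path (`.nii.gz`).
#' @export
write_volume_nifti <- function(volume, path) {
  g <- volume$grid
  arr <- if (inherits(volume, "binary_mask")) {
    array(as.integer(volume$occupancy), dim = g$shape)
  } else array(as.numeric(volume$values), dim = g$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(g$spacing_mm, 3)
  aff <- rbind(cbind(diag(3) * g$spacing_mm, g$origin_mm), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Critical anatomical structure with its planning role
#'
#' Structures either must remain intact (`role = "intact_H"`, carrying a
#' minimum safe distance `d_risk_mm` that the tool must keep) or should be
#' minimally damaged (`role = "minimize_S"`, carrying an injury weight
#' `lambda_weight`). The signed distance field is precomputed once so that
#' all later clearance queries are lookups.
#'
#' @param name structure name.
#' @param mask a [binary_mask()] of the structure.
#' @param role `"intact_H"` or `"minimize_S"`.
#' @param d_risk_mm safe distance in mm (intact structures only); defaults
#'   from [default_d_risk()] applied to `name`.
#' @param lambda_weight injury weight in `[0, 1]` (minimize structures only).
#' @return An object of class `critical_structure` (fields `name`, `mask`,
#'   `sdf`, `role`, `d_risk_mm`, `lambda_weight`).
#' @export
critical_structure <- function(name, mask, role = c("intact_H", "minimize_S"),
                               d_risk_mm = NULL, lambda_weight = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(mask, "binary_mask"))
  if (role == "intact_H") {
    if (is.null(d_risk_mm)) d_risk_mm <- default_d_risk(name)
    if (d_risk_mm < 0) stop("d_risk_mm must be non-negative")
    lambda_weight <- NULL
  } else {
    if (is.null(lambda_weight))
      stop("minimize_S structures need a lambda_weight")
    if (lambda_weight < 0 || lambda_weight > 1)
      stop("lambda_weight must lie in [0, 1]")
    d_risk_mm <- NULL
  }
  structure(list(name = name, mask = mask, sdf = compute_sdf(mask),
                 role = role, d_risk_mm = d_risk_mm,
                 lambda_weight = lambda_weight),
            class = "critical_structure")
}

#' Default minimum safe distances by structure class
#'
#' Clinical defaults: 2.5 mm for facial-nerve-class structures, 1.5 mm for
#' sinus-dura-class structures, and 0.5 mm for other critical structures
#' (scala, ossicles, carotid, chorda tympani, tympanic drum). Matching is by
#' substring of the structure name; unknown names get the generic 0.5 mm.
#'
#' @param name structure name (free text).
#' @return safe distance in mm.
#' @export
default_d_risk <- function(name) {
  n <- tolower(name)
  if (grepl("facial", n)) return(2.5)
  if (grepl("sinus", n)) return(1.5)
  0.5
}

#' Split structures by role
#' @param structures list of [critical_structure()].
#' @return list with elements `intact` and `minimize`.
#' @export
split_structures <- function(structures) {
  roles <- vapply(structures, function(s) s$role, character(1))
  list(intact = structures[roles == "intact_H"],
       minimize = structures[roles == "minimize_S"])
}
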