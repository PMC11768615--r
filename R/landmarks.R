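#' Named anatomical landmark set in RAS millimetres
#'
#' @param names character vector of unique landmark names.
#' @param points_mm numeric matrix (n x 3) of RAS mm positions.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(names, points_mm) {
  points_mm <- rbind(points_mm)
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (length(names) != nrow(points_mm))
    stop("names and points differ in length")
  structure(list(names = as.character(names),
                 points_mm = unname(points_mm)), class = "landmark_set")
}

#' Read landmarks from CSV (`name,r_mm,a_mm,s_mm`)
#' @param path CSV file path.
#' @return A [landmark_set()].
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "r_mm", "a_mm", "s_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have header name,r_mm,a_mm,s_mm")
  landmark_set(df$name, as.matrix(df[, c("r_mm", "a_mm", "s_mm")]))
}

#' Write landmarks to CSV (`name,r_mm,a_mm,s_mm`)
#' @param lm a [landmark_set()].
#' @param path output path.
#' @export
write_landmarks_csv <- function(lm, path) {
  df <- data.frame(name = lm$names, r_mm = lm$points_mm[, 1],
                   a_mm = lm$points_mm[, 2], s_mm = lm$points_mm[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid alignment of two landmark sets
#'
#' Kabsch/SVD solution of the orthogonal Procrustes problem over the common
#' landmark names: finds the proper rotation `R` and translation `b`
#' minimizing `sum || R x_i + b - y_i ||^2`. A reflection in the SVD
#' solution is corrected by flipping the sign of the smallest singular
#' direction, so the returned rotation always has determinant +1.
#'
#' @param source,dest [landmark_set()] objects sharing at least 3
#'   non-collinear landmark names.
#' @return list with `rotation` (3 x 3), `translation` (length 3), and
#'   `rmse_mm` of the aligned landmarks.
#' @export
rigid_align_landmarks <- function(source, dest) {
  common <- intersect(source$names, dest$names)
  if (length(common) < 3L)
    stop("need at least 3 common landmarks")
  X <- source$points_mm[match(common, source$names), , drop = FALSE]
  Y <- dest$points_mm[match(common, dest$names), , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity check: centered configuration must span a plane
  sv_conf <- svd(Xc)$d
  if (sv_conf[2] < 1e-9 * max(sv_conf[1], 1))
    stop("landmark configuration is collinear; rotation is not determined")
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  b <- cy - as.numeric(R %*% cx)
  fit <- sweep(X %*% t(R), 2, b, "+")
  rmse <- sqrt(mean(rowSums((fit - Y)^2)))
  list(rotation = R, translation = b, rmse_mm = rmse)
}

#' Apply a rigid transform to points
#' @param transform list with `rotation` and `translation`, as returned by
#'   [rigid_align_landmarks()].
#' @param pts numeric matrix (n x 3) or 3-vector, RAS mm.
#' @return transformed numeric matrix (n x 3).
#' @export
apply_rigid <- function(transform, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Invert a rigid transform
#' @param transform list with `rotation` and `translation`.
#' @return the inverse transform in the same form.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  list(rotation = Rt, translation = -as.numeric(Rt %*% transform$translation))
}
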