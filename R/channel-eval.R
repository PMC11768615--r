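#' Surgical channel decomposition
#'
#' The channel is the free space available to the tool after milling:
#' external space (outside the head region), the milled bone, and the
#' internal cavities reachable from them. Internal cavities are non-bone
#' voxels inside the head 6-connected to the milled volume or the exterior
#' through non-bone/milled voxels; sealed cavities are excluded.
#'
#' @param mill a [binary_mask()] of milled bone; must satisfy
#'   `mill` within `bone`.
#' @param bone the skull [binary_mask()].
#' @param head_region [binary_mask()] of the head (exterior = complement).
#' @return An object of class `surgical_channel` with masks `mill`,
#'   `internal`, `external`, `channel` (their union).
#' @export
build_channel <- function(mill, bone, head_region) {
  stopifnot(inherits(mill, "binary_mask"), inherits(bone, "binary_mask"))
  if (any(mill$occupancy & !bone$occupancy))
    stop("mill mask extends outside the bone mask")
  g <- mill$grid
  ex <- !head_region$occupancy
  open <- !bone$occupancy | mill$occupancy
  open <- open | ex
  visited <- array(cpp_flood_fill(as.logical(open), as.logical(ex), g$shape),
                   dim = g$shape)
  internal <- visited & !ex & !mill$occupancy
  channel <- visited
  structure(list(mill = mill,
                 internal = binary_mask(g, internal),
                 external = binary_mask(g, ex),
                 channel = binary_mask(g, channel),
                 grid = g),
            class = "surgical_channel")
}

#' @export
print.surgical_channel <- function(x, ...) {
  cat(sprintf("<surgical_channel: mill %d, internal %d, external %d voxels>\n",
              sum(x$mill$occupancy), sum(x$internal$occupancy),
              sum(x$external$occupancy)))
  invisible(x)
}

#' Deterministic quasi-uniform directions on a hemisphere
#'
#' Fibonacci-spiral directions on the hemisphere around `axis`, with a
#' seeded azimuthal phase so different seeds decorrelate the sampling while
#' staying reproducible.
#'
#' @param n number of directions (>= 32 for metric use).
#' @param axis hemisphere pole (unit 3-vector).
#' @param seed integer seed for the azimuthal phase.
#' @return numeric matrix (n x 3) of unit directions.
#' @export
hemisphere_directions <- function(n, axis = c(1, 0, 0), seed = 1L) {
  axis <- axis / sqrt(sum(axis^2))
  i <- seq_len(n) - 0.5
  z <- i / n                       # (0, 1]: hemisphere
  rho <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phase <- (seed %% 10007L) / 10007 * 2 * pi
  th <- ga * (seq_len(n) - 1) + phase
  local <- cbind(rho * cos(th), rho * sin(th), z)
  # orthonormal frame with axis as the pole
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  local %*% rbind(e1, e2, axis)
}

#' Spatial accessibility of the targets through the channel
#'
#' Per target, the fraction of `n_directions` deterministic hemisphere
#' directions (approach side) whose radius-`r` capsule ray from the target
#' to the grid boundary stays inside the channel; samples within `eps_mm`
#' of the target are exempt (the target's epsilon-ball). The capsule test
#' uses the channel's inner distance field, so a direction passes iff the
#' interpolated distance to non-channel space stays at or above `r` along
#' the ray. The accessibility is the mean over targets.
#'
#' @param channel a [build_channel()] result.
#' @param targets numeric matrix (m x 3) of target points, RAS mm.
#' @param tool a [tool_model()].
#' @param n_directions number of hemisphere directions (>= 32).
#' @param seed seed for the direction phase.
#' @param approach_axis hemisphere pole (default +R).
#' @param eps_mm epsilon-ball radius (default: one voxel).
#' @return scalar `mu_a` in `[0, 1]`, with per-target fractions as
#'   attribute `"per_target"`.
#' @export
accessibility <- function(channel, targets, tool, n_directions = 64L,
                          seed = 1L, approach_axis = c(1, 0, 0),
                          eps_mm = NULL) {
  targets <- rbind(targets)
  if (nrow(targets) == 0L) stop("empty target list")
  if (n_directions < 32L) stop("n_directions must be at least 32")
  g <- channel$grid
  if (is.null(eps_mm)) eps_mm <- g$spacing_mm
  dist <- cpp_edt3d(as.logical(!channel$channel$occupancy), g$shape,
                    g$spacing_mm)
  dirs <- hemisphere_directions(n_directions, approach_axis, seed)
  frac <- cpp_access_fraction(dist, g$shape, g$origin_mm, g$spacing_mm,
                              targets, dirs, tool$radius_mm, eps_mm,
                              g$spacing_mm / 2)
  mu <- mean(frac)
  attr(mu, "per_target") <- frac
  mu
}

#' Injury objective: weighted damaged-volume fractions
#'
#' `Q_i = lambda_bone * V(mill)/V(bone) + sum_j lambda_j *
#' V(mill intersect S_j)/V(S_j)`, with the weights summing to one.
#'
#' @param mill the milled [binary_mask()] (restricted to bone).
#' @param bone the skull [binary_mask()].
#' @param s_structures list of [critical_structure()] with role
#'   `minimize_S` (their `lambda_weight` fields are the weights).
#' @param lambda_bone weight of the bone term.
#' @return scalar `Q_i >= 0`.
#' @export
injury <- function(mill, bone, s_structures, lambda_bone = 0.5) {
  if (!any(bone$occupancy)) stop("bone mask is empty")
  lambdas <- vapply(s_structures, function(s) s$lambda_weight, numeric(1))
  if (any(c(lambda_bone, lambdas) < 0)) stop("weights must be non-negative")
  if (abs(lambda_bone + sum(lambdas) - 1) > 1e-9)
    stop("injury weights must sum to 1")
  q <- lambda_bone * sum(mill$occupancy) / sum(bone$occupancy)
  for (s in s_structures) {
    vs <- sum(s$mask$occupancy)
    if (vs == 0L) next
    q <- q + s$lambda_weight * sum(mill$occupancy & s$mask$occupancy) / vs
  }
  q
}

#' Global spatial compactness of a volume
#'
#' Obstacle-aware sum of inverse pairwise distances over the ordered voxel
#' pairs of the volume: pairs without line of sight (the voxel-stepped
#' segment leaves the volume) contribute zero (distance set to infinity).
#' For tractability the full double sum is estimated from a seeded sample
#' of voxels (without replacement) and scaled by `n*(n-1)`; the exhaustive
#' sum is available as an oracle mode.
#'
#' @param mask a [binary_mask()] (the milling volume by default; pass the
#'   channel mask to score the full channel).
#' @param n_samples voxels to sample (>= 2); ignored in exhaustive mode.
#' @param seed sampling seed.
#' @param exhaustive if TRUE, sum over all voxel pairs.
#' @param step_mm line-of-sight stepping (default: half voxel).
#' @return scalar `mu_gsc` (mm^-1 scale), with the sample size used as
#'   attribute `"n_samples"`.
#' @export
compactness <- function(mask, n_samples = 200L, seed = 1L,
                        exhaustive = FALSE, step_mm = NULL) {
  g <- mask$grid
  if (is.null(step_mm)) step_mm <- g$spacing_mm / 2
  idx <- which(mask$occupancy)
  n <- length(idx)
  if (n == 0L) stop("mask is empty")
  if (n == 1L) return(structure(0, n_samples = 1L))
  if (n_samples < 2L) stop("n_samples must be at least 2")
  if (exhaustive || n <= n_samples) {
    sub <- idx
  } else {
    # draw with a private RNG state so metric evaluation never disturbs
    # the caller's random stream (the optimizer shares the global RNG)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    sub <- sample(idx, n_samples)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }
  res <- cpp_compactness_sum(as.logical(mask$occupancy), g$shape,
                             g$spacing_mm, as.integer(sub - 1L), step_mm)
  mean_unordered <- res$sum_unordered / res$n_unordered
  mu <- mean_unordered * n * (n - 1)   # ordered-pair total
  structure(mu, n_samples = length(sub))
}

#' Spectral-arc-length smoothness of the plan's boundary contour
#'
#' The union of the (deformed) per-target area rasters on the control
#' plane, `U = 1 - prod_t (1 - B_t)`, defines the plan's 2-D boundary. Its
#' outer contour is resampled to `n_resample` uniform arc-length points;
#' the unit tangent signal (first derivative of position with respect to
#' arc length, complex-valued) is Fourier-transformed with zero-padding,
#' and the spectral arc length of the max-normalized magnitude spectrum up
#' to the cutoff `omega_c` (cycles per contour circuit) is returned:
#' `mu_sa = -int_0^omega_c sqrt((1/omega_c)^2 + (dVhat/domega)^2) domega`.
#' Values are non-positive; closer to zero means smoother.
#'
#' The tangent signal is periodic, so its exact spectrum lives on integer
#' cycles per circuit; the default FFT length equals the resampling count
#' (no zero-padding), and the two-sided magnitude spectrum is folded onto
#' positive frequencies so the contour's traversal orientation is
#' irrelevant. A longer `n_fft` interpolates the spectrum between
#' harmonics (with the attendant Dirichlet leakage) and is exposed for
#' experimentation only.
#'
#' @param areas list of `area_function` (deformed), or a single logical
#'   raster matrix.
#' @param pixel_mm raster pitch (taken from the areas when omitted).
#' @param omega_c spectral cutoff in cycles per circuit (default 20).
#' @param n_resample contour resampling count (default 512).
#' @param n_fft FFT length (default: `n_resample`, the exact harmonic
#'   spectrum).
#' @return scalar `mu_sa <= 0`.
#' @export
boundary_smoothness <- function(areas, pixel_mm = NULL, omega_c = 20,
                                n_resample = 512L, n_fft = n_resample) {
  if (is.matrix(areas)) {
    U <- areas
    if (is.null(pixel_mm)) pixel_mm <- 1
  } else {
    U <- Reduce(`|`, lapply(areas, function(a) a$raster))
    if (is.null(pixel_mm)) pixel_mm <- areas[[1]]$plane$pixel_mm
  }
  if (!any(U)) stop("union raster is empty")
  contour <- outer_contour(U, pixel_mm)
  if (nrow(contour) < 8L) stop("contour has fewer than 8 points")
  spectral_arc_length(contour, omega_c = omega_c, n_resample = n_resample,
                      n_fft = n_fft)
}

# longest closed 0.5-level contour of a binary raster (mm coordinates)
outer_contour <- function(U, pixel_mm) {
  pad <- matrix(0, nrow(U) + 2L, ncol(U) + 2L)
  pad[1 + seq_len(nrow(U)), 1 + seq_len(ncol(U))] <- U * 1
  x <- (seq_len(nrow(pad)) - 1) * pixel_mm
  y <- (seq_len(ncol(pad)) - 1) * pixel_mm
  cl <- grDevices::contourLines(x, y, pad, levels = 0.5)
  if (length(cl) == 0L) stop("no contour found")
  area <- vapply(cl, function(cc) {
    xx <- cc$x; yy <- cc$y
    abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
  }, numeric(1))
  cc <- cl[[which.max(area)]]
  pts <- cbind(cc$x, cc$y)
  if (!isTRUE(all.equal(pts[1, ], pts[nrow(pts), ])))
    pts <- rbind(pts, pts[1, ])
  pts
}

# Spectral arc length of the unit-tangent signal of a closed curve. The
# tangent is complex-valued, so its spectrum is two-sided; the negative-
# frequency half is folded onto the positive axis (magnitudes added) so
# the result does not depend on the traversal orientation of the contour.
# Without zero-padding (n_fft = n_resample) the bins are the exact Fourier
# harmonics of the periodic tangent (integer cycles per circuit).
spectral_arc_length <- function(pts, omega_c, n_resample, n_fft) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- seg > 0
  pts <- pts[c(TRUE, keep), , drop = FALSE]
  seg <- seg[keep]
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  su <- seq(0, total, length.out = n_resample + 1L)[-(n_resample + 1L)]
  xs <- stats::approx(s, pts[, 1], xout = su)$y
  ys <- stats::approx(s, pts[, 2], xout = su)$y
  ds <- total / n_resample
  z <- complex(real = xs, imaginary = ys)
  tangent <- (c(z[-1], z[1]) - z) / ds     # unit-speed derivative, periodic
  spec <- abs(stats::fft(c(tangent, rep(0, n_fft - n_resample))))
  # bin k (0-based) corresponds to k * n_resample / n_fft cycles per circuit
  domega <- n_resample / n_fft
  kmax <- min(floor((n_fft - 1L) / 2), floor(omega_c / domega))
  v <- spec[1:(kmax + 1L)]
  v[-1] <- v[-1] + spec[n_fft + 1L - seq_len(kmax)]  # fold negative freqs
  v <- v / max(v)
  -sum(sqrt((domega / omega_c)^2 + diff(v)^2))
}

#' Constructability objective
#'
#' `Q_c = -(mu_gsc / mu_gsc_ref) * exp(mu_sa)`: compactness normalized by
#' its value on the maximum milling area, damped by the exponentiated
#' boundary smoothness. More negative is better; the maximum area with a
#' perfectly smooth boundary anchors at -1.
#'
#' @param mu_gsc compactness of the candidate volume.
#' @param mu_gsc_ref compactness of the maximum milling area (> 0).
#' @param mu_sa spectral-arc-length smoothness (<= 0).
#' @return scalar `Q_c`.
#' @export
constructability <- function(mu_gsc, mu_gsc_ref, mu_sa) {
  if (mu_gsc_ref <= 0) stop("mu_gsc_ref must be positive")
  -(mu_gsc / mu_gsc_ref) * exp(mu_sa)
}

#' Evaluation settings for the channel metrics
#'
#' @param n_directions hemisphere directions for [accessibility()].
#' @param access_seed,compact_seed metric sampling seeds (fixed per
#'   problem so objective evaluation is deterministic in the parameters).
#' @param compact_samples voxel sample size for [compactness()].
#' @param lambda_bone bone weight of the injury objective; the remaining
#'   weight is split equally among the minimize-S structures.
#' @param omega_c,n_resample,n_fft smoothness spectral settings.
#' @param approach_axis hemisphere pole for accessibility.
#' @param compactness_on `"mill"` (default) or `"channel"`.
#' @return list of class `eval_config`.
#' @export
eval_config <- function(n_directions = 64L, access_seed = 11L,
                        compact_samples = 200L, compact_seed = 12L,
                        lambda_bone = 0.5, omega_c = 20, n_resample = 512L,
                        n_fft = n_resample, approach_axis = c(1, 0, 0),
                        compactness_on = c("mill", "channel")) {
  structure(list(n_directions = as.integer(n_directions),
                 access_seed = as.integer(access_seed),
                 compact_samples = as.integer(compact_samples),
                 compact_seed = as.integer(compact_seed),
                 lambda_bone = lambda_bone, omega_c = omega_c,
                 n_resample = as.integer(n_resample),
                 n_fft = as.integer(n_fft),
                 approach_axis = approach_axis,
                 compactness_on = match.arg(compactness_on)),
            class = "eval_config")
}

#' Evaluate all channel metrics for a candidate milling volume
#'
#' @param mill candidate milling [binary_mask()] (clipped to bone).
#' @param areas the deformed per-target area functions (for smoothness).
#' @param scene list with `bone`, `head_region`, `structures` (a phantom
#'   scene or equivalent).
#' @param targets effective target points (m x 3).
#' @param tool a [tool_model()].
#' @param mu_gsc_ref reference compactness of the maximum milling area.
#' @param config an [eval_config()].
#' @return list of class `evaluation_result`: `mu_a`, `Q_a`, `Q_i`,
#'   `mu_gsc`, `mu_gsc_ref`, `mu_sa`, `Q_c`.
#' @export
evaluate_plan <- function(mill, areas, scene, targets, tool, mu_gsc_ref,
                          config = eval_config()) {
  sset <- split_structures(scene$structures)
  nS <- length(sset$minimize)
  lam <- if (nS > 0) (1 - config$lambda_bone) / nS else 0
  s_structs <- lapply(sset$minimize, function(s) {
    s$lambda_weight <- lam
    s
  })
  chan <- build_channel(mill, scene$bone, scene$head_region)
  mu_a <- accessibility(chan, targets, tool,
                        n_directions = config$n_directions,
                        seed = config$access_seed,
                        approach_axis = config$approach_axis)
  q_i <- injury(mill, scene$bone, s_structs, lambda_bone = config$lambda_bone)
  cmask <- if (config$compactness_on == "mill") mill else chan$channel
  mu_gsc <- compactness(cmask, n_samples = config$compact_samples,
                        seed = config$compact_seed)
  mu_sa <- boundary_smoothness(areas, omega_c = config$omega_c,
                               n_resample = config$n_resample,
                               n_fft = config$n_fft)
  structure(list(mu_a = as.numeric(mu_a), Q_a = -as.numeric(mu_a),
                 Q_i = q_i, mu_gsc = as.numeric(mu_gsc),
                 mu_gsc_ref = mu_gsc_ref, mu_sa = mu_sa,
                 Q_c = constructability(as.numeric(mu_gsc), mu_gsc_ref,
                                        mu_sa)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation: mu_a %.3f  Q_i %.4f  mu_gsc %.3g  mu_sa %.3f  Q_c %.4f>\n",
    x$mu_a, x$Q_i, x$mu_gsc, x$mu_sa, x$Q_c))
  invisible(x)
}
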