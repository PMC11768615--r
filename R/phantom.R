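#' Specification of the synthetic temporal-bone phantom
#'
#' The phantom emulates the constraint topology of a translabyrinthine
#' mastoidectomy scene with closed-form shapes: a lateral bone slab of
#' sinusoidally varying thickness (outer skull surface at high R), a deep
#' ellipsoidal target (acoustic-neuroma-like), tube-shaped nerve/vessel
#' structures and a sheet-shaped sinus-dura-like structure flanking the
#' feasible corridor, and one small tube-shaped scala-like structure (role
#' minimize-S) embedded in the bone slab at the edge of the milled bundle,
#' so that milling can actually damage it and injury trade-offs are
#' exercised. A guaranteed-clear corridor capsule is validated at build
#' time against every intact structure.
#'
#' All positions are RAS mm on a grid spanning `[0, extent_mm]` per axis.
#' The seed perturbs the bone-thickness modulation phase only, so scenes
#' vary with the seed while every closed-form parameter stays exact for
#' analytic oracles.
#'
#' @param seed integer; drives the bone modulation phase.
#' @param spacing_mm isotropic voxel size (default 1.0 mm, the phantom's
#'   standard test resolution).
#' @param extent_mm world extent per axis (grid covers `[0, extent_mm]`).
#' @param tool_radius_mm tool radius used in the corridor clearance
#'   validation.
#' @param bone list: `x_outer`, `x_inner` (slab bounds along R, mm),
#'   `mod_amp` and `mod_period` of the inner-surface sinusoidal modulation.
#' @param head_x_max head region is `R <= head_x_max` (exterior beyond).
#' @param target list: ellipsoid `center` and `semi_axes` (mm).
#' @param intact list of intact-structure definitions (capsules/sheets with
#'   `d_risk`).
#' @param minimize list of minimize-structure definitions (capsules with
#'   `lambda`).
#' @param corridor list: `p0`, `p1`, `radius` of the guaranteed-clear
#'   capsule.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         spacing_mm = 1.0,
                         extent_mm = 60,
                         tool_radius_mm = 1.5,
                         bone = list(x_outer = 46, x_inner = 36,
                                     mod_amp = 2, mod_period = 20),
                         head_x_max = 46,
                         target = list(center = c(18, 30, 30),
                                       semi_axes = c(6, 6.5, 6.5)),
                         intact = list(
                           list(type = "capsule", name = "facial_nerve",
                                p0 = c(28, 14, 6), p1 = c(28, 14, 54),
                                radius = 1.5, d_risk = 2.5),
                           list(type = "sheet", name = "sinus_dura",
                                center = c(33, 47, 30),
                                half_size = c(13, 1.5, 22), d_risk = 1.5),
                           list(type = "capsule", name = "ossicle_chain",
                                p0 = c(24, 30, 12), p1 = c(30, 30, 8),
                                radius = 2, d_risk = 0.5)),
                         minimize = list(
                           list(type = "capsule", name = "scala_vestibuli",
                                p0 = c(37, 18, 26), p1 = c(37, 18, 34),
                                radius = 2, lambda = 0.5)),
                         corridor = list(p0 = c(46, 30, 30),
                                         p1 = c(18, 30, 30), radius = 8)) {
  spec <- structure(list(seed = as.integer(seed), spacing_mm = spacing_mm,
                         extent_mm = extent_mm,
                         tool_radius_mm = tool_radius_mm, bone = bone,
                         head_x_max = head_x_max, target = target,
                         intact = intact, minimize = minimize,
                         corridor = corridor),
                    class = "phantom_spec")
  spec
}

phantom_grid <- function(spec) {
  n <- as.integer(round(spec$extent_mm / spec$spacing_mm)) + 1L
  voxel_grid(c(n, n, n), spec$spacing_mm, c(0, 0, 0))
}

# voxel-center coordinate arrays of a grid (three 3-D arrays)
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing_mm)
  list(x = array(rep(ax[[1]], times = prod(grid$shape[2:3])), dim = grid$shape),
       y = array(rep(rep(ax[[2]], each = grid$shape[1]),
                     times = grid$shape[3]), dim = grid$shape),
       z = array(rep(ax[[3]], each = prod(grid$shape[1:2])), dim = grid$shape))
}

rasterize_shape <- function(entry, grid, co = grid_coords(grid)) {
  occ <- switch(entry$type,
    capsule = {
      p0 <- entry$p0; p1 <- entry$p1
      u <- p1 - p0; L2 <- sum(u^2)
      wx <- co$x - p0[1]; wy <- co$y - p0[2]; wz <- co$z - p0[3]
      tpar <- pmin(1, pmax(0, (wx * u[1] + wy * u[2] + wz * u[3]) / L2))
      d2 <- (wx - tpar * u[1])^2 + (wy - tpar * u[2])^2 + (wz - tpar * u[3])^2
      d2 <= entry$radius^2
    },
    sheet = {
      abs(co$x - entry$center[1]) <= entry$half_size[1] &
        abs(co$y - entry$center[2]) <= entry$half_size[2] &
        abs(co$z - entry$center[3]) <= entry$half_size[3]
    },
    ellipsoid = {
      ((co$x - entry$center[1]) / entry$semi_axes[1])^2 +
        ((co$y - entry$center[2]) / entry$semi_axes[2])^2 +
        ((co$z - entry$center[3]) / entry$semi_axes[3])^2 <= 1
    },
    stop("unsupported shape type: ", entry$type))
  binary_mask(grid, occ)
}

#' Generate the synthetic phantom scene
#'
#' Rasterizes every closed-form shape of the spec onto one voxel grid,
#' builds [critical_structure()] objects (with precomputed SDFs), and
#' validates at build time that the guaranteed corridor capsule clears
#' every intact structure by more than `tool_radius + d_risk`. The manifest
#' echoes every closed-form parameter so tests can build analytic distance
#' oracles. Identical specs produce bitwise-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid`, `bone`, `target`, `head_region`
#'   ([binary_mask()]s), `structures` (list of [critical_structure()]),
#'   `corridor`, `manifest` (the spec's closed-form parameters), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  # corridor clearance validation against each intact structure (analytic)
  for (entry in spec$intact) {
    d <- analytic_min_distance(entry, spec$corridor$p0, spec$corridor$p1)
    need <- spec$corridor$radius + spec$tool_radius_mm + entry$d_risk
    if (d <= need)
      stop(sprintf(
        "corridor clearance validation failed for structure '%s': %.2f <= %.2f mm",
        entry$name, d, need))
  }
  grid <- phantom_grid(spec)
  co <- grid_coords(grid)
  phase <- (spec$seed %% 97) / 97 * 2 * pi
  w <- 2 * pi / spec$bone$mod_period
  x_inner <- spec$bone$x_inner +
    spec$bone$mod_amp * sin(w * co$y + phase) * sin(w * co$z + phase / 2)
  bone <- binary_mask(grid, co$x >= x_inner & co$x <= spec$bone$x_outer)
  head_region <- binary_mask(grid, co$x <= spec$head_x_max)
  target <- rasterize_shape(c(list(type = "ellipsoid"), spec$target), grid, co)
  structures <- c(
    lapply(spec$intact, function(e)
      critical_structure(e$name, rasterize_shape(e, grid, co),
                         role = "intact_H", d_risk_mm = e$d_risk)),
    lapply(spec$minimize, function(e)
      critical_structure(e$name, rasterize_shape(e, grid, co),
                         role = "minimize_S", lambda_weight = e$lambda)))
  for (s in structures)
    if (s$role == "intact_H" && any(s$mask$occupancy & target$occupancy))
      stop(sprintf("intact structure '%s' intersects the target", s$name))
  manifest <- list(seed = spec$seed, spacing_mm = spec$spacing_mm,
                   extent_mm = spec$extent_mm,
                   tool_radius_mm = spec$tool_radius_mm,
                   bone = spec$bone, head_x_max = spec$head_x_max,
                   target = spec$target, intact = spec$intact,
                   minimize = spec$minimize, corridor = spec$corridor,
                   bone_phase = phase)
  list(grid = grid, bone = bone, target = target, head_region = head_region,
       structures = structures, corridor = spec$corridor,
       manifest = manifest, spec = spec)
}

#' Closed-form minimum distance from a segment to a phantom shape surface
#'
#' The analytic oracle for trajectory-clearance tests. Exact for capsules
#' (segment-to-segment distance minus radius) and sheets/boxes (convex 1-D
#' minimization of the closed-form point-to-box distance along the segment,
#' converged far below voxel scale); ellipsoids use a dense-surface-sampling
#' fallback accurate to about 0.05 mm. Negative values mean the segment
#' pierces the shape.
#'
#' @param entry a shape entry from the phantom manifest (`type` one of
#'   `"capsule"`, `"sheet"`, `"ellipsoid"`).
#' @param p0,p1 segment endpoints, RAS mm.
#' @return scalar signed distance in mm.
#' @export
analytic_min_distance <- function(entry, p0, p1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  switch(entry$type,
    capsule = segment_segment_distance(p0, p1, entry$p0, entry$p1) -
      entry$radius,
    sheet = {
      f <- function(u) point_box_signed_distance(p0 + u * (p1 - p0),
                                                 entry$center, entry$half_size)
      golden_min(f, 0, 1, tol = 1e-10)
    },
    ellipsoid = {
      surf <- ellipsoid_surface_points(entry$center, entry$semi_axes, 50000L)
      us <- seq(0, 1, length.out = 400L)
      best <- Inf
      for (u in us) {
        p <- p0 + u * (p1 - p0)
        d <- sqrt(min((surf[, 1] - p[1])^2 + (surf[, 2] - p[2])^2 +
                        (surf[, 3] - p[3])^2))
        inside <- sum(((p - entry$center) / entry$semi_axes)^2) <= 1
        d <- if (inside) -d else d
        if (d < best) best <- d
      }
      best
    },
    stop("unsupported shape type: ", entry$type))
}

# minimum distance between two 3-D segments (standard clamped closed form)
segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r^2)))
  if (a <= 1e-12) { s <- 0; t <- min(1, max(0, f / e)) }
  else {
    c_ <- sum(d1 * r)
    if (e <= 1e-12) { t <- 0; s <- min(1, max(0, -c_ / a)) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-12) min(1, max(0, (b * f - c_ * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -c_ / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c_) / a)) }
    }
  }
  sqrt(sum((p1 + s * d1 - (p2 + t * d2))^2))
}

# signed distance from a point to an axis-aligned box surface
point_box_signed_distance <- function(p, center, half_size) {
  q <- abs(p - center) - half_size
  outside <- sqrt(sum(pmax(q, 0)^2))
  inside <- min(max(q), 0)
  outside + inside
}

golden_min <- function(f, lo, hi, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2) }
  }
  min(f1, f2)
}

# quasi-uniform surface points of an ellipsoid (Fibonacci sphere, scaled)
ellipsoid_surface_points <- function(center, semi_axes, n = 20000L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  dirs <- cbind(rho * cos(th), rho * sin(th), z)
  sweep(sweep(dirs, 2, semi_axes, "*"), 2, center, "+")
}
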