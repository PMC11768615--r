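#' Build the three-objective planning problem
#'
#' Returns a pure objective function mapping a parameter vector (row-major
#' over targets, N values per target) to `(Q_c, Q_a, Q_i)`: the parameter
#' set deforms the per-target area functions, the surviving cells'
#' cylinders are unioned and clipped to bone, the surgical channel is
#' rebuilt and the three metrics evaluated with fixed seeds, so the
#' function is deterministic in the parameters. Spatial feasibility is
#' structural (only feasibility-checked cylinders are ever instantiated),
#' so the only constraints are the box bounds. A vanished plan (every
#' area deformed to empty) is penalized with objectives `(1e6, 1e6, 1e6)`
#' rather than raising, keeping the evolutionary loop total.
#'
#' @param areas per-target `area_function` list (from
#'   [build_area_functions()]).
#' @param scene list with `bone`, `head_region`, `structures`, `grid`.
#' @param targets effective target points (m x 3), one per area.
#' @param tool a [tool_model()].
#' @param config an [eval_config()].
#' @return list of class `planning_problem`: `fn`, `n_var`, `n_targets`,
#'   `n_points`, `mu_gsc_ref`, `cache`, plus the inputs.
#' @export
make_problem <- function(areas, scene, targets, tool,
                         config = eval_config(), n_points = 8L) {
  targets <- rbind(targets)
  stopifnot(length(areas) == nrow(targets))
  grid <- scene$grid
  cache <- precompute_cylinders(areas, tool, grid)
  nt <- length(areas)
  # reference compactness: the all-ones (maximum-area) reconstruction
  mill0 <- reconstruct_milling(parameter_set(nt, n_points), areas, tool,
                               grid, cache)
  mill0 <- clip_to_bone(mill0, scene$bone)
  mu_ref <- as.numeric(compactness(mill0,
                                   n_samples = config$compact_samples,
                                   seed = config$compact_seed))
  fn <- function(x) {
    params <- matrix(pmin(1, pmax(1e-3, x)), nt, n_points)
    res <- tryCatch({
      deformed <- lapply(seq_len(nt), function(i)
        deform_area(areas[[i]], control_function(params[i, ])))
      occ <- array(FALSE, dim = grid$shape)
      any_cell <- FALSE
      for (i in seq_len(nt)) {
        B <- deformed[[i]]
        rows <- unique(B$entry_map[B$raster & B$entry_map > 0L])
        if (length(rows) == 0L) next
        any_cell <- TRUE
        sel <- match(rows, cache[[i]]$rows)
        occ[unlist(cache[[i]]$cylinders[sel], use.names = FALSE)] <- TRUE
      }
      if (!any_cell) stop("plan vanished")
      mill <- clip_to_bone(binary_mask(grid, occ), scene$bone)
      if (!any(mill$occupancy)) stop("plan vanished")
      ev <- evaluate_plan(mill, deformed, scene, targets, tool, mu_ref,
                          config)
      c(ev$Q_c, ev$Q_a, ev$Q_i)
    }, error = function(e) c(1e6, 1e6, 1e6))
    res
  }
  structure(list(fn = fn, n_var = nt * n_points, n_targets = nt,
                 n_points = n_points, mu_gsc_ref = mu_ref, cache = cache,
                 areas = areas, scene = scene, targets = targets,
                 tool = tool, eval_config = config),
            class = "planning_problem")
}

#' Restrict a milling mask to the bone it can actually remove
#' @param mill,bone [binary_mask()]s on the same grid.
#' @return A [binary_mask()] of their intersection.
#' @export
clip_to_bone <- function(mill, bone) {
  binary_mask(mill$grid, mill$occupancy & bone$occupancy)
}

#' Select the final plan from a Pareto front
#'
#' Candidate one is the compromise-programming pick: the solution with
#' minimal Euclidean distance to the ideal point on min-max-normalized
#' objectives. Candidate two is the pseudo-weight pick with equal weights
#' (1/3, 1/3, 1/3). The final plan is whichever of the two has the larger
#' compactness of its reconstructed milling volume.
#'
#' @param front a `pareto_result` from [run_nsga3()].
#' @param mu_gsc_of function(parameter vector) -> compactness of the
#'   reconstructed mill; used only to break the two-candidate tie.
#' @return list: `index` (row in the front), `parameters`, `objectives`,
#'   `provenance` (`"degenerate front"`, `"agreement"`, `"compromise"`,
#'   or `"pseudo_weight"`).
#' @export
select_solution <- function(front, mu_gsc_of = NULL) {
  obj <- front$objectives
  n <- nrow(obj)
  if (n == 1L)
    return(list(index = 1L, parameters = front$parameters[1, ],
                objectives = obj[1, ], provenance = "degenerate front"))
  rng <- apply(obj, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span < 1e-12] <- 1
  norm <- sweep(sweep(obj, 2, rng[1, ]), 2, span, "/")
  i_comp <- which.min(rowSums(norm^2))
  # pseudo-weights: normalized distance-to-worst ratios per objective
  pw <- sweep(sweep(-obj, 2, -rng[2, ]), 2, span, "/")  # (max - f) / span
  pw <- pw / rowSums(pw)
  i_pw <- which.min(rowSums((pw - 1 / 3)^2))
  if (i_comp == i_pw)
    return(list(index = i_comp, parameters = front$parameters[i_comp, ],
                objectives = obj[i_comp, ], provenance = "agreement"))
  if (is.null(mu_gsc_of)) {
    pick <- i_comp
    prov <- "compromise"
  } else {
    g1 <- mu_gsc_of(front$parameters[i_comp, ])
    g2 <- mu_gsc_of(front$parameters[i_pw, ])
    if (g1 >= g2) { pick <- i_comp; prov <- "compromise" }
    else { pick <- i_pw; prov <- "pseudo_weight" }
  }
  list(index = pick, parameters = front$parameters[pick, ],
       objectives = obj[pick, ], provenance = prov)
}

#' Optimize the milling plan end to end
#'
#' Builds the planning problem, runs NSGA-III, and selects the final
#' solution from the Pareto front; also reconstructs the selected milling
#' mask and the all-ones baseline for comparison.
#'
#' @param problem a [make_problem()] result.
#' @param opt_config an [optimization_config()].
#' @return list of class `plan_result`: `front`, `selection`, `mill`
#'   (selected mask, clipped to bone), `mill_baseline` (all-ones),
#'   `objectives_baseline`, `problem`.
#' @export
optimize_plan <- function(problem, opt_config = optimization_config()) {
  front <- run_nsga3(problem$fn, problem$n_var, opt_config)
  mu_of <- function(p) {
    params <- matrix(p, problem$n_targets, problem$n_points)
    mill <- tryCatch(
      clip_to_bone(reconstruct_milling(params, problem$areas, problem$tool,
                                       problem$scene$grid, problem$cache),
                   problem$scene$bone),
      error = function(e) NULL)
    if (is.null(mill)) return(-Inf)
    as.numeric(compactness(mill,
                           n_samples = problem$eval_config$compact_samples,
                           seed = problem$eval_config$compact_seed))
  }
  sel <- select_solution(front, mu_of)
  params_sel <- matrix(sel$parameters, problem$n_targets, problem$n_points)
  mill <- clip_to_bone(
    reconstruct_milling(params_sel, problem$areas, problem$tool,
                        problem$scene$grid, problem$cache),
    problem$scene$bone)
  ones <- parameter_set(problem$n_targets, problem$n_points)
  mill0 <- clip_to_bone(
    reconstruct_milling(ones, problem$areas, problem$tool,
                        problem$scene$grid, problem$cache),
    problem$scene$bone)
  structure(list(front = front, selection = sel, mill = mill,
                 mill_baseline = mill0,
                 objectives_baseline = problem$fn(as.numeric(ones)),
                 problem = problem),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  o <- x$selection$objectives
  cat(sprintf(
    "<plan_result: Q_c %.4f  Q_a %.4f  Q_i %.4f (%s; front of %d)>\n",
    o[1], o[2], o[3], x$selection$provenance, nrow(x$front$parameters)))
  invisible(x)
}
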