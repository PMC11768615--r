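#' Planning-run configuration
#'
#' Validated container for every tunable of a planning run. Numeric fields
#' are range-checked at construction and unknown keys are rejected, so a
#' malformed YAML fails before any computation.
#'
#' @param seed global seed; every stochastic component derives its seed
#'   from it.
#' @param tool_radius_mm cylindrical tool radius (mm).
#' @param planning_spacing_mm lattice resolution for planning; volumes are
#'   resampled to it on load (clinical default 0.25 mm; the bundled
#'   phantom runs at its native 1.0 mm when `NULL`).
#' @param entry_max_offset_mm radius of the entry-candidate disk.
#' @param approach_axis unit tool-travel direction (entry toward target).
#' @param n_points control points per target (default 8).
#' @param termination list: `threshold` (default 5e-4), `window` (25),
#'   `enabled`.
#' @param d_risk named list of per-structure safe-distance overrides (mm).
#' @param lambda_bone bone weight of the injury objective; remaining
#'   weight is split equally across minimize-S structures.
#' @param eval list of [eval_config()] overrides.
#' @param opt list of [optimization_config()] overrides.
#' @param phantom list of [phantom_spec()] overrides (phantom runs).
#' @param inputs list of NIfTI input paths (`bone`, `target`,
#'   `head_region`, `structures` manifest YAML) for clinical-style runs.
#' @param out_dir artifact directory (`NULL` = no files written).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, tool_radius_mm = 1.5,
                       planning_spacing_mm = NULL,
                       entry_max_offset_mm = 12,
                       approach_axis = c(-1, 0, 0), n_points = 8L,
                       termination = list(), d_risk = list(),
                       lambda_bone = 0.5, eval = list(), opt = list(),
                       phantom = list(), inputs = NULL, out_dir = NULL) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0)
      stop(sprintf("config field '%s' must be a positive scalar", nm))
  }
  chk_pos(tool_radius_mm, "tool_radius_mm")
  if (!is.null(planning_spacing_mm))
    chk_pos(planning_spacing_mm, "planning_spacing_mm")
  chk_pos(entry_max_offset_mm, "entry_max_offset_mm")
  if (n_points < 3) stop("n_points must be at least 3")
  if (lambda_bone < 0 || lambda_bone > 1)
    stop("lambda_bone must lie in [0, 1]")
  term_known <- c("threshold", "window", "enabled")
  if (length(setdiff(names(termination), term_known)))
    stop("unknown termination keys: ",
         paste(setdiff(names(termination), term_known), collapse = ", "))
  term <- do.call(termination_config, termination)
  ev <- do.call(eval_config, eval)
  oc <- do.call(optimization_config,
                c(opt, if (is.null(opt$seed)) list(seed = seed)))
  structure(list(seed = as.integer(seed), tool_radius_mm = tool_radius_mm,
                 planning_spacing_mm = planning_spacing_mm,
                 entry_max_offset_mm = entry_max_offset_mm,
                 approach_axis = approach_axis,
                 n_points = as.integer(n_points), termination = term,
                 d_risk = d_risk, lambda_bone = lambda_bone, eval = ev,
                 opt = oc, phantom = phantom, inputs = inputs,
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown top-level keys are rejected; every numeric field is validated
#' by [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

# polynomial rolling hash of a serialized object (config provenance)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

read_structure_manifest <- function(path, d_risk_overrides = list()) {
  man <- yaml::read_yaml(path)
  lapply(man$structures, function(e) {
    mask <- read_volume_nifti(e$path, "mask")
    dr <- d_risk_overrides[[e$name]]
    critical_structure(e$name, mask, role = e$role,
                       d_risk_mm = if (!is.null(dr)) dr else e$d_risk,
                       lambda_weight = e$lambda)
  })
}

load_scene <- function(config) {
  if (is.null(config$inputs)) {
    spec <- do.call(phantom_spec,
                    c(config$phantom,
                      if (is.null(config$phantom$seed))
                        list(seed = config$seed),
                      if (is.null(config$phantom$tool_radius_mm))
                        list(tool_radius_mm = config$tool_radius_mm)))
    generate_phantom(spec)
  } else {
    bone <- read_volume_nifti(config$inputs$bone, "mask")
    target <- read_volume_nifti(config$inputs$target, "mask")
    head <- read_volume_nifti(config$inputs$head_region, "mask")
    structures <- read_structure_manifest(config$inputs$structures,
                                          config$d_risk)
    sp <- config$planning_spacing_mm
    if (!is.null(sp) && !isTRUE(all.equal(sp, bone$grid$spacing_mm))) {
      bone <- resample_isotropic(bone, sp)
      target <- resample_isotropic(target, sp)
      head <- resample_isotropic(head, sp)
      structures <- lapply(structures, function(s)
        critical_structure(s$name, resample_isotropic(s$mask, sp),
                           role = s$role, d_risk_mm = s$d_risk_mm,
                           lambda_weight = s$lambda_weight))
    }
    list(grid = bone$grid, bone = bone, target = target,
         head_region = head, structures = structures, manifest = NULL)
  }
}

#' Run the full planning pipeline
#'
#' Executes scene ingestion (phantom generation or NIfTI load), entry
#' candidate detection, effective-target extraction, maximum-milling-area
#' generation, control-plane parameterization, NSGA-III optimization,
#' Pareto selection, and final evaluation. When `out_dir` is set, all
#' artifacts (masks as NIfTI, point sets as CSV, front as CSV, metrics and
#' report as JSON) are written there; the report embeds the config hash,
#' seeds and per-stage timings so a run is reconstructible from it.
#'
#' @param config a [run_config()].
#' @return list of class `plan_report`: `scene`, `entries`, `stages`,
#'   `max_area`, `plan` (a `plan_result`), `metrics`, `report`.
#' @export
run_pipeline <- function(config = run_config()) {
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- toc(t0)
    res
  }
  tool <- tool_model(config$tool_radius_mm)
  scene <- stage("ingest", load_scene(config))
  d_over <- config$d_risk
  if (length(d_over)) {
    scene$structures <- lapply(scene$structures, function(s) {
      if (s$role == "intact_H" && !is.null(d_over[[s$name]]))
        s$d_risk_mm <- d_over[[s$name]]
      s
    })
  }
  tgt_centroid <- colMeans(mask_points(scene$target))
  entries <- stage("entries",
    find_entry_candidates(scene$bone, tgt_centroid, config$approach_axis,
                          config$entry_max_offset_mm))
  plane <- default_control_plane(entries, tgt_centroid, scene$grid, tool)
  stages_t <- stage("targets",
    extract_targets(scene$target, entries, scene$structures, tool, plane))
  t4 <- stages_t$t4$points_mm
  max_area <- stage("max_area",
    generate_max_area(t4, entries, scene$structures, tool, scene$grid,
                      config$termination))
  areas <- stage("parameterize",
                 build_area_functions(max_area, plane, tool))
  kept_targets <- t4[max_area$target_rows, , drop = FALSE]
  ev <- config$eval
  ev$approach_axis <- -config$approach_axis / sqrt(sum(config$approach_axis^2))
  ev$lambda_bone <- config$lambda_bone
  problem <- stage("problem",
    make_problem(areas, scene, kept_targets, tool, ev,
                 n_points = config$n_points))
  plan <- stage("optimize", optimize_plan(problem, config$opt))
  metrics <- stage("evaluate", {
    params <- matrix(plan$selection$parameters, problem$n_targets,
                     problem$n_points)
    deformed <- lapply(seq_along(areas), function(i)
      deform_area(areas[[i]], control_function(params[i, ])))
    evaluate_plan(plan$mill, deformed, scene, kept_targets, tool,
                  problem$mu_gsc_ref, ev)
  })
  report <- list(
    package_version = as.character(utils::packageVersion("mastoidplan")),
    seed = config$seed, config_hash = config_hash(unclass(config)),
    n_entries = nrow(entries), n_targets_t4 = nrow(t4),
    n_targets_kept = problem$n_targets,
    n_parameters = problem$n_var,
    dropped_targets = max_area$dropped,
    selection = plan$selection$provenance,
    objectives = list(Q_c = metrics$Q_c, Q_a = metrics$Q_a,
                      Q_i = metrics$Q_i),
    objectives_baseline = as.list(stats::setNames(
      plan$objectives_baseline, c("Q_c", "Q_a", "Q_i"))),
    timings_s = timings)
  out <- structure(list(scene = scene, entries = entries,
                        stages = stages_t, plane = plane,
                        max_area = max_area, plan = plan,
                        metrics = metrics, report = report,
                        config = config),
                   class = "plan_report")
  if (!is.null(config$out_dir)) write_plan_artifacts(out, config$out_dir)
  out
}

#' @export
print.plan_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<plan_report: %d entries, %d targets, %d parameters; ",
           "Q_i %.4f (baseline %.4f)>\n"),
    r$n_entries, r$n_targets_kept, r$n_parameters, r$objectives$Q_i,
    r$objectives_baseline$Q_i))
  invisible(x)
}

#' Write all artifacts of a finished planning run
#'
#' @param result a `plan_report` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
write_plan_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_volume_nifti(result$plan$mill, p("mill_selected.nii.gz"))
  write_volume_nifti(result$plan$mill_baseline, p("mill_max_area.nii.gz"))
  write_volume_nifti(result$max_area$union_mask, p("max_area_union.nii.gz"))
  kt <- do.call(rbind, lapply(seq_along(result$max_area$per_target),
    function(i) {
      pt <- result$max_area$per_target[[i]]
      data.frame(target_id = i, entry_r = pt$entries[, 1],
                 entry_a = pt$entries[, 2], entry_s = pt$entries[, 3])
    }))
  utils::write.csv(kt, p("feasible_entries.csv"), row.names = FALSE)
  utils::write.csv(stages_to_df(result$stages), p("target_stages.csv"),
                   row.names = FALSE)
  utils::write.csv(front_to_df(result$plan$front), p("pareto_front.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(result$metrics), p("metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
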