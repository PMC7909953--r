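#' Pipeline configuration
#'
#' Bundles all inputs and thresholds of the per-sample two-system analysis.
#' The defaults are the field-standard values: junction merge radius 0.2 mm,
#' side-branch collinearity threshold p = 0.95, diameter sampling step
#' 1.5 mm, cumulative-curve ranges 0.015-1.5 mm (surface gaps) and
#' 0.015-3 mm (branch points).
#'
#' @param bd_mask,pv_mask [voxel_grid()] objects or file paths readable by
#'   [read_volume()].
#' @param bd_origin_mm,pv_origin_mm length-3 origin (hilar) coordinates in
#'   mm; both are required.
#' @param voxel_size_mm voxel size, required when masks are paths to files
#'   without spacing metadata.
#' @param merge_threshold_mm junction merge radius.
#' @param side_branch_p collinearity threshold for side-branch detection.
#' @param diameter_step_mm main-branch diameter sampling step.
#' @param gap_curve_mm,bp_curve_mm `c(lo, hi)` cumulative-curve ranges.
#' @param region_windows diameter region windows, see
#'   [region_windows_preset()].
#' @param out_dir output directory (created if needed); `NULL` disables file
#'   output.
#' @param seed integer seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bd_mask, pv_mask, bd_origin_mm, pv_origin_mm,
                            voxel_size_mm = NULL,
                            merge_threshold_mm = 0.2,
                            side_branch_p = 0.95,
                            diameter_step_mm = 1.5,
                            gap_curve_mm = c(0.015, 1.5),
                            bp_curve_mm = c(0.015, 3),
                            region_windows = region_windows_preset(),
                            out_dir = NULL,
                            seed = 1L) {
  if (missing(bd_origin_mm) || is.null(bd_origin_mm) ||
      missing(pv_origin_mm) || is.null(pv_origin_mm))
    stop("both system origins (bd_origin_mm, pv_origin_mm) are required")
  stopifnot(length(bd_origin_mm) == 3, length(pv_origin_mm) == 3,
            merge_threshold_mm > 0, diameter_step_mm > 0,
            side_branch_p > 0, side_branch_p < 1,
            length(gap_curve_mm) == 2, length(bp_curve_mm) == 2)
  structure(
    list(bd_mask = bd_mask, pv_mask = pv_mask,
         bd_origin_mm = as.numeric(bd_origin_mm),
         pv_origin_mm = as.numeric(pv_origin_mm),
         voxel_size_mm = voxel_size_mm,
         merge_threshold_mm = merge_threshold_mm,
         side_branch_p = side_branch_p,
         diameter_step_mm = diameter_step_mm,
         gap_curve_mm = as.numeric(gap_curve_mm),
         bp_curve_mm = as.numeric(bp_curve_mm),
         region_windows = region_windows,
         out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full two-system pipeline
#'
#' Executes, for both systems: mask loading and validation, skeletonization,
#' graph conversion, junction merging, generation assignment, region
#' partition (reference region size from the PV system, applied to BD),
#' whole-system and main-branch length/tortuosity, volumes, diameter
#' profiles, furcation census; then the dual-system analyses: branch-point
#' distances and surface-gap distances with cumulative curves and the
#' maximum gap. Results are written to `out_dir` as `summary.json` plus
#' per-item CSVs and GraphML; the run is deterministic, so rerunning a
#' config reproduces the outputs byte for byte. Any stage error aborts with
#' a stage-named message and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  written <- character(0)
  out_dir <- config$out_dir
  emit <- function(fun, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    fun(path)
    written <<- c(written, path)
  }
  on_fail <- function(stage, e) {
    if (length(written)) unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) on_fail(name, e))

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  load_grid <- function(mask, label)
    if (inherits(mask, "voxel_grid")) mask
    else read_volume(mask, voxel_size_mm = config$voxel_size_mm,
                     label = label)
  grids <- stage("load", list(bd = load_grid(config$bd_mask, "BD"),
                              pv = load_grid(config$pv_mask, "PV")))

  analyse_system <- function(grid, origin, label) {
    skel <- skeletonize_mask(grid)
    graph <- graph_from_skeleton(skel)
    merged <- merge_junctions(graph, config$merge_threshold_mm)
    tab <- assign_generations(merged, origin, config$side_branch_p)
    lgn <- lengths_by_generation(tab)
    mb <- main_branch(merged, origin)
    prof <- diameter_profile(grid, mb, config$diameter_step_mm,
                             config$region_windows)
    fur <- classify_furcations(merged, origin)
    list(grid = grid, skel = skel, graph = graph, merged = merged,
         table = tab, l_gn = lgn, main = mb, profile = prof,
         furcations = fur, label = label,
         curved_mm = curved_length(merged),
         chord_mm = chord_length(merged),
         tortuosity_pct = tortuosity_of(merged))
  }
  bd <- stage("skeleton/branching BD",
              analyse_system(grids$bd, config$bd_origin_mm, "BD"))
  pv <- stage("skeleton/branching PV",
              analyse_system(grids$pv, config$pv_origin_mm, "PV"))

  reg <- stage("regions", {
    # trees with fewer than three generations get the degenerate partition
    pv_borders <- if (nrow(pv$l_gn) >= 3) region_borders(pv$l_gn)
                  else apply_reference_partition(
                         pv$l_gn, sum(pv$l_gn$mean_curved_mm) / 3)
    pv_part <- region_summaries(pv$table, pv_borders, pv$l_gn)
    bd_part <- region_summaries(bd$table,
                                apply_reference_partition(
                                  bd$l_gn, pv_part$target_size_mm), bd$l_gn)
    list(pv = pv_part, bd = bd_part)
  })

  dual <- stage("dual-system", {
    # unbranched systems (e.g. a single straight duct) have no branch
    # points; the branch-point analysis is then skipped
    have_bp <- nrow(junction_points(bd$merged)) > 0 &&
               nrow(junction_points(pv$merged)) > 0
    bp <- if (have_bp)
      branch_point_distances(junction_points(bd$merged),
                             junction_points(pv$merged))
    gaps <- gap_distances(bd$skel, pv$skel, grids$bd, grids$pv)
    list(bp = bp,
         bp_curve = if (have_bp)
           cumulative_curve(bp$d_bp_mm, config$bp_curve_mm[1],
                            config$bp_curve_mm[2]),
         gaps = gaps,
         gap_curve = cumulative_curve(gaps$d_gap_mm, config$gap_curve_mm[1],
                                      config$gap_curve_mm[2]),
         max_gap_mm = max_gap(gaps))
  })

  system_summary <- function(s, part) list(
    label = s$label,
    volume_mm3 = system_volume(s$grid),
    whole = list(curved_mm = s$curved_mm, chord_mm = s$chord_mm,
                 tortuosity_pct = s$tortuosity_pct),
    main_branch = list(curved_mm = s$main$curved_mm,
                       chord_mm = s$main$chord_mm,
                       tortuosity_pct = tortuosity_of(s$main)),
    tortuosity_by_region = as.list(tortuosity_by_region(s$table, part)),
    furcations = unclass(s$furcations),
    n_branches = nrow(s$table),
    n_generations = max(s$table$generation),
    region_summary = part$summary,
    region_mean_diameter_mm = as.list(region_mean_diameter(s$profile)))

  summary <- list(
    config = list(
      merge_threshold_mm = config$merge_threshold_mm,
      side_branch_p = config$side_branch_p,
      diameter_step_mm = config$diameter_step_mm,
      gap_curve_mm = config$gap_curve_mm,
      bp_curve_mm = config$bp_curve_mm,
      voxel_size_mm = grids$bd$voxel_size_mm,
      bd_origin_mm = config$bd_origin_mm,
      pv_origin_mm = config$pv_origin_mm,
      seed = config$seed),
    bd = system_summary(bd, reg$bd),
    pv = system_summary(pv, reg$pv),
    ratios = list(
      volume_bd_pv = volume_ratio(grids$bd, grids$pv),
      curved_bd_pv = bd$curved_mm / pv$curved_mm,
      chord_bd_pv = bd$chord_mm / pv$chord_mm,
      diameter_bd_pv = as.list(bd_pv_diameter_ratio(bd$profile, pv$profile))),
    dual = list(max_gap_mm = dual$max_gap_mm,
                n_branch_points_bd = if (is.null(dual$bp)) 0L
                                     else nrow(dual$bp),
                n_gap_points = nrow(dual$gaps)))

  stage("write outputs", {
    for (s in list(bd, pv)) {
      lbl <- tolower(s$label)
      emit(function(p) write.csv(s$merged$nodes, p, row.names = FALSE),
           paste0(lbl, "_nodes.csv"))
      emit(function(p) write.csv(s$merged$links, p, row.names = FALSE),
           paste0(lbl, "_links.csv"))
      emit(function(p) write.csv(as.data.frame(s$table), p,
                                 row.names = FALSE),
           paste0(lbl, "_branches.csv"))
      emit(function(p) write.csv(as.data.frame(s$profile), p,
                                 row.names = FALSE),
           paste0(lbl, "_diameter_profile.csv"))
      emit(function(p) write_graphml(s$merged, p),
           paste0(lbl, "_graph.graphml"))
    }
    regions_tab <- rbind(
      cbind(system = "PV", reg$pv$generations),
      cbind(system = "BD", reg$bd$generations))
    emit(function(p) write.csv(regions_tab, p, row.names = FALSE),
         "regions.csv")
    if (!is.null(dual$bp)) {
      emit(function(p) write.csv(as.data.frame(dual$bp), p,
                                 row.names = FALSE),
           "distances_branchpoints.csv")
      emit(function(p) write.csv(as.data.frame(dual$bp_curve), p,
                                 row.names = FALSE),
           "curve_branchpoints.csv")
    }
    emit(function(p) write.csv(as.data.frame(dual$gaps), p,
                               row.names = FALSE),
         "distances_gaps.csv")
    emit(function(p) write.csv(as.data.frame(dual$gap_curve), p,
                               row.names = FALSE),
         "curve_gaps.csv")
    emit(function(p) jsonlite::write_json(summary, p, auto_unbox = TRUE,
                                          digits = NA, pretty = TRUE,
                                          dataframe = "rows"),
         "summary.json")
  })
  invisible(summary)
}
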