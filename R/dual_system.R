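#' Junction positions of a graph
#'
#' Coordinates (mm) of junction-kind nodes -- the branching points used in
#' inter-system branch-point distance analysis. Apply [merge_junctions()]
#' first so that branching points closer than the merge radius count once.
#'
#' @param graph a [skeleton_graph()].
#' @return n x 3 matrix of mm coordinates.
#' @export
junction_points <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  sel <- graph$nodes$kind == "junction"
  as.matrix(graph$nodes[sel, c("x_mm", "y_mm", "z_mm")])
}

#' Branch-point to branch-point distances between two systems
#'
#' For every branching point of the first system (BD), the 3D Euclidean
#' distance to the nearest branching point of the second system (PV). Ties
#' are broken by the lexicographically smallest second-system coordinate.
#'
#' @param bd_junctions n x 3 matrix of first-system branch points (mm), or a
#'   [skeleton_graph()] (junctions are extracted).
#' @param pv_junctions same for the second system; must be nonempty.
#' @return A `branch_point_distances` data frame: `bd_x/y/z_mm`,
#'   `pv_x/y/z_mm`, `d_bp_mm`.
#' @seealso [cumulative_curve()]
#' @export
branch_point_distances <- function(bd_junctions, pv_junctions) {
  if (inherits(bd_junctions, "skeleton_graph"))
    bd_junctions <- junction_points(bd_junctions)
  if (inherits(pv_junctions, "skeleton_graph"))
    pv_junctions <- junction_points(pv_junctions)
  bd <- as_point_matrix(bd_junctions)
  pv <- as_point_matrix(pv_junctions)
  if (!nrow(pv)) stop("second-system branch point set is empty")
  if (!nrow(bd)) stop("first-system branch point set is empty")
  nn <- cpp_nearest_neighbour(bd, pv)
  out <- data.frame(
    bd_x_mm = bd[, 1], bd_y_mm = bd[, 2], bd_z_mm = bd[, 3],
    pv_x_mm = pv[nn$index, 1], pv_y_mm = pv[nn$index, 2],
    pv_z_mm = pv[nn$index, 3],
    d_bp_mm = nn$distance)
  class(out) <- c("branch_point_distances", "data.frame")
  out
}

#' Surface-gap distances between two systems
#'
#' For every skeleton point of the first system (BD), finds the nearest
#' skeleton point of the second system (PV), connects the two points with a
#' line, and measures the non-resin span on that line: the voxels along the
#' digital line that are foreground in neither binary mask. The gap is the
#' Euclidean distance between the first and last such voxel centres (0 when
#' the masks touch or overlap along the line). An alternative
#' `method = "radius"` estimates the gap by subtracting the two local radii
#' from the skeleton-to-skeleton distance; the two definitions agree for
#' locally circular cross-sections.
#'
#' @param bd_skel,pv_skel `skeleton_voxels` objects of the two systems.
#' @param bd_grid,pv_grid the corresponding [voxel_grid()] masks
#'   (co-registered: identical dims and voxel size).
#' @param method `"line"` (non-resin span; default) or `"radius"`.
#' @return A `gap_measurements` data frame: `bd_x/y/z_mm`, `pv_x/y/z_mm`,
#'   `skel_dist_mm` (skeleton point distance) and `d_gap_mm`.
#' @export
gap_distances <- function(bd_skel, pv_skel, bd_grid, pv_grid,
                          method = c("line", "radius")) {
  method <- match.arg(method)
  stopifnot(inherits(bd_skel, "skeleton_voxels"),
            inherits(pv_skel, "skeleton_voxels"),
            inherits(bd_grid, "voxel_grid"),
            inherits(pv_grid, "voxel_grid"))
  if (!identical(dim(bd_grid), dim(pv_grid)) ||
      abs(bd_grid$voxel_size_mm - pv_grid$voxel_size_mm) > 1e-9)
    stop("grids are not co-registered (dims or voxel size differ)")
  vs <- bd_grid$voxel_size_mm
  bd_mm <- vox_centers_mm(bd_skel$points, vs)
  pv_mm <- vox_centers_mm(pv_skel$points, vs)
  nn <- cpp_nearest_neighbour(bd_mm, pv_mm)
  pv_sel <- pv_mm[nn$index, , drop = FALSE]
  if (method == "line") {
    gaps_vox <- cpp_line_gaps(
      mm_to_voxcoord(bd_mm, vs), mm_to_voxcoord(pv_sel, vs),
      bd_grid$occupancy, pv_grid$occupancy, dim(bd_grid$occupancy))
    d_gap <- gaps_vox * vs
  } else {
    r_bd <- radius_at(bd_grid, bd_mm)
    r_pv <- radius_at(pv_grid, pv_sel)
    d_gap <- pmax(0, nn$distance - r_bd - r_pv)
  }
  out <- data.frame(
    bd_x_mm = bd_mm[, 1], bd_y_mm = bd_mm[, 2], bd_z_mm = bd_mm[, 3],
    pv_x_mm = pv_sel[, 1], pv_y_mm = pv_sel[, 2], pv_z_mm = pv_sel[, 3],
    skel_dist_mm = nn$distance, d_gap_mm = d_gap)
  class(out) <- c("gap_measurements", "data.frame")
  out
}

#' Maximum gap distance
#'
#' The largest surface gap between the two systems in a sample.
#'
#' @param measurements a `gap_measurements` data frame (or numeric vector of
#'   distances).
#' @return Maximum distance in mm.
#' @export
max_gap <- function(measurements) {
  d <- if (is.data.frame(measurements)) measurements$d_gap_mm
       else as.numeric(measurements)
  if (!length(d)) stop("no gap measurements")
  max(d)
}

#' Cumulative distance curve
#'
#' Cumulative percentage of distances at or below each bin edge. Bin edges
#' run from `lo_mm` in steps of `lo_mm` (one scan voxel, by default 0.015
#' mm) up to `hi_mm`; any distances beyond `hi_mm` accumulate into one final
#' overflow edge so the curve always terminates at 100%.
#'
#' @param distances numeric vector of distances (mm), or a
#'   `gap_measurements` / `branch_point_distances` data frame.
#' @param lo_mm first bin edge and bin width (default 0.015 mm).
#' @param hi_mm last regular bin edge (e.g. 1.5 mm for gaps, 3 mm for branch
#'   points).
#' @return A `cumulative_curve` data frame: `bin_upper_edge_mm`,
#'   `cumulative_percent` (nondecreasing, final value 100).
#' @export
cumulative_curve <- function(distances, lo_mm = 0.015, hi_mm) {
  if (is.data.frame(distances))
    distances <- distances[[grep("^d_", names(distances), value = TRUE)[1]]]
  d <- as.numeric(distances)
  if (!length(d)) stop("empty distance list")
  if (!(hi_mm > lo_mm) || !(lo_mm > 0)) stop("need hi_mm > lo_mm > 0")
  edges <- seq(lo_mm, hi_mm, by = lo_mm)
  if (max(d) > max(edges) + 1e-12) edges <- c(edges, max(d))
  pct <- vapply(edges, function(e) 100 * mean(d <= e + 1e-12), numeric(1))
  out <- data.frame(bin_upper_edge_mm = edges, cumulative_percent = pct)
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Write a per-distance table
#'
#' One distance per row with sample and genotype columns -- the layout of
#' published per-sample distance source-data tables -- so curves from
#' different samples can be pooled or re-summarized externally with
#' [cumulative_curve()].
#'
#' @param measurements a `gap_measurements` or `branch_point_distances`
#'   data frame, or a numeric distance vector.
#' @param path output CSV path.
#' @param sample,genotype identifiers repeated on every row.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(measurements, path, sample = "",
                                 genotype = "") {
  d <- if (is.data.frame(measurements))
    measurements[[grep("^d_", names(measurements), value = TRUE)[1]]]
  else as.numeric(measurements)
  write.csv(data.frame(sample = sample, genotype = genotype,
                       distance_mm = d),
            path, row.names = FALSE)
  invisible(path)
}
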