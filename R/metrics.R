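#' Curved (actual) length
#'
#' Cumulative sum of 3D Euclidean distances between neighbouring points, in
#' mm. For a [skeleton_graph()] the whole-system value is the sum over all
#' link chains.
#'
#' @param x an ordered coordinate matrix (mm), a link chain, or a
#'   [skeleton_graph()].
#' @return Length in mm.
#' @seealso [chord_length()], [tortuosity_percent()]
#' @export
curved_length <- function(x) UseMethod("curved_length")

#' @export
curved_length.default <- function(x) {
  x <- as_point_matrix(x)
  if (nrow(x) < 1) stop("need at least one point")
  if (nrow(x) == 1) return(0)
  sum(sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2)))
}

#' @export
curved_length.skeleton_graph <- function(x) sum(x$links$curved_mm)

#' @export
curved_length.main_branch <- function(x) x$curved_mm

#' Chord (theoretical) length
#'
#' Straight-line node-to-node distance, summed over links for a graph: the
#' length the system would have if every link were a straight segment. For a
#' coordinate matrix, the distance between its first and last points.
#' Always `<=` the curved length.
#'
#' @param x a [skeleton_graph()], a `main_branch`, or a coordinate matrix.
#' @return Length in mm.
#' @export
chord_length <- function(x) UseMethod("chord_length")

#' @export
chord_length.default <- function(x) {
  x <- as_point_matrix(x)
  sqrt(sum((x[nrow(x), ] - x[1, ])^2))
}

#' @export
chord_length.skeleton_graph <- function(x) sum(x$links$chord_mm)

#' @export
chord_length.main_branch <- function(x) x$chord_mm

#' Percent tortuosity
#'
#' Curved length divided by chord length, expressed in percent above a
#' perfectly straight duct: `(curved / chord) * 100 - 100`, so a straight
#' segment scores 0%.
#'
#' @param curved_mm curved (actual) length, mm.
#' @param chord_mm chord (theoretical) length, mm; must be positive.
#' @return Percent tortuosity (>= 0 up to numerical noise).
#' @examples
#' tortuosity_percent(pi, 2) # semicircle of radius 1: ~57.08
#' @export
tortuosity_percent <- function(curved_mm, chord_mm) {
  if (any(chord_mm <= 0))
    stop("chord length must be positive (degenerate closed loop?)")
  (curved_mm / chord_mm) * 100 - 100
}

#' Whole-object tortuosity
#'
#' Convenience wrapper: percent tortuosity of a graph, main branch, or chain.
#'
#' @param x object accepted by [curved_length()] and [chord_length()].
#' @return Percent tortuosity.
#' @export
tortuosity_of <- function(x) tortuosity_percent(curved_length(x), chord_length(x))

#' System volume
#'
#' Number of foreground voxels multiplied by the volume of one voxel.
#'
#' @param grid a [voxel_grid()].
#' @return Volume in mm^3 (0 for an empty grid).
#' @export
system_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  sum(grid$occupancy) * grid$voxel_size_mm^3
}

#' Volume ratio of two systems
#'
#' Divides the first system's volume by the second's (e.g. BD / PV).
#'
#' @param grid_num,grid_den numerator and denominator [voxel_grid()]s.
#' @return Dimensionless ratio.
#' @export
volume_ratio <- function(grid_num, grid_den) {
  v <- system_volume(grid_den)
  if (v == 0) stop("denominator system has zero volume")
  system_volume(grid_num) / v
}

snap_to_node <- function(graph, origin_mm, max_vox = 20) {
  pos <- as.matrix(graph$nodes[, c("x_mm", "y_mm", "z_mm")])
  d2 <- sqrt(rowSums(sweep(pos, 2, origin_mm)^2))
  i <- which.min(d2)
  if (d2[i] > max_vox * graph$voxel_size_mm)
    stop(sprintf(
      "origin (%.3f, %.3f, %.3f) is %.3f mm from the nearest node (> %d voxels); wrong-system origin?",
      origin_mm[1], origin_mm[2], origin_mm[3], d2[i], max_vox))
  graph$nodes$id[i]
}

#' Main branch of a system
#'
#' The main branch is the longest branch: the path from the (manually
#' defined, hilar) origin to the endpoint that maximises curved path length.
#' The origin is snapped to the nearest graph node; ties between endpoints of
#' equal path length are broken by the lexicographically smallest endpoint
#' position.
#'
#' @param graph a [skeleton_graph()].
#' @param origin_mm numeric length-3, origin coordinate in mm. Must lie
#'   within 20 voxels of some node.
#' @return An object of class `main_branch`: list with `chain` (ordered mm
#'   coordinates from origin to tip), `node_ids`, `link_ids`, `curved_mm`,
#'   `chord_mm`, `origin_node`.
#' @export
main_branch <- function(graph, origin_mm) {
  stopifnot(inherits(graph, "skeleton_graph"))
  o <- snap_to_node(graph, origin_mm)
  g <- as_igraph(graph)
  vnames <- as.integer(igraph::V(g)$name)
  targets <- graph$nodes$id[graph$nodes$kind == "endpoint" &
                            graph$nodes$id != o]
  if (!length(targets)) targets <- graph$nodes$id[graph$nodes$id != o]
  if (!length(targets)) stop("graph has no endpoint to reach from the origin")
  dist <- igraph::distances(g, v = match(o, vnames),
                            to = match(targets, vnames))[1, ]
  reachable <- is.finite(dist)
  if (!any(reachable)) stop("no endpoint reachable from the origin")
  targets <- targets[reachable]; dist <- dist[reachable]
  best <- dist >= max(dist) - 1e-9
  cand <- targets[best]
  if (length(cand) > 1) { # lexicographic tie-break on endpoint position
    pos <- as.matrix(graph$nodes[match(cand, graph$nodes$id),
                                 c("x_mm", "y_mm", "z_mm")])
    cand <- cand[order(pos[, 1], pos[, 2], pos[, 3])]
  }
  tip <- cand[1]
  sp <- igraph::shortest_paths(g, from = match(o, vnames),
                               to = match(tip, vnames),
                               output = "both")
  node_ids <- vnames[as.integer(sp$vpath[[1]])]
  link_ids <- igraph::edge_attr(g, "link_id", sp$epath[[1]])
  chain <- matrix(numeric(0), 0, 3)
  for (k in seq_along(link_ids)) {
    li <- match(link_ids[k], graph$links$id)
    ch <- graph$chains[[li]]
    if (graph$links$node_a[li] != node_ids[k]) ch <- ch[rev(seq_len(nrow(ch))), ]
    if (nrow(chain)) ch <- ch[-1, , drop = FALSE]
    chain <- rbind(chain, ch)
  }
  if (!nrow(chain))
    chain <- as.matrix(graph$nodes[match(o, graph$nodes$id),
                                   c("x_mm", "y_mm", "z_mm")])
  structure(
    list(chain = unname(chain), node_ids = node_ids, link_ids = link_ids,
         curved_mm = curved_length.default(chain),
         chord_mm = chord_length.default(chain),
         origin_node = o),
    class = "main_branch")
}

#' @export
print.main_branch <- function(x, ...) {
  cat(sprintf("<main_branch> %d links, curved %.3f mm, chord %.3f mm (tortuosity %.2f%%)\n",
              length(x$link_ids), x$curved_mm, x$chord_mm,
              tortuosity_percent(x$curved_mm, x$chord_mm)))
  invisible(x)
}

#' Local radius from the mask boundary
#'
#' Radius at a skeleton point, defined as the minimal Euclidean distance from
#' the point to the segmented-area boundary. The boundary is obtained by
#' eroding the mask with a spherical structuring element of one-voxel radius
#' and subtracting the eroded mask from the original, leaving the voxel
#' layer between background and the area of interest.
#'
#' The centre of a boundary voxel sits half a voxel inside the physical
#' mask surface, so the raw minimum distance underestimates the true radius
#' by about half a voxel; `boundary_offset_vox` (default 0.5) adds that
#' quantization offset back. Set it to 0 for the raw distance.
#'
#' @param grid a [voxel_grid()].
#' @param points_mm point or n x 3 matrix of points (mm) on/inside the mask.
#' @param boundary optional precomputed boundary voxel index matrix (from an
#'   earlier call; recomputing it is the expensive part).
#' @param boundary_offset_vox half-voxel surface-quantization correction, in
#'   voxels.
#' @return Numeric vector of radii in mm.
#' @export
radius_at <- function(grid, points_mm, boundary = NULL,
                      boundary_offset_vox = 0.5) {
  stopifnot(inherits(grid, "voxel_grid"))
  points_mm <- as_point_matrix(points_mm)
  d <- dim(grid$occupancy)
  idx <- mm_to_voxindex(points_mm, grid$voxel_size_mm)
  idx <- pmin(pmax(idx, 1L), matrix(d, nrow(idx), 3, byrow = TRUE))
  inside <- grid$occupancy[idx]
  if (!all(inside))
    stop("point(s) outside the mask foreground: row ",
         paste(which(!inside), collapse = ", "))
  if (is.null(boundary)) boundary <- boundary_voxels(grid)
  if (!nrow(boundary)) stop("mask has no boundary (degenerate)")
  bpos <- vox_centers_mm(boundary, grid$voxel_size_mm)
  vapply(seq_len(nrow(points_mm)), function(i) {
    sqrt(min(rowSums(sweep(bpos, 2, points_mm[i, ])^2)))
  }, numeric(1)) + boundary_offset_vox * grid$voxel_size_mm
}

#' Preset diameter region windows
#'
#' Arc-length windows (mm from the origin along the main branch) used to pool
#' diameters into hilar, intermediate and peripheral regions. The
#' `"standard"` preset is 0-3 / 4.5-9 / 10.5-13.5 mm; the `"narrow"` preset
#' (for smaller lobes) is 0-1.5 / 3-6 / 7.5-9 mm.
#'
#' @param preset `"standard"` or `"narrow"`.
#' @return Named list of `c(lo, hi)` windows.
#' @export
region_windows_preset <- function(preset = c("standard", "narrow")) {
  preset <- match.arg(preset)
  if (preset == "standard")
    list(hilar = c(0, 3), intermediate = c(4.5, 9), periphery = c(10.5, 13.5))
  else
    list(hilar = c(0, 1.5), intermediate = c(3, 6), periphery = c(7.5, 9))
}

#' Diameter profile along the main branch
#'
#' Samples the local diameter (2 x [radius_at()]) every `step_mm` of arc
#' length along the main branch, interpolating linearly between chain points
#' to hit exact multiples of the step. The reported (smoothed) value at each
#' sample is the mean of the diameter there and at its two neighbouring
#' sample points on each side; near the profile ends the window shrinks
#' symmetrically (minimum one point). Samples are labelled with the region
#' window containing their arc position.
#'
#' @param grid a [voxel_grid()].
#' @param main a `main_branch` (or an ordered mm coordinate matrix).
#' @param step_mm sampling step along the branch (default 1.5 mm).
#' @param region_windows named list of `c(lo, hi)` arc windows; see
#'   [region_windows_preset()].
#' @return A `radius_profile` data frame with columns `position_mm`,
#'   `diameter_raw_mm`, `diameter_smoothed_mm`, `region`; the windows are
#'   attached as attribute `region_windows`.
#' @export
diameter_profile <- function(grid, main, step_mm = 1.5,
                             region_windows = region_windows_preset()) {
  stopifnot(inherits(grid, "voxel_grid"))
  chain <- if (inherits(main, "main_branch")) main$chain else as_point_matrix(main)
  L <- curved_length.default(chain)
  if (L < step_mm) {
    warning(sprintf(
      "main branch (%.3f mm) is shorter than the sampling step (%g mm); single sample at 0",
      L, step_mm))
    at <- 0
  } else {
    at <- seq(0, L, by = step_mm)
  }
  pts <- interpolate_chain(chain, at)
  # interpolated points can fall marginally outside the mask between voxel
  # centres; snap such samples to the nearest chain vertex
  d <- dim(grid$occupancy)
  idx <- pmin(pmax(mm_to_voxindex(pts, grid$voxel_size_mm), 1L),
              matrix(d, nrow(pts), 3, byrow = TRUE))
  off <- !grid$occupancy[idx]
  if (any(off)) {
    for (i in which(off)) {
      dd <- rowSums(sweep(chain, 2, pts[i, ])^2)
      pts[i, ] <- chain[which.min(dd), ]
    }
  }
  boundary <- boundary_voxels(grid)
  raw <- 2 * radius_at(grid, pts, boundary = boundary)
  n <- length(raw)
  smoothed <- vapply(seq_len(n), function(i) {
    k <- min(2L, i - 1L, n - i)
    mean(raw[(i - k):(i + k)])
  }, numeric(1))
  region <- rep(NA_character_, n)
  for (w in names(region_windows)) {
    win <- region_windows[[w]]
    region[at >= win[1] - 1e-9 & at <= win[2] + 1e-9] <- w
  }
  out <- data.frame(position_mm = at, diameter_raw_mm = raw,
                    diameter_smoothed_mm = smoothed, region = region)
  attr(out, "region_windows") <- region_windows
  class(out) <- c("radius_profile", "data.frame")
  out
}

#' Region-mean diameters of a profile
#'
#' @param profile a `radius_profile` from [diameter_profile()].
#' @return Named numeric vector of mean smoothed diameters per region window
#'   (NA where a window holds no samples).
#' @export
region_mean_diameter <- function(profile) {
  stopifnot(inherits(profile, "radius_profile"))
  windows <- attr(profile, "region_windows")
  vapply(names(windows), function(w) {
    v <- profile$diameter_smoothed_mm[!is.na(profile$region) &
                                      profile$region == w]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' BD/PV diameter ratio per region
#'
#' Region-mean diameter of the first system divided by the region-mean
#' diameter of the second, per region window. In wild-type liver this ratio
#' is stereotypically about 1:3 (BD:PV).
#'
#' @param profile_num,profile_den `radius_profile`s computed with identical
#'   region windows.
#' @return Named numeric vector of per-region ratios.
#' @export
bd_pv_diameter_ratio <- function(profile_num, profile_den) {
  wn <- attr(profile_num, "region_windows")
  wd <- attr(profile_den, "region_windows")
  if (!identical(wn, wd))
    stop("profiles were computed with different region windows")
  region_mean_diameter(profile_num) / region_mean_diameter(profile_den)
}
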