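#' Merge nearby junction nodes
#'
#' Branching points closer than `threshold_mm` (default 0.2 mm) are merged
#' transitively -- the union of all pairs under the threshold -- and
#' represented by one node placed at the centroid of the member positions.
#' Links running between members of one merge group are absorbed (their
#' chains are internal to the merged node). Chains of surviving links are
#' re-anchored at the merged node position. Merging with threshold 0 is the
#' identity, and a larger threshold never yields more nodes.
#'
#' @param graph a [skeleton_graph()].
#' @param threshold_mm merge radius in mm.
#' @return A [skeleton_graph()] with merged junctions.
#' @export
merge_junctions <- function(graph, threshold_mm = 0.2) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nodes <- graph$nodes
  jn <- which(nodes$kind == "junction")
  if (threshold_mm <= 0 || length(jn) < 2) return(graph)
  pos <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  parent <- uf_new(nrow(nodes))
  pj <- pos[jn, , drop = FALSE]
  dd <- as.matrix(dist(pj))
  close <- which(dd < threshold_mm & upper.tri(dd), arr.ind = TRUE)
  if (!nrow(close)) return(graph)
  for (r in seq_len(nrow(close)))
    parent <- uf_union(parent, jn[close[r, 1]], jn[close[r, 2]])
  root <- vapply(seq_len(nrow(nodes)), function(i) uf_find(parent, i),
                 integer(1))

  groups <- split(seq_len(nrow(nodes)), root)
  new_pos <- pos
  absorbed_voxels <- integer(nrow(nodes))
  for (g in groups) {
    if (length(g) > 1) {
      cen <- colMeans(pos[g, , drop = FALSE])
      new_pos[g[1], ] <- cen
      absorbed_voxels[g[1]] <- sum(nodes$n_voxels[g])
    }
  }
  keep <- vapply(seq_len(nrow(nodes)), function(i) root[i] == i, logical(1))
  old2new <- match(root, which(keep))

  links <- graph$links
  chains <- graph$chains
  a <- old2new[links$node_a]
  b <- old2new[links$node_b]
  # absorbed links: both endpoints merged into the same node (pre-existing
  # self-links are genuine cycles and are kept)
  internal <- a == b & (root[links$node_a] != links$node_a |
                        root[links$node_b] != links$node_b)
  keep_links <- !internal

  new_nodes <- nodes[keep, , drop = FALSE]
  new_nodes$x_mm <- new_pos[keep, 1]
  new_nodes$y_mm <- new_pos[keep, 2]
  new_nodes$z_mm <- new_pos[keep, 3]
  # merged nodes account for their members' voxels plus absorbed link chains
  merged_extra <- absorbed_voxels[keep]
  new_nodes$n_voxels <- ifelse(merged_extra > 0, merged_extra,
                               new_nodes$n_voxels)
  if (any(internal)) {
    tgt <- a[internal] # new-node index of the absorbing group
    add <- tapply(links$n_chain[internal], tgt, sum)
    ki <- as.integer(names(add))
    new_nodes$n_voxels[ki] <- new_nodes$n_voxels[ki] + as.integer(add)
  }
  new_nodes$id <- seq_len(nrow(new_nodes))

  links <- links[keep_links, , drop = FALSE]
  chains <- chains[keep_links]
  links$node_a <- new_nodes$id[match(a[keep_links], seq_len(sum(keep)))]
  links$node_b <- new_nodes$id[match(b[keep_links], seq_len(sum(keep)))]
  links$id <- seq_len(nrow(links))
  npos <- as.matrix(new_nodes[, c("x_mm", "y_mm", "z_mm")])
  for (li in seq_len(nrow(links))) {
    ch <- chains[[li]]
    ch[1, ] <- npos[links$node_a[li], ]
    ch[nrow(ch), ] <- npos[links$node_b[li], ]
    chains[[li]] <- ch
  }
  links$curved_mm <- NULL; links$chord_mm <- NULL
  new_nodes$degree <- NULL
  out <- skeleton_graph(new_nodes, links, chains,
                        voxel_size_mm = graph$voxel_size_mm,
                        dims = graph$dims, label = graph$label,
                        n_skeleton_voxels = graph$n_skeleton_voxels)
  attr(out, "merge_threshold_mm") <- threshold_mm
  out
}

# Breadth-first orientation of links away from an origin node. Returns, per
# link: the parent-side node, visit order, and whether the link closes a
# cycle (reached with both endpoints already visited).
orient_links <- function(graph, origin_node) {
  nlinks <- nrow(graph$links)
  incident <- vector("list", nrow(graph$nodes))
  for (li in seq_len(nlinks)) {
    a <- graph$links$node_a[li]; b <- graph$links$node_b[li]
    incident[[a]] <- c(incident[[a]], li)
    if (b != a) incident[[b]] <- c(incident[[b]], li)
  }
  from_node <- rep(NA_integer_, nlinks)
  cycle <- logical(nlinks)
  visited_node <- logical(nrow(graph$nodes))
  visited_link <- logical(nlinks)
  queue <- origin_node
  visited_node[origin_node] <- TRUE
  order_visited <- integer(0)
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    for (li in incident[[u]]) {
      if (visited_link[li]) next
      visited_link[li] <- TRUE
      v <- if (graph$links$node_a[li] == u) graph$links$node_b[li]
           else graph$links$node_a[li]
      from_node[li] <- u
      order_visited <- c(order_visited, li)
      if (visited_node[v]) {
        cycle[li] <- TRUE # closes a cycle (or is a self-link)
      } else {
        visited_node[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  list(from_node = from_node, cycle = cycle, order = order_visited,
       visited_node = visited_node)
}

#' Furcation census
#'
#' Classifies each (merged) junction by its number of outputs -- links
#' oriented away from the origin: two outputs make a bifurcation, three a
#' trifurcation, more a higher-order furcation. Junctions left with fewer
#' than two outputs after orientation (possible inside cycles) are reported
#' separately and logged.
#'
#' @param graph a [skeleton_graph()], normally after [merge_junctions()].
#' @param origin_mm origin coordinate in mm (defines the flow direction).
#' @return A `furcation_census` list: `n_bifurcation`, `n_trifurcation`,
#'   `n_higher`, `n_junctions`, `n_unclassified`.
#' @export
classify_furcations <- function(graph, origin_mm) {
  stopifnot(inherits(graph, "skeleton_graph"))
  o <- snap_to_node(graph, origin_mm)
  ori <- orient_links(graph, o)
  jn <- graph$nodes$id[graph$nodes$kind == "junction"]
  outputs <- vapply(jn, function(u) sum(ori$from_node == u, na.rm = TRUE),
                    integer(1))
  unclass <- sum(outputs < 2)
  if (unclass)
    message(unclass, " junction(s) with fewer than two outputs after ",
            "orientation; not classified")
  structure(
    list(n_bifurcation = sum(outputs == 2),
         n_trifurcation = sum(outputs == 3),
         n_higher = sum(outputs > 3),
         n_junctions = length(jn),
         n_unclassified = unclass),
    class = "furcation_census")
}

#' @export
print.furcation_census <- function(x, ...) {
  cat(sprintf("<furcation_census> %d junctions: %d bi-, %d tri-, %d higher-furcations",
              x$n_junctions, x$n_bifurcation, x$n_trifurcation, x$n_higher))
  if (x$n_unclassified) cat(sprintf(" (%d unclassified)", x$n_unclassified))
  cat("\n")
  invisible(x)
}

#' Assign branch generations
#'
#' Breadth-first from the origin (generation 1 at the origin links). Each
#' link's direction is the unit node-to-node chord oriented away from the
#' origin. At every junction the dot product `p` between a child's unit
#' vector and its parent's is computed: a child with `p` above
#' `side_branch_p` (default 0.95) is a near-collinear continuation and
#' inherits the parent's generation (a *side branch* split off instead);
#' when several children exceed the threshold only the most collinear one
#' continues the parent generation. All other children increment the
#' generation by one. Links that close a cycle receive the minimum
#' generation over their two approach paths (logged).
#'
#' @param graph a [skeleton_graph()], normally after [merge_junctions()].
#' @param origin_mm origin coordinate in mm; the containing link(s) start
#'   generation 1.
#' @param side_branch_p collinearity threshold on the dot product.
#' @return A `branch_table` data frame: one row per link with `link_id`,
#'   `node_parent`, `node_child`, `generation`, `parent_link`,
#'   `is_side_branch`, `curved_mm`, `chord_mm`.
#' @export
assign_generations <- function(graph, origin_mm, side_branch_p = 0.95) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (side_branch_p <= 0 || side_branch_p >= 1)
    stop("side_branch_p must be in (0, 1)")
  o <- snap_to_node(graph, origin_mm)
  pos <- as.matrix(graph$nodes[, c("x_mm", "y_mm", "z_mm")])
  nlinks <- nrow(graph$links)
  incident <- vector("list", nrow(graph$nodes))
  for (li in seq_len(nlinks)) {
    a <- graph$links$node_a[li]; b <- graph$links$node_b[li]
    incident[[a]] <- c(incident[[a]], li)
    if (b != a) incident[[b]] <- c(incident[[b]], li)
  }
  generation <- rep(NA_integer_, nlinks)
  parent_link <- rep(NA_integer_, nlinks)
  side <- logical(nlinks)
  unit <- matrix(NA_real_, nlinks, 3) # oriented away from origin
  visited_node <- logical(nrow(graph$nodes))
  visited_node[o] <- TRUE
  any_cycle <- FALSE

  link_unit <- function(li, from) {
    to <- if (graph$links$node_a[li] == from) graph$links$node_b[li]
          else graph$links$node_a[li]
    v <- pos[to, ] - pos[from, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) v else v / nv
  }
  far_node <- function(li, from)
    if (graph$links$node_a[li] == from) graph$links$node_b[li]
    else graph$links$node_a[li]

  # queue entries: node to expand + the link (and generation) we arrived by
  queue <- list(list(node = o, via = NA_integer_))
  while (length(queue)) {
    it <- queue[[1]]; queue <- queue[-1]
    u <- it$node
    children <- incident[[u]][is.na(generation[incident[[u]]])]
    if (!length(children)) next
    if (is.na(it$via)) { # origin: all incident links are generation 1
      for (li in children) {
        generation[li] <- 1L
        unit[li, ] <- link_unit(li, u)
      }
    } else {
      gp <- generation[it$via]
      up <- unit[it$via, ]
      pvals <- vapply(children, function(li) sum(link_unit(li, u) * up),
                      numeric(1))
      inherit <- rep(FALSE, length(children))
      over <- pvals > side_branch_p
      if (any(over)) inherit[which.max(ifelse(over, pvals, -Inf))] <- TRUE
      for (k in seq_along(children)) {
        li <- children[k]
        generation[li] <- if (inherit[k]) gp else gp + 1L
        parent_link[li] <- it$via
        side[li] <- inherit[k]
        unit[li, ] <- link_unit(li, u)
      }
    }
    for (li in children) {
      v <- far_node(li, u)
      if (visited_node[v]) {
        any_cycle <- TRUE # link closes a cycle; generation from first approach
      } else {
        visited_node[v] <- TRUE
        queue[[length(queue) + 1]] <- list(node = v, via = li)
      }
    }
  }
  # second pass for cycle-closing links: minimum generation over both
  # approach paths (a closing link was assigned from the side reached first;
  # the other side may imply a smaller generation)
  if (any_cycle) {
    message("cycle(s) detected; closing links take the minimum generation ",
            "over their two approaches")
    repeat {
      changed <- FALSE
      for (li in which(!is.na(generation))) {
        for (end in unique(c(graph$links$node_a[li], graph$links$node_b[li]))) {
          inc <- setdiff(incident[[end]], li)
          inc <- inc[!is.na(generation[inc])]
          if (!length(inc)) next
          cand <- min(generation[inc]) + 1L
          if (cand < generation[li]) {
            generation[li] <- cand
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  reached <- !is.na(generation)
  if (!all(reached))
    message(sum(!reached), " link(s) outside the origin's connected ",
            "component; excluded from the branch table")
  node_parent <- integer(nlinks)
  node_child <- integer(nlinks)
  for (li in which(reached)) {
    # parent-side node: the node nearer the origin along the BFS
    pn <- if (is.na(parent_link[li])) o else {
      # the shared node between li and its parent link
      ends_p <- c(graph$links$node_a[parent_link[li]],
                  graph$links$node_b[parent_link[li]])
      ends_l <- c(graph$links$node_a[li], graph$links$node_b[li])
      intersect(ends_l, ends_p)[1]
    }
    node_parent[li] <- pn
    node_child[li] <- if (graph$links$node_a[li] == pn) graph$links$node_b[li]
                      else graph$links$node_a[li]
  }
  out <- data.frame(
    link_id = graph$links$id[reached],
    node_parent = node_parent[reached],
    node_child = node_child[reached],
    generation = generation[reached],
    parent_link = parent_link[reached],
    is_side_branch = side[reached],
    curved_mm = graph$links$curved_mm[reached],
    chord_mm = graph$links$chord_mm[reached])
  attr(out, "origin_node") <- o
  attr(out, "side_branch_p") <- side_branch_p
  class(out) <- c("branch_table", "data.frame")
  out
}

#' Per-generation branch statistics
#'
#' Arithmetic mean curved branch length and branch count per generation
#' (`l_Gn` in the region-partition formulas). Generations are contiguous
#' from 1 by construction of [assign_generations()].
#'
#' @param table a `branch_table`.
#' @return Data frame with columns `generation`, `n_branches`,
#'   `mean_curved_mm`, `total_curved_mm`.
#' @export
lengths_by_generation <- function(table) {
  stopifnot(inherits(table, "branch_table"), nrow(table) >= 1)
  gens <- sort(unique(table$generation))
  if (!identical(gens, seq_len(max(gens))))
    stop("generations are not contiguous from 1: ", paste(gens, collapse = ","))
  out <- do.call(rbind, lapply(gens, function(g) {
    v <- table$curved_mm[table$generation == g]
    data.frame(generation = g, n_branches = length(v),
               mean_curved_mm = mean(v), total_curved_mm = sum(v))
  }))
  rownames(out) <- NULL
  out
}
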