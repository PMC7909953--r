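#' Medial-axis skeleton of a binary mask
#'
#' Reduces a binary mask to a one-voxel-wide curve skeleton by homotopic
#' thinning. Border voxels are peeled in six directional subiterations per
#' pass; a voxel is deleted only while it is a *simple point* (its removal
#' changes neither the number of 26-connected foreground components nor the
#' number of 6-connected background components in its 3x3x3 neighbourhood),
#' so the skeleton preserves the connected components and loops of the mask.
#' Curve endpoints (voxels with exactly one 26-neighbour) are never deleted.
#' The result is a thinning fixed point: no removable simple point remains.
#'
#' @param grid a [voxel_grid()] with at least one foreground voxel.
#' @return An object of class `skeleton_voxels`: list with `points` (n x 3
#'   integer matrix of 1-based voxel indices), `dims`, `voxel_size_mm`,
#'   `label`.
#' @seealso [graph_from_skeleton()]
#' @export
skeletonize_mask <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!any(grid$occupancy)) stop("nothing to skeletonize: mask is empty")
  d <- dim(grid$occupancy)
  sk <- cpp_thin3d(grid$occupancy, d)
  structure(
    list(points = which(array(sk, d), arr.ind = TRUE),
         dims = d, voxel_size_mm = grid$voxel_size_mm, label = grid$label),
    class = "skeleton_voxels")
}

#' @export
print.skeleton_voxels <- function(x, ...) {
  cat(sprintf("<skeleton_voxels%s> %d voxels in %d x %d x %d grid @ %g mm\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              nrow(x$points), x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm))
  invisible(x)
}

# Occupancy array of a skeleton (used for idempotence checks and re-use of
# voxel-space kernels).
skeleton_as_grid <- function(skel) {
  occ <- array(FALSE, skel$dims)
  occ[skel$points] <- TRUE
  voxel_grid(occ, skel$voxel_size_mm, skel$label)
}

# 26-neighbourhood adjacency among a set of voxels. Returns a list with the
# per-point degree and an adjacency list of integer indices into `pts`.
voxel_adjacency <- function(pts, dims) {
  n <- nrow(pts)
  code <- (pts[, 1] - 1) + dims[1] * ((pts[, 2] - 1) + dims[2] * (pts[, 3] - 1))
  ord <- order(code)
  sorted <- code[ord]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(pts, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
          nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nbcode <- (nb[ok, 1] - 1) + dims[1] * ((nb[ok, 2] - 1) +
                                           dims[2] * (nb[ok, 3] - 1))
    pos <- findInterval(nbcode, sorted)
    hit <- pos > 0 & sorted[pmax(pos, 1)] == nbcode
    from <- c(from, which(ok)[hit])
    to <- c(to, ord[pos[hit]])
  }
  adj <- vector("list", n)
  if (length(from)) {
    sp <- split(to, from)
    adj[as.integer(names(sp))] <- sp
  }
  for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  list(degree = lengths(adj), adj = adj, code = code)
}

#' Convert a skeleton to a node/link network graph
#'
#' Classifies skeleton voxels by their number of 26-neighbours: one neighbour
#' makes an endpoint, two a chain point, three or more a junction voxel.
#' Mutually 26-adjacent junction voxels are grouped into a single node placed
#' at the cluster centroid; maximal chains of degree-2 voxels between nodes
#' become links carrying the ordered voxel-centre coordinates. Isolated
#' cycles (anastomoses) are represented by one artificial degree-2 anchor
#' node so the cycle becomes a self-link. Every skeleton voxel is accounted
#' for exactly once, either in a node cluster or in one link chain.
#'
#' @param skel a `skeleton_voxels` object from [skeletonize_mask()].
#' @return An object of class `skeleton_graph`; see [skeleton_graph()].
#' @export
graph_from_skeleton <- function(skel) {
  stopifnot(inherits(skel, "skeleton_voxels"))
  pts <- skel$points
  n <- nrow(pts)
  if (n == 0) stop("empty skeleton")
  vs <- skel$voxel_size_mm
  ad <- voxel_adjacency(pts, skel$dims)
  deg <- ad$degree
  adj <- ad$adj

  node_of <- integer(n) # 0 = chain voxel
  node_members <- list()
  node_kind <- character(0)

  # junction clusters (26-connected groups of junction voxels)
  jmask <- deg >= 3
  visited <- logical(n)
  for (i in order(ad$code)) {
    if (!jmask[i] || visited[i]) next
    comp <- integer(0)
    queue <- i
    visited[i] <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, c0)
      for (nb in adj[[c0]]) {
        if (jmask[nb] && !visited[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    node_members[[length(node_members) + 1]] <- sort(comp)
    node_kind <- c(node_kind, "junction")
  }
  # endpoints and isolated voxels are single-voxel nodes
  for (i in order(ad$code)) {
    if (deg[i] == 1 || deg[i] == 0) {
      node_members[[length(node_members) + 1]] <- i
      node_kind <- c(node_kind, "endpoint")
    }
  }
  for (k in seq_along(node_members)) node_of[node_members[[k]]] <- k

  chains <- list()
  chain_members <- list()
  link_a <- integer(0); link_b <- integer(0)
  chain_visited <- logical(n)

  node_pos <- function(k) {
    m <- node_members[[k]]
    colMeans(vox_centers_mm(pts[m, , drop = FALSE], vs))
  }
  positions <- t(vapply(seq_along(node_members), node_pos, numeric(3)))

  add_link <- function(a, b, interior) {
    link_a <<- c(link_a, a); link_b <<- c(link_b, b)
    ch <- rbind(positions[a, ],
                if (length(interior))
                  vox_centers_mm(pts[interior, , drop = FALSE], vs),
                positions[b, ])
    chains[[length(chains) + 1]] <<- unname(ch)
    chain_members[[length(chain_members) + 1]] <<- interior
  }

  # walks from node voxels through chain voxels
  for (k in seq_along(node_members)) {
    for (m in node_members[[k]]) {
      for (start in adj[[m]]) {
        if (node_of[start] != 0 || chain_visited[start]) next
        interior <- integer(0)
        prev <- m; cur <- start
        repeat {
          chain_visited[cur] <- TRUE
          interior <- c(interior, cur)
          nxt <- setdiff(adj[[cur]], prev)
          # prefer a node voxel to terminate; a chain voxel continues the walk
          if (!length(nxt)) { # dead end without node: should not occur
            nxt <- NA_integer_
            break
          }
          if (length(nxt) > 1) {
            # adjacent to several voxels (e.g. both ends of a tight loop);
            # terminate at a node if one is present
            nd <- nxt[node_of[nxt] != 0]
            nxt <- if (length(nd)) nd[1] else nxt[!chain_visited[nxt]][1]
            if (is.na(nxt)) break
          }
          if (node_of[nxt] != 0) break
          if (chain_visited[nxt]) { nxt <- NA_integer_; break }
          prev <- cur; cur <- nxt
        }
        if (!is.na(nxt) && node_of[nxt] != 0)
          add_link(k, node_of[nxt], interior)
      }
    }
  }

  # direct node-node adjacency (no interior chain voxels)
  pair_seen <- character(0)
  for (k in seq_along(node_members)) {
    for (m in node_members[[k]]) {
      for (nb in adj[[m]]) {
        k2 <- node_of[nb]
        if (k2 == 0 || k2 == k) next
        key <- paste(sort(c(k, k2)), collapse = "-")
        if (key %in% pair_seen) next
        pair_seen <- c(pair_seen, key)
        add_link(min(k, k2), max(k, k2), integer(0))
      }
    }
  }

  # isolated cycles: pure degree-2 components never reached from a node
  for (i in order(ad$code)) {
    if (chain_visited[i] || node_of[i] != 0 || deg[i] != 2) next
    # anchor node at this voxel
    node_members[[length(node_members) + 1]] <- i
    node_kind <- c(node_kind, "anchor")
    k <- length(node_members)
    node_of[i] <- k
    positions <- rbind(positions, vox_centers_mm(pts[i, , drop = FALSE], vs))
    interior <- integer(0)
    prev <- i; cur <- adj[[i]][1]
    while (node_of[cur] == 0) {
      chain_visited[cur] <- TRUE
      interior <- c(interior, cur)
      nxt <- setdiff(adj[[cur]], prev)[1]
      prev <- cur; cur <- nxt
    }
    add_link(k, k, interior)
  }

  nodes <- data.frame(
    id = seq_along(node_members),
    x_mm = positions[, 1], y_mm = positions[, 2], z_mm = positions[, 3],
    kind = node_kind,
    n_voxels = lengths(node_members))
  links <- data.frame(
    id = seq_along(link_a), node_a = link_a, node_b = link_b,
    n_chain = lengths(chain_members))
  links$curved_mm <- vapply(chains, function(ch)
    sum(sqrt(rowSums((ch[-1, , drop = FALSE] -
                      ch[-nrow(ch), , drop = FALSE])^2))), numeric(1))
  links$chord_mm <- sqrt(rowSums((positions[link_a, , drop = FALSE] -
                                  positions[link_b, , drop = FALSE])^2))
  degree <- tabulate(c(link_a, link_b), nbins = nrow(nodes))
  nodes$degree <- degree

  skeleton_graph(nodes, links, chains,
                 voxel_size_mm = vs, dims = skel$dims, label = skel$label,
                 node_voxels = lapply(node_members, function(m)
                   pts[m, , drop = FALSE]),
                 chain_voxels = lapply(chain_members, function(m)
                   pts[m, , drop = FALSE]),
                 n_skeleton_voxels = n)
}

#' Skeleton network graph
#'
#' Constructor for the node/link graph representation of a skeleton. Usually
#' produced by [graph_from_skeleton()]; exposed so that graphs can also be
#' built programmatically (e.g. analytic test geometries).
#'
#' @param nodes data frame with columns `id`, `x_mm`, `y_mm`, `z_mm`, `kind`
#'   (`"endpoint"`, `"junction"`, or `"anchor"`), and optionally `n_voxels`,
#'   `degree`.
#' @param links data frame with columns `id`, `node_a`, `node_b`, and
#'   optionally `n_chain`, `curved_mm`, `chord_mm` (recomputed if absent).
#' @param chains list (one per link) of ordered coordinate matrices in mm;
#'   each chain must start and end at its nodes' positions.
#' @param voxel_size_mm voxel size the skeleton was traced on.
#' @param dims,label,node_voxels,chain_voxels,n_skeleton_voxels optional
#'   provenance carried along from [graph_from_skeleton()].
#' @return An object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, links, chains, voxel_size_mm,
                           dims = NULL, label = "", node_voxels = NULL,
                           chain_voxels = NULL, n_skeleton_voxels = NULL) {
  stopifnot(is.data.frame(nodes), is.data.frame(links),
            length(chains) == nrow(links))
  if (is.null(nodes$n_voxels)) nodes$n_voxels <- 1L
  if (is.null(links$n_chain))
    links$n_chain <- vapply(chains, function(ch) max(0L, nrow(ch) - 2L),
                            integer(1))
  if (is.null(links$curved_mm))
    links$curved_mm <- vapply(chains, function(ch)
      sum(sqrt(rowSums((ch[-1, , drop = FALSE] -
                        ch[-nrow(ch), , drop = FALSE])^2))), numeric(1))
  pos <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  if (is.null(links$chord_mm))
    links$chord_mm <- sqrt(rowSums((pos[links$node_a, , drop = FALSE] -
                                    pos[links$node_b, , drop = FALSE])^2))
  if (is.null(nodes$degree))
    nodes$degree <- tabulate(c(links$node_a, links$node_b),
                             nbins = nrow(nodes))
  for (li in seq_along(chains)) {
    ch <- chains[[li]]
    if (max(abs(ch[1, ] - pos[links$node_a[li], ])) > 1e-6 ||
        max(abs(ch[nrow(ch), ] - pos[links$node_b[li], ])) > 1e-6)
      stop("chain ", li, " does not start/end at its nodes' positions")
  }
  structure(
    list(nodes = nodes, links = links, chains = chains,
         voxel_size_mm = voxel_size_mm, dims = dims, label = label,
         node_voxels = node_voxels, chain_voxels = chain_voxels,
         n_skeleton_voxels = n_skeleton_voxels),
    class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph%s> %d nodes (%d endpoints, %d junctions), %d links, %.3f mm curved\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    nrow(x$nodes), sum(x$nodes$kind == "endpoint"),
    sum(x$nodes$kind == "junction"), nrow(x$links), sum(x$links$curved_mm)))
  invisible(x)
}

# total voxels represented by the graph (node clusters + chain interiors);
# equals the skeleton voxel count when built by graph_from_skeleton.
graph_voxel_count <- function(graph) {
  sum(graph$nodes$n_voxels) + sum(graph$links$n_chain)
}

#' Convert a skeleton graph to an igraph object
#'
#' Edge attribute `weight` carries the curved link length in mm, `link_id`
#' the row of `graph$links`.
#'
#' @param graph a [skeleton_graph()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$links$node_a, to = graph$links$node_b,
               weight = graph$links$curved_mm, link_id = graph$links$id),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, kind = graph$nodes$kind))
  g
}

#' Export a skeleton graph
#'
#' `write_graph_csv()` writes the node and link tables as a CSV pair;
#' `write_graphml()` writes GraphML (via igraph) with positions and lengths
#' as attributes.
#'
#' @param graph a [skeleton_graph()].
#' @param nodes_path,links_path,path output file paths.
#' @return The output path(s), invisibly.
#' @export
write_graph_csv <- function(graph, nodes_path, links_path) {
  stopifnot(inherits(graph, "skeleton_graph"))
  write.csv(graph$nodes, nodes_path, row.names = FALSE)
  write.csv(graph$links, links_path, row.names = FALSE)
  invisible(c(nodes_path, links_path))
}

#' @rdname write_graph_csv
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  igraph::V(g)$x <- graph$nodes$x_mm
  igraph::V(g)$y <- graph$nodes$y_mm
  igraph::V(g)$z <- graph$nodes$z_mm
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Prune short terminal spur links
#'
#' Homotopic thinning can leave one- or two-voxel terminal spurs where a
#' surface bump of the rasterized/segmented tube transiently became a locked
#' curve endpoint. This removes endpoint links whose curved length is below
#' `min_length_mm` and whose far node is a junction, then dissolves any
#' junction left with degree 2 by splicing its two incident links into one.
#' Pruning is off by default throughout the package (short terminal
#' branches in real data are kept); enable it for noisy masks or when exact
#' phantom topology is required.
#'
#' @param graph a [skeleton_graph()].
#' @param min_length_mm prune endpoint links shorter than this (mm).
#' @return A [skeleton_graph()] without sub-threshold spurs.
#' @export
prune_spurs <- function(graph, min_length_mm) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (min_length_mm <= 0) return(graph)
  repeat {
    nodes <- graph$nodes; links <- graph$links
    deg <- tabulate(c(links$node_a, links$node_b), nbins = nrow(nodes))
    leaf <- nodes$id[deg[nodes$id] == 1 & nodes$kind == "endpoint"]
    is_junction <- function(id) nodes$kind[match(id, nodes$id)] == "junction"
    spur <- vapply(seq_len(nrow(links)), function(li) {
      a <- links$node_a[li]; b <- links$node_b[li]
      if (links$curved_mm[li] >= min_length_mm) return(FALSE)
      (a %in% leaf && is_junction(b)) || (b %in% leaf && is_junction(a))
    }, logical(1))
    if (!any(spur)) break
    drop_nodes <- intersect(leaf, c(links$node_a[spur], links$node_b[spur]))
    links <- links[!spur, , drop = FALSE]
    chains <- graph$chains[!spur]
    # splice junctions reduced to degree 2; demote those reduced to degree 1
    repeat {
      deg <- tabulate(c(links$node_a, links$node_b), nbins = nrow(nodes))
      two <- setdiff(nodes$id[deg[nodes$id] == 2 & nodes$kind == "junction"],
                     drop_nodes)
      two <- Filter(function(id) {
        inc <- which(links$node_a == id | links$node_b == id)
        length(inc) == 2 # not a self-link
      }, two)
      if (!length(two)) break
      id <- two[[1]]
      inc <- which(links$node_a == id | links$node_b == id)
      l1 <- inc[1]; l2 <- inc[2]
      orient <- function(li, endpoint_last) {
        ch <- chains[[li]]
        at_b <- links$node_b[li] == id
        if (endpoint_last != at_b) ch <- ch[rev(seq_len(nrow(ch))), ]
        ch
      }
      ch1 <- orient(l1, TRUE)   # ends at the dissolved node
      ch2 <- orient(l2, FALSE)  # starts at the dissolved node
      far1 <- setdiff(unlist(links[l1, c("node_a", "node_b")]), id)[1]
      far2 <- setdiff(unlist(links[l2, c("node_a", "node_b")]), id)[1]
      chains[[l1]] <- rbind(ch1, ch2[-1, , drop = FALSE])
      links$node_a[l1] <- far1
      links$node_b[l1] <- far2
      links$n_chain[l1] <- links$n_chain[l1] + links$n_chain[l2] +
        nodes$n_voxels[match(id, nodes$id)]
      links$curved_mm[l1] <- NA_real_
      links <- links[-l2, , drop = FALSE]
      chains <- chains[-l2]
      drop_nodes <- c(drop_nodes, id)
    }
    deg <- tabulate(c(links$node_a, links$node_b), nbins = nrow(nodes))
    nodes$kind[deg[nodes$id] == 1 & nodes$kind == "junction"] <- "endpoint"
    keep <- !(nodes$id %in% drop_nodes)
    nodes <- nodes[keep, , drop = FALSE]
    old <- nodes$id
    nodes$id <- seq_len(nrow(nodes))
    links$node_a <- match(links$node_a, old)
    links$node_b <- match(links$node_b, old)
    links$id <- seq_len(nrow(links))
    nodes$degree <- NULL
    links$curved_mm <- NULL; links$chord_mm <- NULL
    graph <- skeleton_graph(nodes, links, chains,
                            voxel_size_mm = graph$voxel_size_mm,
                            dims = graph$dims, label = graph$label,
                            n_skeleton_voxels = graph$n_skeleton_voxels)
  }
  graph
}
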