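# Build a skeleton_graph from named vertex positions and an edge list --
# analytic graphs for branching/region tests, no rasterization involved.
# vertices: named list of length-3 mm positions; edges: list of c(from, to)
# name pairs; chains default to straight two-point segments but can be
# overridden via the `chains` list (named "from-to").
toy_graph <- function(vertices, edges, chains = list(), voxel_size_mm = VS) {
  vn <- names(vertices)
  pos <- do.call(rbind, vertices)
  deg <- table(factor(unlist(edges), levels = vn))
  kind <- ifelse(deg >= 3, "junction", ifelse(deg == 1, "endpoint", "anchor"))
  # degree-2 pass-through vertices occur in synthetic chains; call them
  # junctions only when degree >= 3, endpoints at degree 1
  nodes <- data.frame(id = seq_along(vn),
                      x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                      kind = as.character(kind))
  links <- data.frame(id = seq_along(edges),
                      node_a = vapply(edges, function(e) match(e[1], vn),
                                      integer(1)),
                      node_b = vapply(edges, function(e) match(e[2], vn),
                                      integer(1)))
  chain_list <- lapply(seq_along(edges), function(i) {
    key <- paste(edges[[i]], collapse = "-")
    if (!is.null(chains[[key]])) chains[[key]]
    else rbind(vertices[[edges[[i]][1]]], vertices[[edges[[i]][2]]])
  })
  skeleton_graph(nodes, links, chain_list, voxel_size_mm = voxel_size_mm)
}

# Tiny union-find oracle (independent of the implementation's internals).
bf_merge_groups <- function(pos, threshold) {
  n <- nrow(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < threshold &&
          grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}
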