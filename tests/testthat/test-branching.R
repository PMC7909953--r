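# Two consecutive bifurcations `gap_mm` apart on the x axis: the first
# splits off one leaf arm and continues to the second, which splits into two.
h_graph <- function(gap_mm) {
  toy_graph(
    vertices = list(
      o  = c(-1, 0, 0),
      j1 = c(0, 0, 0),
      j2 = c(gap_mm, 0, 0),
      a1 = c(-0.3, 1, 0),
      b1 = c(gap_mm + 0.3, 1, 0), b2 = c(gap_mm + 0.3, -1, 0)),
    edges = list(c("o", "j1"), c("j1", "a1"),
                 c("j1", "j2"), c("j2", "b1"), c("j2", "b2")))
}

test_that("junctions closer than the merge radius collapse to one node", {
  g <- merge_junctions(h_graph(0.1), 0.2)
  expect_equal(sum(g$nodes$kind == "junction"), 1)
  j <- g$nodes[g$nodes$kind == "junction", ]
  expect_equal(j$degree, 4) # one input + three arms; internal link absorbed
  expect_equal(unname(unlist(j[, c("x_mm", "y_mm", "z_mm")])),
               c(0.05, 0, 0)) # centroid of the two members
  expect_equal(nrow(g$links), 4)

  # junctions 0.3 mm apart stay distinct
  g2 <- merge_junctions(h_graph(0.3), 0.2)
  expect_equal(sum(g2$nodes$kind == "junction"), 2)
  expect_equal(nrow(g2$links), 5)
})

test_that("merging is transitive and matches a union-find oracle", {
  # three bifurcations in a row, 0.15 mm apart (first-to-last 0.3 mm)
  tg <- toy_graph(
    vertices = list(
      o = c(-1, 0, 0), j1 = c(0, 0, 0), j2 = c(0.15, 0, 0),
      j3 = c(0.30, 0, 0),
      l1 = c(0, 1, 0), l2 = c(0.15, 1, 0), l3 = c(0.3, 1, 0),
      t1 = c(1.3, 0, 0)),
    edges = list(c("o", "j1"), c("j1", "l1"), c("j1", "j2"), c("j2", "l2"),
                 c("j2", "j3"), c("j3", "l3"), c("j3", "t1")))
  merged <- merge_junctions(tg, 0.2)
  expect_equal(sum(merged$nodes$kind == "junction"), 1)

  jpos <- rbind(c(0, 0, 0), c(0.15, 0, 0), c(0.30, 0, 0))
  expect_equal(length(unique(bf_merge_groups(jpos, 0.2))), 1)
  # oracle agrees that 0.2-spacing junctions would NOT merge transitively
  jpos2 <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.50, 0, 0))
  expect_equal(length(unique(bf_merge_groups(jpos2, 0.2))), 3)
  expect_equal(sum(merge_junctions(
    toy_graph(
      vertices = list(
        o = c(-1, 0, 0), j1 = c(0, 0, 0), j2 = c(0.25, 0, 0),
        j3 = c(0.50, 0, 0),
        l1 = c(0, 1, 0), l2 = c(0.25, 1, 0), l3 = c(0.5, 1, 0),
        t1 = c(1.5, 0, 0)),
      edges = list(c("o", "j1"), c("j1", "l1"), c("j1", "j2"),
                   c("j2", "l2"), c("j2", "j3"), c("j3", "l3"),
                   c("j3", "t1"))), 0.2)$nodes$kind == "junction"), 3)
})

test_that("merge with threshold zero is the identity and is monotone", {
  tg <- h_graph(0.1)
  expect_identical(merge_junctions(tg, 0), tg)
  tr <- make_tree(recovery_spec(3, n_generations = 3))
  gr <- graph_from_skeleton(skeletonize_mask(rasterize(tr)))
  counts <- vapply(c(0, 0.05, 0.2, 0.5, 1, 2),
                   function(th) nrow(merge_junctions(gr, th)$nodes),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("furcations are classified by output count", {
  origin <- c(-1, 0, 0)
  expect_equal(unclass(classify_furcations(h_graph(0.3), origin))[1:3],
               list(n_bifurcation = 2L, n_trifurcation = 0L, n_higher = 0L))
  # two merged bifurcations become one trifurcation (1 input, 3 outputs)
  merged <- merge_junctions(h_graph(0.1), 0.2)
  cen <- classify_furcations(merged, origin)
  expect_equal(cen$n_trifurcation, 1)
  expect_equal(cen$n_bifurcation + cen$n_trifurcation + cen$n_higher,
               cen$n_junctions)

  star3 <- toy_graph(
    vertices = list(o = c(-1, 0, 0), j = c(0, 0, 0),
                    t1 = c(1, 0, 0), t2 = c(0, 1, 0), t3 = c(0, -1, 0)),
    edges = list(c("o", "j"), c("j", "t1"), c("j", "t2"), c("j", "t3")))
  expect_equal(classify_furcations(star3, origin)$n_trifurcation, 1)
  star4 <- toy_graph(
    vertices = list(o = c(-1, 0, 0), j = c(0, 0, 0),
                    t1 = c(1, 0, 0), t2 = c(0, 1, 0), t3 = c(0, -1, 0),
                    t4 = c(0, 0, 1)),
    edges = list(c("o", "j"), c("j", "t1"), c("j", "t2"), c("j", "t3"),
                 c("j", "t4")))
  expect_equal(classify_furcations(star4, origin)$n_higher, 1)
})

test_that("generations start at 1 and increment unless nearly collinear", {
  # straight run with a perpendicular child and a nearly-collinear child
  ang <- acos(0.99) # p = 0.99 > 0.95: same generation
  tg <- toy_graph(
    vertices = list(
      o = c(0, 0, 0), j = c(1, 0, 0),
      straightish = c(1, 0, 0) + c(cos(ang), sin(ang), 0),
      perp = c(1, 1, 0)),
    edges = list(c("o", "j"), c("j", "straightish"), c("j", "perp")))
  tab <- assign_generations(tg, c(0, 0, 0), side_branch_p = 0.95)
  expect_equal(tab$generation[tab$link_id == 1], 1) # root link
  gen <- setNames(tab$generation, tab$link_id)
  expect_equal(unname(gen["2"]), 1) # p = 0.99 inherits
  expect_true(tab$is_side_branch[tab$link_id == 2])
  expect_equal(unname(gen["3"]), 2) # perpendicular child increments
  expect_false(tab$is_side_branch[tab$link_id == 3])
})

test_that("only the most collinear child continues the parent generation", {
  a1 <- acos(0.97); a2 <- acos(0.99)
  tg <- toy_graph(
    vertices = list(
      o = c(0, 0, 0), j = c(1, 0, 0),
      c1 = c(1 + cos(a1), sin(a1), 0),
      c2 = c(1 + cos(a2), -sin(a2), 0)),
    edges = list(c("o", "j"), c("j", "c1"), c("j", "c2")))
  tab <- assign_generations(tg, c(0, 0, 0))
  gen <- setNames(tab$generation, tab$link_id)
  expect_equal(unname(gen["3"]), 1) # p = 0.99 wins
  expect_equal(unname(gen["2"]), 2) # p = 0.97 increments anyway
  expect_equal(sum(tab$is_side_branch), 1)
})

test_that("generation labels are invariant under rigid rotation", {
  tr <- make_tree(recovery_spec(7, n_generations = 3))
  gr <- merge_junctions(graph_from_skeleton(skeletonize_mask(rasterize(tr))),
                        0.2)
  tab <- assign_generations(gr, tr$origin_mm)
  # rotate the graph rigidly: node positions and chains
  ax <- c(2, -1, 1) / sqrt(6); ang <- 1.1
  rot <- function(p) t(apply(p, 1, ductr:::rodrigues, axis = ax, angle = ang))
  pos <- rot(as.matrix(gr$nodes[, c("x_mm", "y_mm", "z_mm")]))
  nodes2 <- gr$nodes
  nodes2$x_mm <- pos[, 1]; nodes2$y_mm <- pos[, 2]; nodes2$z_mm <- pos[, 3]
  nodes2$degree <- NULL
  links2 <- gr$links[, c("id", "node_a", "node_b", "n_chain")]
  gr2 <- skeleton_graph(nodes2, links2, lapply(gr$chains, rot),
                        voxel_size_mm = gr$voxel_size_mm)
  tab2 <- assign_generations(gr2, rot(matrix(tr$origin_mm, 1))[1, ])
  expect_equal(tab2$generation[order(tab2$link_id)],
               tab$generation[order(tab$link_id)])
})

test_that("per-generation lengths conserve the total curved length", {
  tr <- make_tree(recovery_spec(13, n_generations = 4))
  gr <- merge_junctions(graph_from_skeleton(skeletonize_mask(rasterize(tr))),
                        0.2)
  tab <- assign_generations(gr, tr$origin_mm)
  lgn <- lengths_by_generation(tab)
  expect_equal(sum(lgn$n_branches * lgn$mean_curved_mm), sum(tab$curved_mm))
  expect_equal(lgn$generation, 1:4)
  expect_equal(lgn$n_branches, c(1, 2, 4, 8))
})

test_that("programmed halving branch lengths are recovered per generation", {
  spec <- phantom_spec(n_generations = 3,
                       length_per_generation = c(1.6, 0.8, 0.4),
                       bifurcation_angle_deg = 40,
                       radius_root_mm = 0.045, radius_taper = 0.85,
                       seed = 19)
  tr <- make_tree(spec)
  gr <- merge_junctions(graph_from_skeleton(skeletonize_mask(rasterize(tr))),
                        0.2)
  lgn <- lengths_by_generation(assign_generations(gr, tr$origin_mm))
  ratios <- lgn$mean_curved_mm[-1] / lgn$mean_curved_mm[-3]
  expect_true(all(abs(ratios - 0.5) < 0.1 * 0.5 + 0.05))
})
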