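test_that("branch-point distances find the true nearest neighbour", {
  pts <- matrix(stats::runif(30, 0, 5), 10, 3)
  same <- branch_point_distances(pts, pts)
  expect_true(all(same$d_bp_mm == 0))

  bp <- branch_point_distances(matrix(c(1, 0, 0), 1),
                               rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(bp$d_bp_mm, 1)
  expect_equal(unlist(bp[, c("pv_x_mm", "pv_y_mm", "pv_z_mm")]),
               c(pv_x_mm = 0, pv_y_mm = 0, pv_z_mm = 0))
  expect_error(branch_point_distances(pts, pts[0, ]), "empty")
})

test_that("nearest neighbours match the O(n^2) brute-force oracle", {
  set.seed(7)
  bd <- matrix(stats::runif(600, 0, 10), 200, 3)
  pv <- matrix(stats::runif(600, 0, 10), 200, 3)
  got <- branch_point_distances(bd, pv)
  oracle <- bf_nearest(bd, pv)
  expect_equal(got$d_bp_mm, oracle$distance)
  expect_equal(as.matrix(got[, c("pv_x_mm", "pv_y_mm", "pv_z_mm")]),
               pv[oracle$index, ], ignore_attr = TRUE)

  # equidistant tie resolves to the lexicographically smallest coordinate
  tie <- branch_point_distances(matrix(0, 1, 3),
                                rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)))
  expect_equal(unlist(tie[, c("pv_x_mm", "pv_y_mm", "pv_z_mm")]),
               c(pv_x_mm = -1, pv_y_mm = 0, pv_z_mm = 0))
})

test_that("overlapping masks have zero gap everywhere", {
  g <- cylinder_grid(4, 40)
  sk <- skeletonize_mask(g)
  gaps <- gap_distances(sk, sk, g, g)
  expect_true(all(gaps$d_gap_mm == 0))
  expect_equal(max_gap(gaps), 0)
})

test_that("parallel cylinders recover the analytic surface gap", {
  r <- 4; sep <- 20
  dims <- c(70, 17, 40)
  a <- capsule_grid(matrix(c(5, 8.5, 8.5), 1), matrix(c(65, 8.5, 8.5), 1),
                    r, dims)
  b <- capsule_grid(matrix(c(5, 8.5, 8.5 + sep), 1),
                    matrix(c(65, 8.5, 8.5 + sep), 1), r, dims)
  ska <- skeletonize_mask(a); skb <- skeletonize_mask(b)
  gaps <- gap_distances(ska, skb, a, b)
  interior <- gaps$bd_x_mm > 15 * VS & gaps$bd_x_mm < 55 * VS
  analytic <- (sep - 2 * r) * VS
  # centre-to-centre span of the non-resin voxels loses up to half a voxel
  # of surface at each end, so allow two voxels here (worst case: surfaces
  # aligned with voxel centres, as in this axis-aligned geometry)
  expect_true(all(abs(gaps$d_gap_mm[interior] - analytic) <= 2 * VS + 1e-9))
  # the gap never exceeds the skeleton-to-skeleton distance
  expect_true(all(gaps$d_gap_mm <= gaps$skel_dist_mm + 1e-12))
  # radius-subtraction variant agrees for circular cross-sections
  gaps_r <- gap_distances(ska, skb, a, b, method = "radius")
  expect_true(all(abs(gaps_r$d_gap_mm[interior] - analytic) <= 2 * VS + 1e-9))
  # co-registration guard
  expect_error(gap_distances(ska, skb, a,
                             voxel_grid(b$occupancy, 0.010)), "co-registered")
})

test_that("programmed uniform and ramped gaps are recovered", {
  spec <- phantom_spec(n_generations = 2,
                       length_per_generation = c(1.2, 0.9),
                       companion_gap_mm = 0.2, seed = 5)
  dp <- make_dual_phantom(spec)
  gaps <- gap_distances(skeletonize_mask(dp$grid_bd),
                        skeletonize_mask(dp$grid_pv),
                        dp$grid_bd, dp$grid_pv)
  programmed <- dp$programmed_gap(gaps$bd_x_mm)
  expect_lte(mean(abs(gaps$d_gap_mm - programmed)), 2 * VS)

  ramp <- make_dual_phantom(phantom_spec(
    n_generations = 2, length_per_generation = c(1.5, 1.1),
    companion_gap_mm = c(0, 0.5), seed = 6))
  gr <- gap_distances(skeletonize_mask(ramp$grid_bd),
                      skeletonize_mask(ramp$grid_pv),
                      ramp$grid_bd, ramp$grid_pv)
  prog <- ramp$programmed_gap(gr$bd_x_mm)
  expect_lte(mean(abs(gr$d_gap_mm - prog)), 2 * VS)
  expect_equal(max_gap(gr), 0.5, tolerance = 2 * VS / 0.5)
})

test_that("cumulative curves bin as hand-computed and end at 100%", {
  cc <- cumulative_curve(c(0.1, 0.2), lo_mm = 0.015, hi_mm = 0.3)
  expect_equal(cc$cumulative_percent[cc$bin_upper_edge_mm == 0.105], 50)
  expect_true(all(cc$cumulative_percent[cc$bin_upper_edge_mm >= 0.21] == 100))

  zeros <- cumulative_curve(rep(0, 5), lo_mm = 0.015, hi_mm = 0.15)
  expect_equal(zeros$cumulative_percent[1], 100)

  expect_error(cumulative_curve(numeric(0), 0.015, 1), "empty")
  expect_error(cumulative_curve(1, 0.5, 0.2), "hi_mm > lo_mm")

  set.seed(33)
  for (i in 1:20) {
    d <- stats::rexp(sample(1:400, 1), rate = 1 / 0.3)
    cc <- cumulative_curve(d, 0.015, 1.5)
    expect_true(all(diff(cc$cumulative_percent) >= 0))
    expect_equal(cc$cumulative_percent[nrow(cc)], 100)
  }
})

test_that("distance tables re-summarize to hand-computed cumulative stats", {
  # synthetic per-sample distance table in the one-row-per-distance layout
  path <- withr::local_tempfile(fileext = ".csv")
  d <- c(0.05, 0.12, 0.12, 0.40, 0.90)
  write_distance_table(d, path, sample = "s1", genotype = "wt")
  tab <- read.csv(path)
  expect_equal(names(tab), c("sample", "genotype", "distance_mm"))
  cc <- cumulative_curve(tab$distance_mm, 0.015, 1.5)
  # hand-computed: 20% at 0.06, 60% at 0.12, 80% at 0.405, 100% at 0.9
  expect_equal(cc$cumulative_percent[cc$bin_upper_edge_mm == 0.06], 20)
  expect_equal(cc$cumulative_percent[cc$bin_upper_edge_mm == 0.12], 60)
  expect_equal(cc$cumulative_percent[cc$bin_upper_edge_mm == 0.405], 80)
  expect_equal(max(cc$cumulative_percent), 100)
  expect_equal(100 * mean(tab$distance_mm <= 0.5), 80) # within 0.5 mm
})
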