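test_that("curved length sums consecutive Euclidean steps", {
  # 3 collinear voxel-adjacent points at 0.012 mm
  ch <- rbind(c(0, 0, 0), c(0.012, 0, 0), c(0.024, 0, 0))
  expect_equal(curved_length(ch), 0.024)
  # one body-diagonal step
  ch2 <- rbind(c(0, 0, 0), c(0.012, 0.012, 0.012))
  expect_equal(curved_length(ch2), sqrt(3) * 0.012)
  expect_equal(curved_length(matrix(c(1, 2, 3), 1)), 0)
})

test_that("chord and tortuosity anchors: straight 0%, semicircle 57.08%", {
  straight <- cbind(seq(0, 5, by = 0.01), 0, 0)
  expect_equal(tortuosity_percent(curved_length(straight),
                                  chord_length(straight)), 0)
  semi <- semicircle_chain(r = 1)
  expect_equal(chord_length(semi), 2)
  expect_equal(tortuosity_percent(curved_length(semi), chord_length(semi)),
               (pi / 2 - 1) * 100, tolerance = 1e-4)
  expect_error(tortuosity_percent(1, 0), "chord")
})

test_that("sinusoidal chain tortuosity matches the quadrature oracle", {
  a <- 0.08; lam <- 0.5; L <- 2 # integer number of periods
  s <- seq(0, L, length.out = 4001)
  chain <- cbind(s, a * sin(2 * pi * s / lam), 0)
  oracle <- stats::integrate(function(t)
    sqrt(1 + (2 * pi * a / lam * cos(2 * pi * t / lam))^2), 0, L,
    subdivisions = 2000L)$value
  measured <- curved_length(chain)
  expect_equal(measured, oracle, tolerance = 1e-4)
  expect_equal(tortuosity_percent(measured, chord_length(chain)),
               (oracle / L - 1) * 100, tolerance = 1e-3)
})

test_that("volume is voxel count times voxel volume", {
  occ <- array(FALSE, c(20, 10, 10)); occ[seq_len(1000)] <- TRUE
  g <- voxel_grid(occ, 0.012)
  expect_equal(system_volume(g), 1000 * 0.012^3)
  expect_equal(volume_ratio(g, g), 1)
  expect_equal(system_volume(voxel_grid(array(FALSE, c(3, 3, 3)), 1)), 0)

  # rasterized cylinder: pi r^2 L within 5% (rasterization error)
  r_vox <- 5; L_vox <- 80
  cyl <- cylinder_grid(r_vox, L_vox)
  analytic <- pi * (r_vox * VS)^2 * (L_vox * VS) +
    4 / 3 * pi * (r_vox * VS)^3 # capsule caps
  expect_equal(system_volume(cyl), analytic, tolerance = 0.05)
})

test_that("main branch follows the longest origin-to-endpoint path", {
  gY <- y_grid(trunk = 40, arm1 = 30, arm2 = 50)
  grY <- graph_from_skeleton(skeletonize_mask(gY))
  origin <- c(9.5, 9.5, 9.5) * VS # near the trunk start
  # snap origin to the actual trunk endpoint node
  ep <- grY$nodes[grY$nodes$kind == "endpoint", ]
  origin <- unlist(ep[which.min(ep$x_mm), c("x_mm", "y_mm", "z_mm")])
  mb <- main_branch(grY, origin)
  # total curved length must be about trunk + long arm (not the short arm)
  expect_equal(mb$curved_mm, (40 + 50) * VS, tolerance = 0.08)
  # the tip is the far end of the 50-voxel arm (y decreasing side)
  tip <- mb$chain[nrow(mb$chain), ]
  expect_lt(tip[2], origin[2])

  # straight tube: the main branch is the whole skeleton
  cyl <- cylinder_grid(3, 40)
  grC <- graph_from_skeleton(skeletonize_mask(cyl))
  o <- unlist(grC$nodes[1, c("x_mm", "y_mm", "z_mm")])
  expect_equal(main_branch(grC, o)$curved_mm, curved_length(grC))

  expect_error(main_branch(grC, o + c(0, 50 * VS, 0)), "origin")
})

test_that("main branch matches the phantom's designated trunk", {
  tr <- make_tree(recovery_spec(5, n_generations = 4))
  gr <- merge_junctions(graph_from_skeleton(skeletonize_mask(rasterize(tr))),
                        0.2)
  mb <- main_branch(gr, tr$origin_mm)
  # all root-to-leaf paths tie in programmed length in this symmetric
  # phantom, so assert the path length (curved carries the digital
  # chain-length bias) and that the tip is a true leaf tip
  expect_equal(mb$curved_mm, tr$trunk$curved_mm, tolerance = 0.10)
  expect_equal(length(mb$link_ids), length(tr$trunk$ids))
  leaf_tips <- do.call(rbind, lapply(tr$segments, function(s)
    if (s$generation == 4) s$points[nrow(s$points), ]))
  tip <- mb$chain[nrow(mb$chain), ]
  expect_lt(min(sqrt(rowSums(sweep(leaf_tips, 2, tip)^2))), 3 * VS)
})

test_that("radius_at recovers local radii from the eroded boundary", {
  # digital ball of radius 5 voxels
  dims <- c(15, 15, 15); ctr <- c(8, 8, 8)
  idx <- as.matrix(expand.grid(x = 1:15, y = 1:15, z = 1:15))
  occ <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 5, dims)
  ball <- voxel_grid(occ, VS)
  r <- radius_at(ball, (ctr - 0.5) * VS)
  expect_equal(r / VS, 5, tolerance = 1 / 5) # 5 +- 1 voxel

  # 1-voxel-thick line: radius at most one voxel
  occ2 <- array(FALSE, c(20, 5, 5)); occ2[3:18, 3, 3] <- TRUE
  line <- voxel_grid(occ2, VS)
  expect_lte(radius_at(line, c(9.5, 2.5, 2.5) * VS), VS)

  # cylinder interior axis points: r +- 1 voxel
  cyl <- cylinder_grid(4, 40)
  ctr_y <- (dim(cyl)[2] / 2 + 0.5 - 0.5) * VS
  pts <- cbind(seq(15, 30) * VS, ctr_y, ctr_y)
  rr <- radius_at(cyl, pts)
  expect_true(all(abs(rr / VS - 4) <= 1))

  expect_error(radius_at(cyl, c(0.5, 0.5, 0.5) * VS), "outside")
})

test_that("diameter profile samples every step and smooths over neighbours", {
  # analytic chain of 7 mm sampled at 1.5 mm
  cyl <- cylinder_grid(4, 600) # 7.2 mm long
  gr <- graph_from_skeleton(skeletonize_mask(cyl))
  o <- unlist(gr$nodes[which.min(gr$nodes$x_mm), c("x_mm", "y_mm", "z_mm")])
  mb <- main_branch(gr, o)
  prof <- diameter_profile(cyl, mb, step_mm = 1.5)
  expect_equal(prof$position_mm,
               seq(0, curved_length(mb), by = 1.5))
  # constant radius: flat profile within one voxel
  expect_lt(max(prof$diameter_raw_mm) - min(prof$diameter_raw_mm), VS)
  # programmed diameter 2r recovered within one voxel
  expect_lte(abs(mean(prof$diameter_smoothed_mm) - 8 * VS), VS)

  # short branch: single sample with a warning
  short <- cylinder_grid(3, 30)
  gs <- graph_from_skeleton(skeletonize_mask(short))
  os <- unlist(gs$nodes[1, c("x_mm", "y_mm", "z_mm")])
  expect_warning(p1 <- diameter_profile(short, main_branch(gs, os)),
                 "shorter")
  expect_equal(nrow(p1), 1)
})

test_that("a tapering cone profiles as monotonically decreasing diameters", {
  # linear taper from 6 to 2 voxels over 500 voxels
  n <- 25
  xs <- seq(10, 510, length.out = n + 1)
  rads <- seq(6, 2, length.out = n + 1)
  dims <- c(520, 21, 21)
  p0 <- cbind(xs[-(n + 1)], 10.5, 10.5); p1 <- cbind(xs[-1], 10.5, 10.5)
  cone <- capsule_grid(p0, p1, rads[-(n + 1)], dims)
  gr <- graph_from_skeleton(skeletonize_mask(cone))
  o <- unlist(gr$nodes[which.min(gr$nodes$x_mm), c("x_mm", "y_mm", "z_mm")])
  mb <- main_branch(gr, o)
  prof <- diameter_profile(cone, mb, step_mm = 1.5)
  d <- prof$diameter_smoothed_mm
  expect_true(all(diff(d) < VS / 2)) # decreasing up to voxel noise
  # compare against the programmed taper at the sampled positions, away
  # from the tip cap (the last half-millimetre probes the rounded end)
  body <- prof$position_mm < mb$curved_mm - 0.5
  analytic <- 2 * (6 - prof$position_mm / (500 * VS) * 4) * VS
  expect_true(all(abs(prof$diameter_raw_mm - analytic)[body] <= 2.5 * VS))
})

test_that("diameter ratios per region follow the programmed radii", {
  big <- cylinder_grid(6, 400)
  small <- cylinder_grid(2, 400)
  # co-registered dims are irrelevant to the ratio; profiles are per system
  prof_of <- function(g) {
    gr <- graph_from_skeleton(skeletonize_mask(g))
    o <- unlist(gr$nodes[which.min(gr$nodes$x_mm), c("x_mm", "y_mm", "z_mm")])
    diameter_profile(g, main_branch(gr, o), step_mm = 1.5)
  }
  pb <- prof_of(big); ps <- prof_of(small)
  expect_equal(unname(bd_pv_diameter_ratio(pb, pb)["hilar"]), 1)
  ratio <- bd_pv_diameter_ratio(ps, pb)
  expect_equal(unname(ratio["hilar"]), 1 / 3, tolerance = 0.12)

  pn <- prof_of(big)
  attr(pn, "region_windows") <- region_windows_preset("narrow")
  expect_error(bd_pv_diameter_ratio(pn, pb), "different region windows")
})

test_that("tortuosity is stable under rigid rotation of the phantom", {
  # a helical tube covers tangent directions isotropically in azimuth; its
  # measured tortuosity should not depend on how the tube sits on the grid.
  # Voxel-centre chains carry a direction-dependent length bias of a few
  # percent, which bounds the attainable invariance (see the package
  # vignette); 5% is what the plain cumulative-distance estimator supports.
  s <- seq(0, 3, by = VS / 2)
  pts <- cbind(s, 0.08 * sin(2 * pi * s / 0.6), 0.08 * cos(2 * pi * s / 0.6))
  mk_truth <- function(p) {
    sh <- 0.05 + 4 * VS - apply(p, 2, min)
    p <- sweep(p, 2, sh, "+")
    structure(list(
      spec = phantom_spec(radius_root_mm = 0.05, seed = 1),
      segments = list(list(id = 1L, points = p, generation = 1L,
                           radius_mm = 0.05, parent = NA_integer_)),
      bbox_mm = rbind(lo = apply(p, 2, min), hi = apply(p, 2, max))),
      class = "phantom_truth")
  }
  tort_of_truth <- function(truth)
    tortuosity_of(graph_from_skeleton(skeletonize_mask(rasterize(truth))))
  t0 <- tort_of_truth(mk_truth(pts))
  ax <- c(1, 2, 3) / sqrt(14)
  for (ang in c(0.4, 1.1)) {
    rotated <- t(apply(pts, 1, ductr:::rodrigues, axis = ax, angle = ang))
    t1 <- tort_of_truth(mk_truth(rotated))
    expect_equal((t1 + 100) / (t0 + 100), 1, tolerance = 0.05,
                 info = paste("angle", ang))
  }
})
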