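# Shared fixture builders. Everything is generated in code at test time;
# voxel size defaults to 0.012 mm, the adult-scan resolution.

VS <- 0.012

# Rasterize a set of capsules given in voxel units directly (bypasses the
# phantom module for low-level geometry fixtures).
capsule_grid <- function(p0, p1, radii_vox, dims, voxel_size_mm = VS,
                         label = "") {
  occ <- ductr:::cpp_rasterize_capsules(
    as.matrix(p0), as.matrix(p1), radii_vox, as.integer(dims))
  voxel_grid(array(occ, dims), voxel_size_mm, label = label)
}

# Axis-aligned solid cylinder along x (capsule caps), radius and length in
# voxels.
cylinder_grid <- function(radius_vox = 4, length_vox = 60,
                          voxel_size_mm = VS) {
  pad <- radius_vox + 4
  dims <- c(length_vox + 2 * pad, 2 * pad + 1, 2 * pad + 1)
  c0 <- (dims[2]) / 2
  capsule_grid(matrix(c(pad, c0, c0), 1),
               matrix(c(pad + length_vox, c0, c0), 1),
               radius_vox, dims, voxel_size_mm)
}

# Y-shaped phantom: trunk along x then two arms at +-angle in the xy plane.
# Arm lengths in voxels.
y_grid <- function(trunk = 40, arm1 = 30, arm2 = 50, radius = 3,
                   angle_deg = 35, voxel_size_mm = VS) {
  a <- angle_deg * pi / 180
  pad <- radius + 5
  j <- c(pad + trunk, 0, 0)
  e1 <- j + arm1 * c(cos(a), sin(a), 0)
  e2 <- j + arm2 * c(cos(a), -sin(a), 0)
  ymax <- max(arm1, arm2) * sin(a) + pad
  off <- c(0, ymax, pad + 1)
  p0 <- rbind(c(pad, 0, 0), j, j)
  p1 <- rbind(j, e1, e2)
  p0 <- sweep(p0, 2, off, "+"); p1 <- sweep(p1, 2, off, "+")
  dims <- ceiling(apply(rbind(p0, p1), 2, max) + pad)
  capsule_grid(p0, p1, rep(radius, 3), dims, voxel_size_mm)
}

# Solid torus in the xy plane: centreline circle of radius R_vox, tube
# radius r_vox.
torus_grid <- function(R_vox = 20, r_vox = 4, voxel_size_mm = VS) {
  pad <- r_vox + 4
  cc <- R_vox + pad
  th <- seq(0, 2 * pi, length.out = 181)
  P <- cbind(cc + R_vox * cos(th), cc + R_vox * sin(th), pad + 1)
  dims <- c(2 * cc, 2 * cc, 2 * pad + 2)
  capsule_grid(P[-nrow(P), ], P[-1, ], rep(r_vox, nrow(P) - 1), dims,
               voxel_size_mm)
}

# Analytic semicircle chain (mm), radius r, fine sampling.
semicircle_chain <- function(r = 1, n = 2001) {
  th <- seq(0, pi, length.out = n)
  cbind(r * cos(th), r * sin(th), 0)
}

# O(n^2) nearest-neighbour oracle with the lexicographic tie-break.
bf_nearest <- function(query, ref) {
  idx <- integer(nrow(query)); dd <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(ref) - query[i, ])^2))
    best <- which(d < min(d) + 1e-12)
    if (length(best) > 1)
      best <- best[order(ref[best, 1], ref[best, 2], ref[best, 3])]
    idx[i] <- best[1]; dd[i] <- d[best[1]]
  }
  list(index = idx, distance = dd)
}

# Exhaustive region-border oracle: minimise |cs[T1]-S| + |cs[T2]-2S| over
# all admissible pairs, ties to the lexicographically earliest pair.
bf_region_borders <- function(l) {
  M <- length(l); S <- sum(l) / 3; cs <- cumsum(l)
  best <- NULL; bestval <- Inf
  for (T1 in 1:(M - 2)) for (T2 in (T1 + 1):(M - 1)) {
    val <- abs(cs[T1] - S) + abs(cs[T2] - 2 * S)
    if (val < bestval - 1e-12) { bestval <- val; best <- c(T1, T2) }
  }
  best
}

# Default tree spec used across topology-recovery tests: geometry chosen so
# that the rasterized tree is resolvable (radii >= 2 voxels, junctions
# farther apart than the 0.2 mm merge radius, bifurcation angle 35 degrees).
recovery_spec <- function(seed, n_generations = 4) {
  phantom_spec(n_generations = n_generations,
               length_per_generation = c(1.2, 0.8, 0.6, 0.45),
               bifurcation_angle_deg = 35,
               radius_root_mm = 0.05, radius_taper = 0.8,
               voxel_size_mm = VS, seed = seed)
}
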