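# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Voxel index convention: 1-based array indices (x, y, z); the physical
# position of a voxel is its centre, (index - 0.5) * voxel_size per axis.
vox_centers_mm <- function(idx, voxel_size_mm) {
  (idx - 0.5) * voxel_size_mm
}

# mm coordinates -> continuous voxel coordinates (0-based cell space, voxel
# centre at index + 0.5), as consumed by the C++ kernels.
mm_to_voxcoord <- function(points_mm, voxel_size_mm) {
  points_mm / voxel_size_mm
}

# mm point -> 1-based index of the containing voxel
mm_to_voxindex <- function(points_mm, voxel_size_mm) {
  idx <- floor(points_mm / voxel_size_mm) + 1L
  storage.mode(idx) <- "integer"
  idx
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 3) stop("points must have 3 columns (x, y, z)")
  x
}

# Erosion with the 6-neighbourhood ball (spherical structuring element of
# one-voxel radius). Voxels outside the grid count as background.
erode_ball1 <- function(occ) {
  d <- dim(occ)
  out <- occ
  shift_and <- function(out, occ, axis, by) {
    pad <- function(n) rep(FALSE, n)
    idx <- vector("list", 3)
    for (k in 1:3) idx[[k]] <- seq_len(d[k])
    src <- idx
    src[[axis]] <- idx[[axis]] + by
    keep <- src[[axis]] >= 1 & src[[axis]] <= d[axis]
    shifted <- array(FALSE, d)
    dst <- idx; dst[[axis]] <- idx[[axis]][keep]
    src[[axis]] <- src[[axis]][keep]
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
    out & shifted
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- shift_and(out, occ, axis, by)
  out
}

# Voxel indices (1-based, n x 3) of the mask boundary: foreground voxels that
# do not survive erosion by the one-voxel spherical element.
boundary_voxels <- function(grid) {
  occ <- grid$occupancy
  b <- occ & !erode_ball1(occ)
  which(b, arr.ind = TRUE)
}

# Arc-length positions of polyline vertices (mm), starting at 0.
arc_positions <- function(chain) {
  chain <- as_point_matrix(chain)
  if (nrow(chain) == 1) return(0)
  steps <- sqrt(rowSums((chain[-1, , drop = FALSE] -
                         chain[-nrow(chain), , drop = FALSE])^2))
  c(0, cumsum(steps))
}

# Linear interpolation of a polyline at given arc-length positions.
interpolate_chain <- function(chain, at) {
  chain <- as_point_matrix(chain)
  s <- arc_positions(chain)
  out <- matrix(NA_real_, length(at), 3)
  for (k in 1:3) out[, k] <- approx(s, chain[, k], xout = pmin(at, max(s)),
                                    rule = 2)$y
  out
}

# Run an expression with a deterministic RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Minimal union-find for transitive merging.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
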