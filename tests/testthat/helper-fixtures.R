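# Shared fixtures and independent brute-force oracles used across tests.

random_cloud <- function(n, seed, lo = -1, hi = 1, colors = FALSE) {
  withr::with_seed(seed, {
    pos <- matrix(runif(3 * n, lo, hi), ncol = 3)
    point_cloud(pos, colors = if (colors) matrix(runif(3 * n), ncol = 3))
  })
}

# points uniform on a sphere surface, optional cap removal and noise
sphere_cap_cloud <- function(n, center = c(0, 0, 0), r = 0.1, seed = 1,
                             coverage = 1, noise_sd = 0) {
  withr::with_seed(seed, {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    if (coverage < 1) u <- u[u[, 3] > 1 - 2 * coverage, , drop = FALSE]
    pos <- sweep(u * r, 2, center, "+")
    if (noise_sd > 0) pos <- pos + matrix(rnorm(length(pos), sd = noise_sd),
                                          ncol = 3)
    point_cloud(pos)
  })
}

# brute-force symmetric chamfer via a full distance matrix
brute_chamfer <- function(a, b) {
  d <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                           nrow(a) + seq_len(nrow(b)),
                                           drop = FALSE]
  mean(apply(d, 1, min)) + mean(apply(d, 2, min))
}

# all permutations of 1..n as rows (n small)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# exact strict-inside fraction for a CONVEX mesh b: a point is inside iff
# it lies strictly on the inner side of every face plane
convex_inside_fraction <- function(a, b) {
  v <- b$vertices
  f <- b$faces
  centroid <- colMeans(v)
  inside <- rep(TRUE, nrow(a$vertices))
  for (t in seq_len(nrow(f))) {
    p0 <- v[f[t, 1], ]
    n <- pracma::cross(v[f[t, 2], ] - p0, v[f[t, 3], ] - p0)
    if (sum(n * (centroid - p0)) > 0) n <- -n  # outward normal
    inside <- inside & (as.vector(a$vertices %*% n) < sum(n * p0))
  }
  mean(inside)
}

# brute-force per-voxel centroid downsampling
brute_voxel <- function(pos, res, lo = -1, hi = 1) {
  w <- (hi - lo) / res
  idx <- floor((pos - lo) / w)
  idx[idx >= res] <- res - 1
  key <- idx[, 1] + res * (idx[, 2] + res * idx[, 3])
  out <- lapply(sort(unique(key)), function(k) {
    colMeans(pos[key == k, , drop = FALSE])
  })
  do.call(rbind, out)
}
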