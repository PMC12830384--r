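#' k-means clustering of a point cloud
#'
#' Lloyd's algorithm with k-means++ seeding under an explicit seed.
#' Assignment and centroid updates alternate until the largest centroid
#' movement falls below `tol` or `max_iter` iterations elapse. A cluster
#' that empties during the iteration is re-seeded at the point farthest
#' from its nearest centroid. Choose `k` larger than the expected number of
#' components (1.5-2x is a good default); over-provisioning prevents one
#' cluster from spanning several components and is corrected later by
#' merging.
#'
#' @param cloud a [point_cloud()] with at least `k` points.
#' @param k number of clusters.
#' @param seed integer seed for the k-means++ initialization.
#' @param max_iter,tol iteration cap and convergence tolerance on centroid
#'   movement.
#' @return a `cluster_set`: list with `labels` (1-based, length
#'   `n_points(cloud)`), `k`, `centers`, and the `cloud`.
#' @export
kmeans_cluster <- function(cloud, k, seed = 1, max_iter = 300, tol = 1e-6) {
  x <- cloud$positions
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1) stop("'k' must be >= 1")
  if (k > n) stop(sprintf("'k' (%d) exceeds the point count (%d)", k, n))
  centers <- with_seed(seed, kmeanspp_init(x, k))
  xs <- rowSums(x^2)
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sqdist_to_centers(x, xs, centers)
    labels <- max.col(-d2, ties.method = "first")
    counts <- tabulate(labels, nbins = k)
    if (any(counts == 0)) {
      # re-seed empty clusters at the point farthest from its centroid
      for (j in which(counts == 0)) {
        far <- which.max(apply(d2, 1, min))
        centers[j, ] <- x[far, ]
        d2 <- sqdist_to_centers(x, xs, centers)
        labels <- max.col(-d2, ties.method = "first")
      }
      counts <- tabulate(labels, nbins = k)
    }
    new_centers <- rowsum(x, factor(labels, levels = seq_len(k))) / counts
    move <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (move < tol) break
  }
  structure(list(labels = labels, k = k, centers = centers, cloud = cloud),
            class = "cluster_set")
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, 3)
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) <= 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = p)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

sqdist_to_centers <- function(x, xs, centers) {
  cs <- rowSums(centers^2)
  d2 <- outer(xs, cs, "+") - 2 * (x %*% t(centers))
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters over %d points>\n", x$k,
              length(x$labels)))
  invisible(x)
}

#' Extract one cluster as a point cloud
#'
#' @param clusters a `cluster_set`.
#' @param index cluster index in `1..k`.
#' @return the sub-cloud with that label (point order preserved); an empty
#'   cluster yields a zero-row cloud that fitting skips.
#' @export
extract_cluster <- function(clusters, index) {
  if (index < 1 || index > clusters$k) stop("cluster index out of range")
  keep <- clusters$labels == index
  cloud <- clusters$cloud
  structure(list(positions = cloud$positions[keep, , drop = FALSE],
                 colors = if (is.null(cloud$colors)) NULL else
                   cloud$colors[keep, , drop = FALSE]),
            class = "point_cloud")
}

#' Within-cluster sum of squares of a cluster set
#' @param clusters a `cluster_set`.
#' @return total within-cluster sum of squared distances to centroids.
#' @export
cluster_wss <- function(clusters) {
  x <- clusters$cloud$positions
  sum((x - clusters$centers[clusters$labels, , drop = FALSE])^2)
}
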