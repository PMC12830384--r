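test_that("sphere overlap uses the strict alpha rule", {
  a <- sphere_model(c(0, 0, 0), 0.5)
  b89 <- sphere_model(c(0.89, 0, 0), 0.5)
  b90 <- sphere_model(c(0.90, 0, 0), 0.5)
  expect_true(spheres_overlap(a, b89, 0.9))    # 0.89 < 0.9 * 1.0
  expect_false(spheres_overlap(a, b90, 0.9))   # boundary excluded
  expect_true(spheres_overlap(a, sphere_model(c(0, 0, 0), 0.2)))
})

# small two-sphere world: each true sphere is split into two half clusters
split_world <- function(seed = 1) {
  c1 <- c(-0.11, 0, 0)
  c2 <- c(0.11, 0, 0)
  mk <- function(center, side, seed) {
    cl <- sphere_cap_cloud(900, center = center, r = 0.11, seed = seed)
    keep <- if (side > 0) cl$positions[, 3] >= center[3] else
      cl$positions[, 3] < center[3]
    cl$positions[keep, , drop = FALSE]
  }
  pos <- rbind(mk(c1, 1, seed), mk(c1, -1, seed + 1),
               mk(c2, 1, seed + 2), mk(c2, -1, seed + 3))
  labels <- rep(1:4, times = c(
    nrow(mk(c1, 1, seed)), nrow(mk(c1, -1, seed + 1)),
    nrow(mk(c2, 1, seed + 2)), nrow(mk(c2, -1, seed + 3))))
  cloud <- point_cloud(pos)
  clusters <- structure(list(labels = labels, k = 4L,
                             centers = rowsum(pos, labels) / tabulate(labels),
                             cloud = cloud),
                        class = "cluster_set")
  list(clusters = clusters, truth = rbind(c1, c2))
}

test_that("non-overlapping fits leave the cluster set unchanged", {
  w <- split_world()
  cfg <- ransac_config(initial_radius = 0.11)
  # synthetic far-apart fits: no overlap edges
  fits <- list(
    structure(list(sphere = sphere_model(c(-5, 0, 0), 0.1),
                   rotation = diag(3), chamfer = 0.01, inlier_ratio = 1,
                   valid = TRUE, iterations = 1), class = "fit_result"),
    structure(list(sphere = sphere_model(c(5, 0, 0), 0.1),
                   rotation = diag(3), chamfer = 0.01, inlier_ratio = 1,
                   valid = TRUE, iterations = 1), class = "fit_result"),
    NULL, NULL)
  step <- merge_step(w$clusters, fits, cfg, seed = 3)
  expect_false(step$changed)
  expect_identical(step$clusters$labels, w$clusters$labels)
})

test_that("an over-split component merges into one cluster with one fit", {
  w <- split_world(seed = 11)
  cfg <- ransac_config(initial_radius = 0.11)
  fits <- fit_all_clusters(w$clusters, cfg, seed = 5)
  expect_true(sum(vapply(fits, function(f) !is.null(f) && f$valid, TRUE)) >= 2)
  out <- merge_to_fixpoint(w$clusters, fits, cfg, seed = 6)
  expect_lte(out$clusters$k, 3)
  valid <- which(vapply(out$fits, function(f) !is.null(f) && f$valid, TRUE))
  expect_gte(length(valid), 2 - 1)
  # point conservation through all rounds
  expect_equal(length(out$clusters$labels), length(w$clusters$labels))
  expect_equal(sum(tabulate(out$clusters$labels, out$clusters$k)),
               length(w$clusters$labels))
})

test_that("three mutually overlapping fits re-cluster at k = m - 1", {
  # one true sphere split into 3 clusters by octant slicing
  cl <- sphere_cap_cloud(1500, r = 0.12, seed = 21)
  ang <- atan2(cl$positions[, 2], cl$positions[, 1])
  labels <- cut(ang, breaks = c(-pi, -pi / 3, pi / 3, pi),
                labels = FALSE)
  clusters <- structure(list(labels = labels, k = 3L,
                             centers = rowsum(cl$positions, labels) /
                               tabulate(labels),
                             cloud = cl),
                        class = "cluster_set")
  cfg <- ransac_config(initial_radius = 0.12)
  near <- sphere_model(c(0.005, 0, 0), 0.115)
  fits <- lapply(1:3, function(i) {
    structure(list(sphere = near, rotation = diag(3), chamfer = 0.01,
                   inlier_ratio = 1, valid = TRUE, iterations = 1),
              class = "fit_result")
  })
  step <- merge_step(clusters, fits, cfg, seed = 22)
  expect_true(step$changed)
  expect_equal(step$clusters$k, 2)  # pooled and re-clustered at m - 1
})

test_that("merging strictly decreases cluster count and terminates within k rounds", {
  w <- split_world(seed = 31)
  cfg <- ransac_config(initial_radius = 0.11)
  fits <- fit_all_clusters(w$clusters, cfg, seed = 7)
  out <- merge_to_fixpoint(w$clusters, fits, cfg, seed = 8)
  expect_lte(out$rounds, w$clusters$k)
  if (length(out$history) > 1) {
    changed_rounds <- diff(c(w$clusters$k, out$history))
    expect_true(all(changed_rounds <= 0))
  }
})
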