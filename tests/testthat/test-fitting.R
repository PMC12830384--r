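test_that("point-to-sphere distance follows | r - ||p - c|| |", {
  s <- sphere_model(c(0, 0, 0), 1)
  expect_equal(point_to_sphere_distance(c(0, 0, 2), s), 1.0)
  expect_equal(point_to_sphere_distance(c(1, 0, 0), s), 0.0)
  expect_equal(point_to_sphere_distance(c(0.3, 0.4, 0),
                                        sphere_model(c(0, 0, 0), 0.4)), 0.1)
})

test_that("chamfer distance is the sum of two mean nearest-neighbor terms", {
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(1, 0, 0), 1)
  expect_equal(chamfer_distance(a, b), 2.0)  # 1 + 1, no 1/2 factor
  v <- icosphere(2)$vertices
  expect_equal(chamfer_distance(v, v), 0.0)
  expect_error(chamfer_distance(matrix(0, 0, 3), b), "non-empty")
})

test_that("chamfer matches the brute-force double loop on random instances", {
  for (i in 1:20) {
    a <- random_cloud(sample(5:50, 1), seed = 100 + i)$positions
    b <- random_cloud(sample(5:50, 1), seed = 200 + i)$positions
    expect_equal(chamfer_distance(a, b), brute_chamfer(a, b),
                 tolerance = 1e-10)
    expect_equal(chamfer_distance(a, b), chamfer_distance(b, a))
  }
})

test_that("the refinement candidate set has exactly 7 x 5 members", {
  cand <- refinement_candidates(sphere_model(c(0.1, 0.2, 0.3), 0.1))
  expect_equal(nrow(cand), 35)
  # 7 distinct translations x 5 distinct scales
  expect_equal(nrow(unique(cand[, c("dx", "dy", "dz")])), 7)
  expect_equal(sort(unique(cand$scale)), c(0.8, 0.9, 1.0, 1.1, 1.2))
  # identity candidate present
  expect_true(any(cand$dx == 0 & cand$dy == 0 & cand$dz == 0 &
                    cand$scale == 1))
  # translations are single-axis steps of the configured width
  steps <- unique(abs(c(cand$dx, cand$dy, cand$dz)))
  expect_equal(sort(steps), c(0, 0.01))
})

test_that("refinement terminates immediately on an already-optimal sphere", {
  cl <- sphere_cap_cloud(400, r = 0.1, seed = 31)
  cfg <- ransac_config(initial_radius = 0.1)
  ref <- refine_locally(cl, sphere_model(c(0, 0, 0), 0.1), cfg = cfg)
  expect_equal(ref$iterations, 1)
  # at the tessellation floor: nothing moved
  expect_equal(ref$sphere$center, c(0, 0, 0))
  expect_equal(ref$sphere$radius, 0.1)
})

test_that("refinement recovers a translated center and a scaled radius", {
  cl <- sphere_cap_cloud(500, center = c(0.03, 0, 0), r = 0.1, seed = 32)
  cfg <- ransac_config(initial_radius = 0.1)
  ref <- refine_locally(cl, sphere_model(c(0, 0, 0), 0.1), cfg = cfg)
  expect_lt(max(abs(ref$sphere$center - c(0.03, 0, 0))),
            cfg$translation_step + 1e-12)

  cl2 <- sphere_cap_cloud(500, r = 0.12, seed = 33)
  ref2 <- refine_locally(cl2, sphere_model(c(0, 0, 0), 0.1), cfg = cfg)
  # reachable radii form a multiplicative grid over the scale factors
  expect_lt(abs(ref2$sphere$radius - 0.12), 0.12 * 0.21)
})

test_that("refinement chamfer traces never increase", {
  cfg <- ransac_config(initial_radius = 0.08)
  for (i in 1:50) {
    cl <- sphere_cap_cloud(120, center = runif(3, -0.2, 0.2),
                           r = runif(1, 0.07, 0.14), seed = 500 + i,
                           coverage = runif(1, 0.4, 1))
    init <- sphere_model(colMeans(cl$positions) + runif(3, -0.02, 0.02),
                         0.08)
    ref <- refine_locally(cl, init, cfg = cfg)
    expect_true(all(diff(ref$trace) <= 1e-12))
  }
})

test_that("hypothesis validity follows the strict inlier conventions", {
  cfg <- ransac_config(initial_radius = 0.1)
  # clean full sphere: valid with all points inliers
  cl <- sphere_cap_cloud(300, r = 0.1, seed = 41)
  hyp <- generate_hypothesis(cl, cfg, seed = 42)
  expect_true(hyp$valid)
  expect_equal(hyp$inlier_ratio, 1.0)
  expect_gt(hyp$inlier_ratio, 0.5)

  # uniform box points: far too diffuse for a small sphere
  box <- random_cloud(400, seed = 43)
  hyp2 <- generate_hypothesis(box, cfg, seed = 44)
  expect_false(hyp2$valid)
  expect_lt(hyp2$inlier_ratio, 0.5)

  # a point at distance exactly epsilon is NOT an inlier (strict <)
  s <- sphere_model(c(0, 0, 0), 0.1)
  d <- point_to_sphere_distance(c(0.1 + cfg$epsilon, 0, 0), s)
  expect_equal(d, cfg$epsilon)
  expect_false(d < cfg$epsilon)
})

test_that("inlier counts are monotone non-decreasing in epsilon", {
  cl <- sphere_cap_cloud(400, r = 0.1, seed = 51, noise_sd = 0.01)
  s <- sphere_model(c(0, 0, 0), 0.1)
  d <- point_to_sphere_distance(cl, s)
  eps <- c(0.0075, 0.015, 0.03)
  counts <- vapply(eps, function(e) sum(d < e), 1L)
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[2])  # halving epsilon loses inliers here
})

test_that("fit_component recovers clean spheres and rejects noise clusters", {
  truth_c <- c(0.05, -0.02, 0.08)
  cl <- sphere_cap_cloud(600, center = truth_c, r = 0.11, seed = 61,
                         coverage = 0.85, noise_sd = 0.003)
  cfg <- ransac_config(initial_radius = 0.1)
  fit <- fit_component(cl, cfg, seed = 62)
  expect_false(is.null(fit))
  expect_lt(sqrt(sum((fit$sphere$center - truth_c)^2)), 0.02)
  expect_lt(abs(fit$sphere$radius - 0.11), 0.11 * 0.15)

  # 60% sphere + 40% scattered points is still valid
  mix <- point_cloud(rbind(
    sphere_cap_cloud(300, center = truth_c, r = 0.11, seed = 63)$positions,
    random_cloud(200, seed = 64)$positions))
  fitm <- fit_component(mix, cfg, seed = 65)
  expect_false(is.null(fitm))
  expect_gt(fitm$inlier_ratio, 0.5)

  # too-small cluster: no-fit signal
  tiny <- random_cloud(5, seed = 66)
  expect_null(fit_component(tiny, cfg, seed = 67))
})

test_that("sphere recovery succeeds across seeds with offset initial radii", {
  # noiseless fully-visible spheres, initial radius within [0.7r, 1.3r]:
  # center recovered within 2 translation steps and radius within one
  # scale step for at least 95% of seeds
  n_seed <- 20L
  ok <- 0L
  results <- withr::with_seed(99, {
    mult <- runif(n_seed, 0.7, 1.3)
    ctr <- matrix(runif(3 * n_seed, -0.1, 0.1), ncol = 3)
    list(mult = mult, ctr = ctr)
  })
  cfg_base <- ransac_config(initial_radius = 0.1)
  for (i in seq_len(n_seed)) {
    r_true <- 0.11
    cfg <- ransac_config(initial_radius = results$mult[i] * r_true)
    cl <- sphere_cap_cloud(500, center = results$ctr[i, ], r = r_true,
                           seed = 700 + i)
    fit <- fit_component(cl, cfg, seed = 800 + i)
    if (!is.null(fit) &&
        sqrt(sum((fit$sphere$center - results$ctr[i, ])^2)) <=
          2 * cfg$translation_step &&
        abs(fit$sphere$radius - r_true) <= r_true * 0.21) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_seed, 0.95)
})
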