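test_that("packing honors component count, determinism, and spacing", {
  agg <- generate_packing(1, seed = 5)
  expect_length(agg$components, 1)

  a1 <- generate_packing(12, seed = 42)
  a2 <- generate_packing(12, seed = 42)
  expect_identical(a1, a2)

  # exhaustive pairwise non-interpenetration check
  agg <- generate_packing(20, radius_range = c(0.08, 0.12), seed = 7)
  cmp <- agg$components
  for (i in seq_along(cmp)) {
    for (j in seq_len(i - 1)) {
      d <- sqrt(sum((cmp[[i]]$center - cmp[[j]]$center)^2))
      expect_gte(d, 0.95 * (mean(cmp[[i]]$radii) + mean(cmp[[j]]$radii)))
    }
  }
})

test_that("noise-free samples of a single sphere lie exactly on its surface", {
  agg <- generate_packing(1, radius_range = c(0.1, 0.1), seed = 3,
                          noise_sd = 0, occlusion_fraction = 0)
  s <- sample_surface(agg, seed = 9)
  sph <- sphere_model(agg$components[[1]]$center,
                      mean(agg$components[[1]]$radii))
  expect_lt(max(point_to_sphere_distance(s$cloud, sph)), 1e-9)
})

test_that("noise-free multi-sphere samples touch some true component surface", {
  agg <- generate_packing(8, seed = 13, noise_sd = 0,
                          occlusion_fraction = 0.1)
  s <- sample_surface(agg, seed = 14)
  dmin <- rep(Inf, n_points(s$cloud))
  for (cmp in agg$components) {
    sph <- sphere_model(cmp$center, mean(cmp$radii))
    dmin <- pmin(dmin, point_to_sphere_distance(s$cloud, sph))
  }
  expect_lt(max(dmin), 1e-9)
})

test_that("cap occlusion removes close to the requested surface fraction", {
  agg <- generate_packing(1, radius_range = c(0.12, 0.12), seed = 21,
                          noise_sd = 0, occlusion_fraction = 0.3,
                          density_per_component = 30000)
  s <- sample_surface(agg, seed = 22)
  # retention is binomial around 70%
  expect_equal(s$retention[1], 0.7, tolerance = 0.03)
})

test_that("surface sampling is deterministic and point count tracks area", {
  agg <- generate_packing(5, seed = 31)
  s1 <- sample_surface(agg, seed = 8)
  s2 <- sample_surface(agg, seed = 8)
  expect_identical(s1$cloud$positions, s2$cloud$positions)
  expect_length(agg$components, 5)

  small <- generate_packing(1, radius_range = c(0.05, 0.05), seed = 2,
                            occlusion_fraction = 0, noise_sd = 0)
  big <- generate_packing(1, radius_range = c(0.1, 0.1), seed = 2,
                          occlusion_fraction = 0, noise_sd = 0)
  ns <- n_points(sample_surface(small, seed = 3)$cloud)
  nb <- n_points(sample_surface(big, seed = 3)$cloud)
  expect_equal(nb / ns, 4, tolerance = 0.1)  # area scales with r^2
})

test_that("ellipsoid and deformed shapes stay within their radial envelopes", {
  ell <- generate_packing(3, shape = "ellipsoid", seed = 5, noise_sd = 0,
                          occlusion_fraction = 0)
  expect_true(all(vapply(ell$components, function(cmp) {
    cmp$radii[3] / cmp$radii[1] >= 1.2 && cmp$radii[3] / cmp$radii[1] <= 1.4
  }, TRUE)))

  def <- generate_packing(1, shape = "deformed", radius_range = c(0.1, 0.1),
                          seed = 6, noise_sd = 0, occlusion_fraction = 0)
  s <- sample_surface(def, seed = 7)
  r <- sqrt(rowSums(sweep(s$cloud$positions, 2,
                          def$components[[1]]$center)^2))
  expect_true(all(r >= 0.1 * 0.9 - 1e-9 & r <= 0.1 * 1.1 + 1e-9))
  expect_gt(max(abs(r - 0.1)), 1e-4)  # the bump field actually deforms
})

test_that("ground truth JSON round-trips", {
  agg <- generate_packing(4, shape = "deformed", seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(agg, path)
  back <- read_ground_truth(path)
  expect_equal(length(back$components), 4)
  for (i in 1:4) {
    expect_equal(back$components[[i]]$center, agg$components[[i]]$center)
    expect_equal(back$components[[i]]$radii, agg$components[[i]]$radii)
    expect_equal(back$components[[i]]$rotation, agg$components[[i]]$rotation)
  }
  expect_equal(back$occlusion_fraction, agg$occlusion_fraction)
})
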