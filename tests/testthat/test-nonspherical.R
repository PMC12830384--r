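test_that("vertex inlier fraction spans its boundary cases", {
  ico <- icosphere(2)
  placed <- transform_mesh(ico, scales = 0.1)
  dense <- sphere_cap_cloud(5000, r = 0.1, seed = 3)
  expect_equal(vertex_inlier_fraction(placed, dense, 0.015), 1.0)

  far <- transform_mesh(ico, center = c(5, 5, 5), scales = 0.1)
  expect_equal(vertex_inlier_fraction(far, dense, 0.015), 0.0)

  # half-occluded cluster covers ~half the template vertices
  hemi <- sphere_cap_cloud(5000, r = 0.1, seed = 4, coverage = 0.5)
  frac <- vertex_inlier_fraction(placed, hemi, 0.015)
  expect_equal(frac, 0.5, tolerance = 0.12)
})

test_that("vertex inlier fraction is monotone in the threshold", {
  placed <- transform_mesh(icosphere(2), scales = 0.1)
  cl <- sphere_cap_cloud(200, r = 0.11, seed = 5, noise_sd = 0.01)
  ths <- c(0.005, 0.01, 0.02, 0.05, 0.2)
  fr <- vapply(ths, function(t) vertex_inlier_fraction(placed, cl, t), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("the rotation variant set is the identity plus +/-10 degrees per axis", {
  rots <- rotated_hypotheses()
  expect_length(rots, 7)
  expect_equal(rots[[1]], diag(3))
  for (R in rots[-1]) {
    # proper rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    # rotation angle is exactly 10 degrees
    angle <- acos((sum(diag(R)) - 1) / 2) * 180 / pi
    expect_equal(angle, 10, tolerance = 1e-9)
  }
  # all seven are distinct
  expect_equal(length(unique(lapply(rots, function(R) round(R, 9)))), 7)
})

test_that("inside_fraction handles containment, coincidence, and hemispheres", {
  ico <- icosphere(2)
  big <- transform_mesh(ico, scales = 1)
  tiny <- transform_mesh(ico, scales = 0.1)
  expect_equal(inside_fraction(tiny, big), 1.0)
  expect_equal(inside_fraction(big, tiny), 0.0)

  # coincident meshes: vertices are on the surface, not strictly inside
  expect_equal(inside_fraction(big, big), 0.0)

  # unit sphere centered on the other's surface: the contained cap has
  # half-angle acos(d / 2r) = 60 degrees, i.e. (1 - cos 60) / 2 = 25% of
  # the surface
  half <- transform_mesh(ico, center = c(1, 0, 0))
  expect_equal(inside_fraction(half, big), 0.25, tolerance = 0.05)

  open_mesh <- component_mesh(ico$vertices, ico$faces[-1, ])
  expect_error(inside_fraction(big, open_mesh), "watertight")
})

test_that("inside_fraction agrees with analytic sphere containment", {
  ico <- icosphere(2)
  for (i in 1:100) {
    prm <- withr::with_seed(3000 + i, list(
      c1 = runif(3, -0.3, 0.3), r1 = runif(1, 0.05, 0.2),
      c2 = runif(3, -0.3, 0.3), r2 = runif(1, 0.05, 0.2)))
    a <- transform_mesh(ico, prm$c1, prm$r1)
    b <- transform_mesh(ico, prm$c2, prm$r2)
    got <- inside_fraction(a, b)
    # independent oracle: the placed icosphere is convex, so strict
    # containment is an exact half-space test against every face plane
    expect_equal(got, convex_inside_fraction(a, b), tolerance = 1e-9)
  }
})

test_that("the inside-outside merge test applies the n% threshold symmetrically", {
  ico <- icosphere(2)
  a <- transform_mesh(ico, c(0, 0, 0), 0.1)
  b <- transform_mesh(ico, c(1, 0, 0), 0.1)
  expect_false(nonspherical_merge_test(a, b, nonspherical_config()))

  # overlap tuned so a small but nonzero share of vertices is inside
  c1 <- transform_mesh(ico, c(0, 0, 0), 0.1)
  c2 <- transform_mesh(ico, c(0.19, 0, 0), 0.1)
  fr <- max(inside_fraction(c1, c2), inside_fraction(c2, c1))
  expect_gt(fr, 0.02)
  expect_lt(fr, 0.10)
  expect_true(nonspherical_merge_test(c1, c2,
                                      nonspherical_config(merge_inside_percent = 2)))
  expect_false(nonspherical_merge_test(c1, c2,
                                       nonspherical_config(merge_inside_percent = 10)))
  expect_equal(nonspherical_merge_test(c1, c2, nonspherical_config()),
               nonspherical_merge_test(c2, c1, nonspherical_config()))
})
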