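test_that("PLY and XYZ round-trips preserve positions and colors", {
  cl <- random_cloud(100, seed = 11, colors = TRUE)
  for (fmt in c("ply", "xyz")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_pointcloud(cl, path, fmt)
    back <- read_pointcloud(path, fmt)
    expect_equal(back$positions, cl$positions, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(back$colors, cl$colors, tolerance = 1e-2,
                 ignore_attr = TRUE)
  }
})

test_that("XYZ text without colors parses; malformed rows are rejected", {
  path <- withr::local_tempfile(lines = c("0 0 0", "1 1 1"))
  cl <- read_pointcloud(path, "xyz")
  expect_equal(n_points(cl), 2)
  expect_null(cl$colors)
  bad <- withr::local_tempfile(lines = c("0 0 0", "1 one 1"))
  expect_error(read_pointcloud(bad, "xyz"), "line 2")
  expect_error(read_pointcloud("no/such/file.xyz"), "no such file")
})

test_that("ascii PLY without color reads back plain positions", {
  path <- withr::local_tempfile(lines = c(
    "ply", "format ascii 1.0", "element vertex 3",
    "property float x", "property float y", "property float z",
    "end_header", "0 0 0", "0.5 0.25 1", "-1 2 3"))
  cl <- read_pointcloud(path, "ply")
  expect_equal(n_points(cl), 3)
  expect_null(cl$colors)
  expect_equal(cl$positions[2, ], c(0.5, 0.25, 1), ignore_attr = TRUE)
})

test_that("binary little-endian PLY with uchar colors reads correctly", {
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 2",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  for (row in list(list(c(0.1, 0.2, 0.3), c(255L, 0L, 128L)),
                   list(c(-1, 0.5, 2), c(0L, 255L, 64L)))) {
    writeBin(row[[1]], con, size = 4, endian = "little")
    writeBin(as.raw(row[[2]]), con)
  }
  close(con)
  cl <- read_pointcloud(path, "ply")
  expect_equal(cl$positions[1, ], c(0.1, 0.2, 0.3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(cl$colors[2, ], c(0, 255, 64) / 255, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("normalization centers the box and scales the largest axis to [-1,1]", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(2, 2, 2)))
  norm <- normalize_pointcloud(cl)
  expect_equal(norm$cloud$positions, rbind(c(-1, -1, -1), c(1, 1, 1)),
               ignore_attr = TRUE)

  # already-normalized input is unchanged
  cl2 <- point_cloud(rbind(c(-1, -1, -1), c(1, 1, 1), c(0.3, -0.2, 0.8)))
  norm2 <- normalize_pointcloud(cl2)
  expect_equal(norm2$cloud$positions, cl2$positions, tolerance = 1e-12)

  # aspect ratio preserved by the single uniform scale
  cl3 <- point_cloud(rbind(c(0, 0, 0), c(4, 2, 2)))
  norm3 <- normalize_pointcloud(cl3)
  expect_equal(range(norm3$cloud$positions[, 1]), c(-1, 1))
  expect_equal(range(norm3$cloud$positions[, 2]), c(-0.5, 0.5))
  expect_equal(range(norm3$cloud$positions[, 3]), c(-0.5, 0.5))

  expect_error(normalize_pointcloud(point_cloud(rbind(c(1, 1, 1), c(1, 1, 1)))),
               "degenerate")
})

test_that("normalization transform record inverts exactly", {
  cl <- random_cloud(50, seed = 4, lo = 3, hi = 9)
  norm <- normalize_pointcloud(cl)
  expect_true(all(abs(norm$cloud$positions) <= 1 + 1e-12))
  back <- invert_transform_points(norm$cloud$positions, norm$transform)
  expect_equal(back, cl$positions, tolerance = 1e-12)
  fwd <- apply_transform_points(cl$positions, norm$transform)
  expect_equal(fwd, norm$cloud$positions, tolerance = 1e-12)
})

test_that("voxel downsampling matches the brute-force per-voxel centroid", {
  cl <- random_cloud(1000, seed = 21)
  down <- voxel_downsample(cl, voxel_grid(200))
  oracle <- brute_voxel(cl$positions, 200)
  expect_equal(down$positions[order(down$positions[, 1]), ],
               oracle[order(oracle[, 1]), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lte(n_points(down), n_points(cl))
})

test_that("voxel downsampling collapses co-voxel points and is idempotent", {
  tight <- point_cloud(matrix(runif(30, 0.1005, 0.1009), ncol = 3))
  down <- voxel_downsample(tight, voxel_grid(200))
  expect_equal(n_points(down), 1)
  expect_equal(down$positions[1, ], colMeans(tight$positions),
               ignore_attr = TRUE)

  two <- point_cloud(rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))
  expect_equal(voxel_downsample(two, voxel_grid(200))$positions,
               two$positions, ignore_attr = TRUE)

  cl <- random_cloud(500, seed = 22)
  once <- voxel_downsample(cl, voxel_grid(50))
  twice <- voxel_downsample(once, voxel_grid(50))
  expect_equal(twice$positions, once$positions, tolerance = 1e-12)

  outside <- point_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(voxel_downsample(outside, voxel_grid(200)), "bounds")
})

test_that("filtering matches per-point brute-force evaluation and is idempotent", {
  cl <- random_cloud(100, seed = 31, colors = TRUE)
  pred <- hsv_range_predicate(v = c(0.25, 0.9))
  box <- list(lower = c(-0.5, -1, -1), upper = c(1, 1, 0.6))
  got <- filter_cloud(cl, pred, box)
  keep <- vapply(seq_len(100), function(i) {
    hsv <- grDevices::rgb2hsv(matrix(cl$colors[i, ], 3), maxColorValue = 1)
    p <- cl$positions[i, ]
    hsv[3] >= 0.25 && hsv[3] <= 0.9 && all(p >= box$lower) && all(p <= box$upper)
  }, TRUE)
  expect_equal(got$positions, cl$positions[keep, , drop = FALSE])
  again <- filter_cloud(got, pred, box)
  expect_equal(again$positions, got$positions)

  expect_equal(filter_cloud(cl)$positions, cl$positions)
  empty <- filter_cloud(cl, crop_box = list(lower = rep(5, 3),
                                            upper = rep(6, 3)))
  expect_equal(n_points(empty), 0)
  nocol <- random_cloud(10, seed = 1)
  expect_error(filter_cloud(nocol, pred), "no colors")
})

test_that("component meshes survive write/read round-trips with transforms", {
  template <- icosphere(1)
  comps <- lapply(1:3, function(i) {
    list(center = c(i, -i / 2, 0.3 * i), axis_scales = c(0.1, 0.12, 0.15),
         rotation = diag(3))
  })
  path <- withr::local_tempfile(fileext = ".obj")
  write_component_meshes(comps, template, path, "obj")
  back <- read_mesh(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expected <- transform_mesh(template, comps[[i]]$center,
                               comps[[i]]$axis_scales)
    expect_equal(back[[i]]$vertices, expected$vertices, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("PLY mesh export concatenates components and reads back", {
  template <- icosphere(1)
  comps <- lapply(1:2, function(i) {
    list(center = c(i, 0, 0), axis_scales = 0.2, rotation = diag(3))
  })
  path <- withr::local_tempfile(fileext = ".ply")
  write_component_meshes(comps, template, path, "ply")
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 2 * nrow(template$vertices))
  expect_equal(nrow(back$faces), 2 * nrow(template$faces))
  expected <- transform_mesh(template, c(1, 0, 0), 0.2)
  expect_equal(back$vertices[seq_len(nrow(template$vertices)), ],
               expected$vertices, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("identity and pure-translation mesh placement behave exactly", {
  template <- icosphere(1)
  ident <- transform_mesh(template)
  expect_equal(ident$vertices, template$vertices)
  shifted <- transform_mesh(template, center = c(1, 2, 3))
  expect_equal(shifted$vertices,
               sweep(template$vertices, 2, c(1, 2, 3), "+"))
})

test_that("icosphere template is unit-norm and watertight", {
  ico <- icosphere(2)
  expect_equal(nrow(ico$vertices), 162)
  expect_equal(nrow(ico$faces), 320)
  expect_true(all(abs(sqrt(rowSums(ico$vertices^2)) - 1) < 1e-9))
  expect_true(isTRUE(is_watertight(ico)))
})
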