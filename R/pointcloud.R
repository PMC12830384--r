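#' Construct a point cloud
#'
#' A point cloud holds the 3D surface samples of an aggregate, with optional
#' per-point RGB colors in `[0, 1]`.
#'
#' @param positions n x 3 numeric matrix of coordinates.
#' @param colors optional n x 3 numeric matrix of RGB values in `[0, 1]`.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(positions, colors = NULL) {
  positions <- as_xyz_matrix(positions, "positions")
  if (nrow(positions) < 1) stop("point cloud must contain at least one point")
  if (!all(is.finite(positions))) stop("point cloud coordinates must be finite")
  if (!is.null(colors)) {
    colors <- as_xyz_matrix(colors, "colors")
    if (nrow(colors) != nrow(positions)) {
      stop("'colors' must have one row per point")
    }
    if (any(colors < 0 | colors > 1)) stop("colors must lie in [0, 1]")
  }
  structure(list(positions = positions, colors = colors),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s>\n", nrow(x$positions),
              if (is.null(x$colors)) "" else ", colored"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$positions)

#' Read a point cloud from PLY or XYZ text
#'
#' PLY files may be ascii or binary little-endian; vertex properties
#' `x`, `y`, `z` are required and `red`, `green`, `blue` (uchar or float)
#' are picked up as colors when present. XYZ files are whitespace-separated
#' `x y z [r g b]` rows; color columns are auto-scaled from 0-255 when any
#' value exceeds 1.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"xyz"`. `"auto"` decides from the
#'   file extension.
#' @return a [point_cloud()].
#' @export
read_pointcloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  }
  if (format == "ply") {
    ply <- read_ply(path)
    point_cloud(ply$vertices, ply$colors)
  } else {
    read_xyz(path)
  }
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("'%s' contains no points", path))
  parsed <- lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(vals) || !(length(vals) %in% c(3L, 6L))) {
      stop(sprintf("malformed XYZ record at line %d of '%s'", i, path))
    }
    vals
  })
  ncols <- unique(lengths(parsed))
  if (length(ncols) != 1) {
    stop(sprintf("inconsistent column counts in '%s'", path))
  }
  mat <- do.call(rbind, parsed)
  colors <- NULL
  if (ncols == 6L) {
    colors <- mat[, 4:6, drop = FALSE]
    if (any(colors > 1)) colors <- colors / 255
  }
  point_cloud(mat[, 1:3, drop = FALSE], colors)
}

#' Write a point cloud
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"ply"` (ascii) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(cloud, path, format = c("ply", "xyz")) {
  format <- match.arg(format)
  pos <- cloud$positions
  if (format == "xyz") {
    m <- pos
    if (!is.null(cloud$colors)) m <- cbind(m, cloud$colors)
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  } else {
    write_ply(path, vertices = pos, colors = cloud$colors)
  }
  invisible(path)
}

# ---- PLY reader/writer -----------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin <- function(bytes, type, n) {
  switch(type,
    char = , int8 = readBin(bytes, "integer", n, size = 1, signed = TRUE),
    uchar = , uint8 = readBin(bytes, "integer", n, size = 1, signed = FALSE),
    short = , int16 = readBin(bytes, "integer", n, size = 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n, size = 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", n, size = 4, endian = "little"),
    float = , float32 = readBin(bytes, "numeric", n, size = 4,
                                endian = "little"),
    double = , float64 = readBin(bytes, "numeric", n, size = 8,
                                 endian = "little"),
    stop(sprintf("unsupported PLY property type '%s'", type)))
}

# Returns list(vertices, colors (NULL or [0,1] matrix), faces (NULL or 1-based
# integer matrix)). Supports ascii and binary_little_endian, scalar vertex
# properties and triangular face lists.
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop(sprintf("'%s': unexpected end of PLY header", path))
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop(sprintf("'%s' is not a PLY file", path))
  fmt_line <- grep("^format", header, value = TRUE)
  if (length(fmt_line) != 1) stop(sprintf("'%s': missing PLY format line", path))
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("'%s': unsupported PLY format '%s'", path, fmt))
  }

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop(sprintf("'%s': PLY file has no vertex element", path))

  out <- list(vertices = NULL, colors = NULL, faces = NULL)
  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    at <- 1L
    for (el in elements) {
      n <- el$count
      block <- rest[seq.int(at, length.out = n)]
      at <- at + n
      if (el$name == "vertex") {
        vals <- matrix(suppressWarnings(
          as.numeric(unlist(strsplit(trimws(block), "\\s+")))),
          nrow = n, byrow = TRUE)
        if (anyNA(vals)) stop(sprintf("'%s': malformed PLY vertex record", path))
        nm <- vapply(el$props, `[[`, "", "name")
        out$vertices <- vals[, match(c("x", "y", "z"), nm), drop = FALSE]
        if (all(c("red", "green", "blue") %in% nm)) {
          cols <- vals[, match(c("red", "green", "blue"), nm), drop = FALSE]
          if (any(cols > 1)) cols <- cols / 255
          out$colors <- cols
        }
      } else if (el$name == "face" && n > 0) {
        out$faces <- t(vapply(block, function(s) {
          v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
          if (v[1] != 3L) stop(sprintf("'%s': only triangular PLY faces supported", path))
          v[2:4] + 1L
        }, integer(3), USE.NAMES = FALSE))
      }
    }
  } else {
    for (el in elements) {
      n <- el$count
      if (n == 0) next
      is_list <- vapply(el$props, `[[`, TRUE, "list")
      if (el$name == "vertex") {
        if (any(is_list)) stop(sprintf("'%s': list property on vertex element", path))
        sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
        stride <- sum(sizes)
        raw <- readBin(con, "raw", n * stride)
        if (length(raw) < n * stride) stop(sprintf("'%s': truncated PLY data", path))
        rawm <- matrix(raw, nrow = stride)
        offs <- cumsum(c(0L, sizes[-length(sizes)]))
        nm <- vapply(el$props, `[[`, "", "name")
        cols <- lapply(seq_along(el$props), function(i) {
          b <- as.vector(rawm[(offs[i] + 1L):(offs[i] + sizes[i]), , drop = FALSE])
          ply_read_bin(b, el$props[[i]]$type, n)
        })
        names(cols) <- nm
        out$vertices <- cbind(cols$x, cols$y, cols$z)
        if (all(c("red", "green", "blue") %in% nm)) {
          cm <- cbind(cols$red, cols$green, cols$blue)
          if (any(cm > 1)) cm <- cm / 255
          out$colors <- cm
        }
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (!p$list) stop(sprintf("'%s': face element without list property", path))
        csz <- ply_type_size[[p$count_type]]
        isz <- ply_type_size[[p$type]]
        stride <- csz + 3L * isz
        raw <- readBin(con, "raw", n * stride)
        rawm <- matrix(raw, nrow = stride)
        cnt <- ply_read_bin(as.vector(rawm[1:csz, , drop = FALSE]), p$count_type, n)
        if (any(cnt != 3L)) stop(sprintf("'%s': only triangular PLY faces supported", path))
        idx <- ply_read_bin(as.vector(rawm[(csz + 1L):stride, , drop = FALSE]),
                            p$type, 3L * n)
        out$faces <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
      } else {
        # skip unknown fixed-stride element
        sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
        readBin(con, "raw", n * sum(sizes))
      }
    }
  }
  out
}

write_ply <- function(path, vertices, colors = NULL, faces = NULL) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop(sprintf("cannot write '%s'", path))
  on.exit(close(con))
  n <- nrow(vertices)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z")
  if (!is.null(colors)) {
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue")
  }
  if (!is.null(faces)) {
    header <- c(header, sprintf("element face %d", nrow(faces)),
                "property list uchar int vertex_indices")
  }
  header <- c(header, "end_header")
  writeLines(header, con)
  body <- apply(vertices, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  if (!is.null(colors)) {
    cb <- apply(round(colors * 255), 1, paste, collapse = " ")
    body <- paste(body, cb)
  }
  writeLines(body, con)
  if (!is.null(faces)) {
    writeLines(paste(3, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

#' Normalize a point cloud to the unit box
#'
#' Centers the cloud at its bounding-box midpoint and applies a single
#' uniform scale so the largest axis extent maps to `[-1, 1]`. A uniform
#' scale (rather than per-axis) preserves sphericity of the components.
#'
#' @param cloud a [point_cloud()].
#' @return a list with `cloud` (the normalized cloud) and `transform`, a
#'   record with `center` and `scale` such that
#'   `normalized = (original - center) * scale`. Pass the record to
#'   [invert_transform_points()] to map results back to the input frame.
#' @export
normalize_pointcloud <- function(cloud) {
  pos <- cloud$positions
  lo <- apply(pos, 2, min)
  hi <- apply(pos, 2, max)
  extent <- hi - lo
  if (max(extent) <= 0) {
    stop("degenerate point cloud: all points are identical")
  }
  center <- (lo + hi) / 2
  scale <- 2 / max(extent)
  out <- sweep(pos, 2, center)
  out <- out * scale
  transform <- list(center = center, scale = scale)
  list(cloud = point_cloud(out, cloud$colors), transform = transform)
}

#' Map points from the normalized frame back to the input frame
#' @param points n x 3 matrix in the normalized frame.
#' @param transform a transform record from [normalize_pointcloud()].
#' @return n x 3 matrix in the original frame.
#' @export
invert_transform_points <- function(points, transform) {
  points <- as_xyz_matrix(points)
  sweep(points / transform$scale, 2, transform$center, "+")
}

#' Apply a normalization transform to points
#' @inheritParams invert_transform_points
#' @return n x 3 matrix in the normalized frame.
#' @export
apply_transform_points <- function(points, transform) {
  points <- as_xyz_matrix(points)
  sweep(points, 2, transform$center) * transform$scale
}

#' Specify a uniform voxel grid
#'
#' @param resolution_per_axis positive integer; the pipeline default divides
#'   the normalized unit box into a `200^3` grid.
#' @param lower,upper numeric length-3 bounds of the gridded box (defaults:
#'   the normalized `[-1, 1]^3` box).
#' @return a `voxel_grid_spec`.
#' @export
voxel_grid <- function(resolution_per_axis = 200, lower = c(-1, -1, -1),
                       upper = c(1, 1, 1)) {
  resolution_per_axis <- as.integer(resolution_per_axis)
  if (resolution_per_axis < 1) stop("'resolution_per_axis' must be >= 1")
  if (any(upper - lower <= 0)) stop("grid bounds must have positive extent")
  structure(list(resolution = resolution_per_axis,
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "voxel_grid_spec")
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in one voxel by their centroid. Voxel
#' membership uses half-open intervals `[lo, hi)` per axis with the last
#' voxel closed, so boundary points are assigned deterministically. Colors,
#' when present, are averaged per voxel.
#'
#' @param cloud a [point_cloud()] (normalized for the default grid).
#' @param grid a [voxel_grid()] specification.
#' @return a downsampled [point_cloud()].
#' @export
voxel_downsample <- function(cloud, grid = voxel_grid()) {
  pos <- cloud$positions
  res <- grid$resolution
  idx <- matrix(0L, nrow(pos), 3)
  for (a in 1:3) {
    lo <- grid$lower[a]; hi <- grid$upper[a]
    tol <- 1e-9 * max(1, abs(lo), abs(hi))   # numerical slack at the faces
    if (any(pos[, a] < lo - tol | pos[, a] > hi + tol)) {
      stop("point outside voxel grid bounds")
    }
    w <- (hi - lo) / res
    i <- floor((pos[, a] - lo) / w)
    i[i >= res] <- res - 1L   # closed last voxel
    i[i < 0] <- 0L
    idx[, a] <- as.integer(i)
  }
  key <- idx[, 1] + res * (idx[, 2] + res * idx[, 3])
  centroids <- rowsum(pos, key, reorder = TRUE)
  counts <- as.vector(rowsum(rep(1, nrow(pos)), key, reorder = TRUE))
  out_pos <- centroids / counts
  out_col <- NULL
  if (!is.null(cloud$colors)) {
    out_col <- rowsum(cloud$colors, key, reorder = TRUE) / counts
  }
  point_cloud(out_pos, out_col)
}

#' Filter a point cloud by color and/or a crop box
#'
#' @param cloud a [point_cloud()].
#' @param color_predicate optional function taking the n x 3 RGB matrix and
#'   returning a logical vector; see [hsv_range_predicate()]. Requires the
#'   cloud to carry colors.
#' @param crop_box optional list with `lower` and `upper` length-3 bounds;
#'   points outside are dropped (closed box).
#' @return the filtered [point_cloud()]; point order is preserved. May be
#'   empty-flagged: an error is raised only downstream, so callers can test
#'   `n_points()`.
#' @export
filter_cloud <- function(cloud, color_predicate = NULL, crop_box = NULL) {
  keep <- rep(TRUE, n_points(cloud))
  if (!is.null(color_predicate)) {
    if (is.null(cloud$colors)) {
      stop("color predicate supplied but the cloud has no colors")
    }
    keep <- keep & as.logical(color_predicate(cloud$colors))
  }
  if (!is.null(crop_box)) {
    pos <- cloud$positions
    for (a in 1:3) {
      keep <- keep & pos[, a] >= crop_box$lower[a] & pos[, a] <= crop_box$upper[a]
    }
  }
  if (!any(keep)) {
    out <- structure(list(positions = cloud$positions[0, , drop = FALSE],
                          colors = if (is.null(cloud$colors)) NULL else
                            cloud$colors[0, , drop = FALSE]),
                     class = "point_cloud")
    return(out)
  }
  point_cloud(cloud$positions[keep, , drop = FALSE],
              if (is.null(cloud$colors)) NULL else
                cloud$colors[keep, , drop = FALSE])
}

#' HSV-range color predicate
#'
#' Builds a predicate for [filter_cloud()] accepting points whose color falls
#' inside the given HSV ranges. Defaults accept everything.
#'
#' @param h,s,v length-2 numeric ranges in `[0, 1]`. A hue range with
#'   `h[1] > h[2]` wraps around 0 (useful for reds).
#' @return a function mapping an RGB matrix to a logical vector.
#' @export
hsv_range_predicate <- function(h = c(0, 1), s = c(0, 1), v = c(0, 1)) {
  force(h); force(s); force(v)
  function(rgb) {
    m <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
    hue <- m[1, ]
    hok <- if (h[1] <= h[2]) hue >= h[1] & hue <= h[2] else
      hue >= h[1] | hue <= h[2]
    hok & m[2, ] >= s[1] & m[2, ] <= s[2] & m[3, ] >= v[1] & m[3, ] <= v[2]
  }
}

#' Bounding-box diagonal of a set of points
#' @param x a `point_cloud` or n x 3 matrix.
#' @return the Euclidean length of the axis-aligned bounding-box diagonal.
#' @export
bbox_diagonal <- function(x) {
  pos <- as_xyz_matrix(x)
  sqrt(sum((apply(pos, 2, max) - apply(pos, 2, min))^2))
}
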