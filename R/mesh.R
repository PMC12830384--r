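#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `component_mesh`.
#' @export
component_mesh <- function(vertices, faces) {
  vertices <- as_xyz_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (nrow(vertices) == 0 || nrow(faces) == 0) stop("mesh must be non-empty")
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) stop("faces must be vertex-index triples")
  if (any(faces < 1) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "component_mesh")
}

#' @export
print.component_mesh <- function(x, ...) {
  cat(sprintf("<component_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Unit icosphere template
#'
#' Subdivided icosahedron with all vertices projected onto the unit sphere.
#' The default template for component fitting uses `subdivisions = 2`
#' (162 vertices, 320 faces); the tessellation density sets the floor of the
#' Chamfer score, so it is exposed in the pipeline configuration.
#'
#' @param subdivisions non-negative integer subdivision level.
#' @return a `component_mesh` with unit-norm vertices.
#' @export
icosphere <- function(subdivisions = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      midcache[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  component_mesh(v, f)
}

#' Place a template mesh by scale, rotation, and translation
#'
#' Vertices are mapped as `center + R %*% (scales * v)`.
#'
#' @param mesh a `component_mesh` (the unit template).
#' @param center length-3 translation.
#' @param scales length-1 (uniform) or length-3 per-axis scale factors.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @return the transformed `component_mesh`.
#' @export
transform_mesh <- function(mesh, center = c(0, 0, 0), scales = 1,
                           rotation = diag(3)) {
  if (length(scales) == 1) scales <- rep(scales, 3)
  v <- sweep(mesh$vertices, 2, scales, "*")
  v <- v %*% t(rotation)
  v <- sweep(v, 2, center, "+")
  component_mesh(v, mesh$faces)
}

#' Check that a mesh is watertight
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh a `component_mesh`.
#' @return logical flag; attribute `"defect"` describes the failure when
#'   `FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (all(tab == 2L)) return(TRUE)
  bad <- sum(tab != 2L)
  structure(FALSE, defect = sprintf(
    "%d edge(s) not shared by exactly two faces", bad))
}

#' Read a mesh from OBJ or PLY
#'
#' OBJ files with multiple `o`/`g` groups are returned as a list of meshes;
#' files with a single group (and PLY files) return one `component_mesh`.
#'
#' @param path file path (`.obj` or `.ply`).
#' @return a `component_mesh` or a list of them.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    ply <- read_ply(path)
    if (is.null(ply$faces)) stop(sprintf("'%s' has no faces", path))
    return(component_mesh(ply$vertices, ply$faces))
  }
  lines <- readLines(path, warn = FALSE)
  verts <- matrix(0, 0, 3)
  groups <- list()
  cur_faces <- matrix(0L, 0, 3)
  cur_name <- "default"
  flush_group <- function() {
    if (nrow(cur_faces) > 0) groups[[length(groups) + 1]] <<-
        list(name = cur_name, faces = cur_faces)
  }
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "v") {
      verts <- rbind(verts, as.numeric(tok[2:4]))
    } else if (tok[1] %in% c("o", "g")) {
      flush_group()
      cur_faces <- matrix(0L, 0, 3)
      cur_name <- if (length(tok) > 1) tok[2] else "unnamed"
    } else if (tok[1] == "f") {
      idx <- as.integer(vapply(tok[-1], function(s)
        strsplit(s, "/")[[1]][1], ""))
      if (length(idx) != 3) stop(sprintf("non-triangular face in '%s'", path))
      cur_faces <- rbind(cur_faces, idx)
    }
  }
  flush_group()
  if (length(groups) == 0) stop(sprintf("'%s' has no faces", path))
  meshes <- lapply(groups, function(g) {
    used <- sort(unique(as.vector(g$faces)))
    remap <- match(g$faces, used)
    component_mesh(verts[used, , drop = FALSE],
                   matrix(remap, ncol = 3))
  })
  names(meshes) <- vapply(groups, `[[`, "", "name")
  if (length(meshes) == 1) meshes[[1]] else meshes
}

#' Write fitted components as meshes
#'
#' Each fitted component places the template by its per-axis scales,
#' rotation, and center; when a normalization `transform` is supplied the
#' vertices are mapped back to the input cloud's original frame before
#' writing.
#'
#' @param components list of fitted components (see [detailed_fit()]).
#' @param template the unit `component_mesh` template.
#' @param path output path; `.obj` writes one file with one `o` group per
#'   component, `.ply` writes one concatenated ascii mesh.
#' @param format `"obj"` or `"ply"`.
#' @param transform optional normalization record from
#'   [normalize_pointcloud()] to invert.
#' @return `path`, invisibly.
#' @export
write_component_meshes <- function(components, template, path,
                                   format = c("obj", "ply"),
                                   transform = NULL) {
  format <- match.arg(format)
  placed <- lapply(components, function(cmp) {
    m <- transform_mesh(template, cmp$center, cmp$axis_scales, cmp$rotation)
    if (!is.null(transform)) {
      m$vertices <- invert_transform_points(m$vertices, transform)
    }
    m
  })
  if (format == "obj") {
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) stop(sprintf("cannot write '%s'", path))
    on.exit(close(con))
    off <- 0L
    for (i in seq_along(placed)) {
      writeLines(sprintf("o component_%03d", i), con)
      writeLines(apply(placed[[i]]$vertices, 1, function(r)
        paste("v", paste(format(r, digits = 17), collapse = " "))), con)
      f <- placed[[i]]$faces + off
      writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
      off <- off + nrow(placed[[i]]$vertices)
    }
  } else {
    verts <- do.call(rbind, lapply(placed, `[[`, "vertices"))
    offs <- cumsum(c(0L, vapply(placed, function(m) nrow(m$vertices),
                                integer(1))))
    faces <- do.call(rbind, lapply(seq_along(placed), function(i)
      placed[[i]]$faces + offs[i]))
    write_ply(path, verts, faces = faces)
  }
  invisible(path)
}
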