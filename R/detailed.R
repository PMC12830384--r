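#' Detailed per-cluster fit with per-axis scaling and rotation
#'
#' Final refinement of a fitted component, initialized from the best RANSAC
#' sphere. The greedy descent of [refine_locally()] is extended to a
#' coordinate descent over single moves around the current state:
#' translations of `+/-translation_step` along each axis, per-axis radius
#' scalings drawn from `scale_factors` (one axis at a time), and rotations
#' of `+/-10` degrees about each coordinate axis. Rotation increments
#' accumulate across iterations (the search can reach angles beyond 10
#' degrees), and the composed rotation is re-orthonormalized at every step.
#' The same three stopping criteria apply (`d_th1`, `d_th2`, `n_refi`), the
#' Chamfer score is evaluated against all cluster points, and it never
#' increases. Per-axis scales are clamped to `[0.4, 2.5]` times the initial
#' radius to prevent degenerate flattening on sparse clusters.
#'
#' @param cluster a `point_cloud` (all points of the cluster).
#' @param init a `fit_result` (or [sphere_model()]) giving the initial
#'   center, radius, and rotation.
#' @param template unit template mesh.
#' @param cfg a [ransac_config()].
#' @param rotation_step rotation increment in degrees.
#' @param source_cluster optional cluster index recorded in the result.
#' @return a `fitted_component`: list with `center`, `axis_scales`,
#'   `rotation`, `chamfer`, `iterations`, `trace`, `source_cluster`.
#' @export
detailed_fit <- function(cluster, init, template = NULL,
                         cfg = ransac_config(), rotation_step = 10,
                         source_cluster = NA_integer_) {
  pts <- as_xyz_matrix(cluster, "cluster")
  if (nrow(pts) == 0) stop("'cluster' must be non-empty")
  if (is.null(template)) template <- icosphere(cfg$template_subdivisions)
  if (inherits(init, "fit_result")) {
    sph <- init$sphere
    rot <- init$rotation
  } else {
    sph <- init
    rot <- diag(3)
  }
  res <- cpp_detailed_fit(pts, template$vertices, sph$center,
                          rep(sph$radius, 3), rot, cfg$translation_step,
                          cfg$scale_factors, rotation_step, cfg$d_th1,
                          cfg$d_th2, cfg$n_refi, 0.4 * sph$radius,
                          2.5 * sph$radius)
  structure(list(center = as.numeric(res$center),
                 axis_scales = as.numeric(res$scales),
                 rotation = res$rotation, chamfer = res$chamfer,
                 iterations = res$iterations, trace = res$trace,
                 source_cluster = source_cluster),
            class = "fitted_component")
}

#' @export
print.fitted_component <- function(x, ...) {
  cat(sprintf(
    "<fitted_component: c = (%.3f, %.3f, %.3f), scales = (%.3f, %.3f, %.3f), chamfer = %.5f>\n",
    x$center[1], x$center[2], x$center[3],
    x$axis_scales[1], x$axis_scales[2], x$axis_scales[3], x$chamfer))
  invisible(x)
}
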