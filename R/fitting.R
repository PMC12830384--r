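#' Sphere model
#' @param center length-3 numeric center.
#' @param radius positive radius.
#' @return an object of class `sphere_model`.
#' @export
sphere_model <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3 || !all(is.finite(center))) {
    stop("'center' must be a finite length-3 vector")
  }
  stopifnot_scalar_pos(radius, "radius")
  structure(list(center = center, radius = radius), class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("<sphere_model: c = (%.4f, %.4f, %.4f), r = %.4f>\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' RANSAC and refinement configuration
#'
#' All defaults are the printed operating values of the method: 50
#' hypotheses, 50 refinement iterations, a 10% subsample per hypothesis,
#' inlier threshold `epsilon = 0.015`, validity at an inlier fraction above
#' 50%, stopping thresholds `d_th1 = 0.015` (absolute Chamfer score) and
#' `d_th2 = 0.001` (improvement), translation step 0.01, and radius scalings
#' `{0.8, 0.9, 1.0, 1.1, 1.2}`. All lengths are in normalized (unit-box)
#' units. `initial_radius` has no universal default: set it to roughly the
#' radius of the smallest component in the aggregate.
#'
#' @param n_hypo number of RANSAC hypotheses per cluster.
#' @param n_refi maximum local-refinement iterations.
#' @param sample_fraction fraction of a cluster sampled per hypothesis.
#' @param epsilon inlier distance threshold (strict `<`).
#' @param min_inlier_ratio validity cutoff on the inlier fraction
#'   (strict `>`).
#' @param d_th1 absolute Chamfer stopping threshold.
#' @param d_th2 Chamfer improvement stopping threshold.
#' @param translation_step candidate translation step size.
#' @param scale_factors candidate radius scalings; must contain 1.0.
#' @param initial_radius initial sphere radius (normalized units).
#' @param template_subdivisions icosphere subdivision level of the default
#'   template (2 gives 162 vertices).
#' @param min_cluster_points clusters smaller than this are skipped.
#' @return a `ransac_config` list.
#' @export
ransac_config <- function(n_hypo = 50, n_refi = 50, sample_fraction = 0.10,
                          epsilon = 0.015, min_inlier_ratio = 0.5,
                          d_th1 = 0.015, d_th2 = 0.001,
                          translation_step = 0.01,
                          scale_factors = c(0.8, 0.9, 1.0, 1.1, 1.2),
                          initial_radius = NULL,
                          template_subdivisions = 2,
                          min_cluster_points = 10) {
  for (nm in c("n_hypo", "n_refi", "sample_fraction", "epsilon",
               "min_inlier_ratio", "d_th1", "d_th2", "translation_step")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (sample_fraction > 1) stop("'sample_fraction' must be in (0, 1]")
  if (min_inlier_ratio >= 1) stop("'min_inlier_ratio' must be in (0, 1)")
  if (!any(scale_factors == 1.0)) stop("'scale_factors' must contain 1.0")
  if (any(scale_factors <= 0)) stop("'scale_factors' must be positive")
  if (!is.null(initial_radius)) stopifnot_scalar_pos(initial_radius,
                                                     "initial_radius")
  structure(list(n_hypo = as.integer(n_hypo), n_refi = as.integer(n_refi),
                 sample_fraction = sample_fraction, epsilon = epsilon,
                 min_inlier_ratio = min_inlier_ratio, d_th1 = d_th1,
                 d_th2 = d_th2, translation_step = translation_step,
                 scale_factors = as.numeric(scale_factors),
                 initial_radius = initial_radius,
                 template_subdivisions = as.integer(template_subdivisions),
                 min_cluster_points = as.integer(min_cluster_points)),
            class = "ransac_config")
}

#' Distance from points to a sphere surface
#'
#' `d = | r - || p - c ||_2 |`, the unsigned distance to the surface of the
#' sphere; the inlier test marks points with `d < epsilon`.
#'
#' @param points a `point_cloud` or n x 3 matrix.
#' @param sphere a [sphere_model()].
#' @return numeric vector of distances.
#' @export
point_to_sphere_distance <- function(points, sphere) {
  p <- as_xyz_matrix(points)
  abs(sphere$radius - sqrt(rowSums(sweep(p, 2, sphere$center)^2)))
}

#' Symmetric Chamfer distance between two point sets
#'
#' The mean nearest-neighbor distance from `a` to `b` plus the mean
#' nearest-neighbor distance from `b` to `a` (a sum of two means, with no
#' 1/2 factor). This is the fitting objective, evaluated between sampled
#' cluster points and the vertices of the placed template mesh.
#'
#' @param a,b point clouds, meshes, or n x 3 matrices; both non-empty.
#' @return non-negative Chamfer score.
#' @export
chamfer_distance <- function(a, b) {
  a <- as_xyz_matrix(a, "a")
  b <- as_xyz_matrix(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("chamfer_distance requires two non-empty point sets")
  }
  cpp_chamfer(a, b)
}

#' Candidate spheres for one refinement iteration
#'
#' Enumerates the candidate set scored in each local-refinement iteration:
#' 7 translations (no move, +/-step along each of x, y, z) crossed with the
#' radius scalings, i.e. 35 candidates under the default configuration.
#' The scalings multiply the initial radius, not the current one: the
#' reachable radii form a fixed grid anchored to the user's physical prior,
#' which is why the method is sensitive to an initial radius chosen below
#' the smallest component.
#'
#' @param sphere the current [sphere_model()].
#' @param cfg a [ransac_config()].
#' @param initial_radius the radius the scale grid is anchored to
#'   (defaults to the current sphere's radius, i.e. the first iteration).
#' @return a data.frame with one row per candidate (`dx`, `dy`, `dz`,
#'   `scale`, and the resulting `cx`, `cy`, `cz`, `radius`).
#' @export
refinement_candidates <- function(sphere, cfg = ransac_config(),
                                  initial_radius = sphere$radius) {
  tdir <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * cfg$translation_step
  grid <- expand.grid(s = seq_along(cfg$scale_factors), t = seq_len(7))
  data.frame(
    dx = tdir[grid$t, 1], dy = tdir[grid$t, 2], dz = tdir[grid$t, 3],
    scale = cfg$scale_factors[grid$s],
    cx = sphere$center[1] + tdir[grid$t, 1],
    cy = sphere$center[2] + tdir[grid$t, 2],
    cz = sphere$center[3] + tdir[grid$t, 3],
    radius = initial_radius * cfg$scale_factors[grid$s])
}

#' Greedy local refinement of a sphere hypothesis
#'
#' Starting from `init`, each iteration scores the 35 candidates of
#' [refinement_candidates()] by the Chamfer distance between `samples` and
#' the placed template, and adopts the strict minimizer (ties keep the
#' current state, preferring no move and the current radius). Candidate
#' radii are the scale grid times the *initial* radius, so the search
#' cannot drift arbitrarily far from the user's size prior. Stops when the
#' score falls below `d_th1`, the improvement falls below `d_th2`, or
#' `n_refi` iterations are reached; the score never increases.
#'
#' @param samples a `point_cloud` or matrix of sample points (non-empty).
#' @param init initial [sphere_model()].
#' @param template unit template mesh (default icosphere from `cfg`).
#' @param cfg a [ransac_config()].
#' @param rotation fixed 3 x 3 rotation applied to the template (used for
#'   rotated hypotheses of non-spherical templates).
#' @return a list with `sphere`, `chamfer`, `iterations`, `trace` (the
#'   Chamfer value at initialization and after each iteration), and the
#'   `rotation`.
#' @export
refine_locally <- function(samples, init, template = NULL,
                           cfg = ransac_config(), rotation = diag(3)) {
  pts <- as_xyz_matrix(samples, "samples")
  if (nrow(pts) == 0) stop("'samples' must be non-empty")
  if (is.null(template)) template <- icosphere(cfg$template_subdivisions)
  uv <- template$vertices %*% t(rotation)
  res <- cpp_refine_sphere(pts, uv, init$center, init$radius,
                           cfg$translation_step, cfg$scale_factors,
                           cfg$d_th1, cfg$d_th2, cfg$n_refi)
  list(sphere = sphere_model(res$center, res$radius), chamfer = res$chamfer,
       iterations = res$iterations, trace = res$trace, rotation = rotation)
}

#' Generate and evaluate one RANSAC hypothesis
#'
#' Draws `sample_fraction` of the cluster (at least 3 points) without
#' replacement, places an initial sphere of radius `cfg$initial_radius` at
#' the sample centroid, refines it locally against the sample, and then
#' evaluates the refined sphere on the whole cluster: points whose surface
#' distance is strictly below `epsilon` are inliers, and the hypothesis is
#' valid when the inlier fraction strictly exceeds `min_inlier_ratio`. For a
#' valid hypothesis the reported Chamfer score is recomputed between the
#' placed template and the inlier points.
#'
#' With a non-spherical template (`nonspherical` supplied), seven rotated
#' variants of the initial placement are each refined and the best kept, and
#' validity uses the generalized criterion: the fraction of template
#' vertices within `epsilon` of the cluster must exceed
#' `min_vertex_inlier_fraction`; the score is then the Chamfer distance to
#' the whole cluster.
#'
#' @param cluster a `point_cloud` (the cluster's points).
#' @param cfg a [ransac_config()] with `initial_radius` set.
#' @param seed integer seed for the subsample.
#' @param template unit template mesh.
#' @param nonspherical optional [nonspherical_config()].
#' @return a `fit_result` (list with `sphere`, `rotation`, `chamfer`,
#'   `inlier_ratio`, `valid`, `iterations`), or `NULL` for clusters smaller
#'   than `cfg$min_cluster_points` (skip signal).
#' @export
generate_hypothesis <- function(cluster, cfg, seed = 1, template = NULL,
                                nonspherical = NULL) {
  n <- n_points(cluster)
  if (n < cfg$min_cluster_points) return(NULL)
  if (is.null(cfg$initial_radius)) {
    stop("cfg$initial_radius must be set (radius of the smallest component)")
  }
  if (is.null(template)) template <- icosphere(cfg$template_subdivisions)
  m <- max(3L, round(cfg$sample_fraction * n))
  idx <- with_seed(seed, sample.int(n, m))
  smp <- cluster$positions[idx, , drop = FALSE]
  init <- sphere_model(colMeans(smp), cfg$initial_radius)

  if (is.null(nonspherical)) {
    ref <- refine_locally(smp, init, template, cfg)
  } else {
    rots <- rotated_hypotheses()
    fits <- lapply(rots, function(R) refine_locally(smp, init, template, cfg,
                                                    rotation = R))
    ref <- fits[[which.min(vapply(fits, `[[`, 0, "chamfer"))]]
  }
  sph <- ref$sphere
  placed <- transform_mesh(template, sph$center, sph$radius, ref$rotation)

  if (is.null(nonspherical)) {
    d <- point_to_sphere_distance(cluster, sph)
    ratio <- mean(d < cfg$epsilon)
    valid <- ratio > cfg$min_inlier_ratio
    chamfer <- if (valid) {
      chamfer_distance(cluster$positions[d < cfg$epsilon, , drop = FALSE],
                       placed$vertices)
    } else NA_real_
  } else {
    ratio <- vertex_inlier_fraction(placed, cluster,
                                    nonspherical$vertex_inlier_threshold)
    valid <- ratio > nonspherical$min_vertex_inlier_fraction
    chamfer <- if (valid) chamfer_distance(cluster, placed$vertices) else
      NA_real_
  }
  structure(list(sphere = sph, rotation = ref$rotation, chamfer = chamfer,
                 inlier_ratio = ratio, valid = valid,
                 iterations = ref$iterations),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result: r = %.4f, inliers = %.0f%%, %s, chamfer = %s>\n",
    x$sphere$radius, 100 * x$inlier_ratio,
    if (x$valid) "valid" else "invalid",
    if (is.na(x$chamfer)) "NA" else sprintf("%.5f", x$chamfer)))
  invisible(x)
}

#' Fit a component to a cluster by RANSAC
#'
#' Runs [generate_hypothesis()] `cfg$n_hypo` times with independently
#' derived sub-seeds and returns the valid hypothesis with the smallest
#' Chamfer score, or `NULL` when no hypothesis is valid (no-fit).
#'
#' @inheritParams generate_hypothesis
#' @param seed master seed; per-hypothesis seeds come from [derive_seed()].
#' @return the best `fit_result`, or `NULL`.
#' @export
fit_component <- function(cluster, cfg, seed = 1, template = NULL,
                          nonspherical = NULL) {
  if (n_points(cluster) < cfg$min_cluster_points) return(NULL)
  if (is.null(template)) template <- icosphere(cfg$template_subdivisions)
  best <- NULL
  for (i in seq_len(cfg$n_hypo)) {
    hyp <- generate_hypothesis(cluster, cfg, derive_seed(seed, 101L, i),
                               template, nonspherical)
    if (is.null(hyp) || !hyp$valid) next
    if (is.null(best) || hyp$chamfer < best$chamfer) best <- hyp
  }
  best
}
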