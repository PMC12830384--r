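#' Full pipeline configuration
#'
#' Bundles every stage parameter at the method's operating values: voxel
#' resolution 200 per axis over the normalized unit box, 50 hypotheses, 50
#' refinement iterations, 10% subsampling, inlier threshold 0.015, 50%
#' validity, stopping thresholds 0.015 / 0.001, translation step 0.01,
#' radius scalings {0.8, 0.9, 1.0, 1.1, 1.2}, and sphere-overlap fraction
#' `alpha = 0.9`.
#'
#' @param k initial number of k-means clusters; choose 1.5-2x the expected
#'   component count.
#' @param initial_radius initial sphere radius, expressed in the input
#'   cloud's units (roughly the radius of the smallest component); the
#'   pipeline converts it to the normalized frame internally.
#' @param seed master seed; all stage and hypothesis seeds derive from it.
#' @param shape component shape mode; `"ellipsoid"` and `"deformed"` enable
#'   the generalized vertex inlier criterion, rotated hypotheses, and the
#'   inside-outside merge rule.
#' @param voxel_resolution per-axis voxel grid resolution.
#' @param alpha sphere overlap fraction for merging.
#' @param ransac a [ransac_config()]; its `initial_radius` is overridden by
#'   the pipeline-level value.
#' @param nonspherical a [nonspherical_config()]; defaults to a merge
#'   threshold of 2% for ellipsoids and 10% for deformed shapes.
#' @param color_predicate,crop_box optional input filters, see
#'   [filter_cloud()].
#' @param normalize normalize the input cloud to the unit box (disable only
#'   for clouds already in normalized units).
#' @param max_merge_rounds cap on merge rounds (default: initial `k`).
#' @param rotation_step detailed-fitting rotation increment in degrees.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(k, initial_radius, seed = 1,
                            shape = c("sphere", "ellipsoid", "deformed"),
                            voxel_resolution = 200, alpha = 0.9,
                            ransac = ransac_config(),
                            nonspherical = NULL,
                            color_predicate = NULL, crop_box = NULL,
                            normalize = TRUE, max_merge_rounds = NULL,
                            rotation_step = 10) {
  shape <- match.arg(shape)
  stopifnot_scalar_pos(k, "k")
  stopifnot_scalar_pos(initial_radius, "initial_radius")
  stopifnot_scalar_pos(alpha, "alpha")
  if (is.null(nonspherical) && shape != "sphere") {
    nonspherical <- nonspherical_config(
      vertex_inlier_threshold = ransac$epsilon,
      merge_inside_percent = if (shape == "ellipsoid") 2 else 10)
  }
  structure(list(k = as.integer(k), initial_radius = initial_radius,
                 seed = as.integer(seed), shape = shape,
                 voxel_resolution = as.integer(voxel_resolution),
                 alpha = alpha, ransac = ransac,
                 nonspherical = nonspherical,
                 color_predicate = color_predicate, crop_box = crop_box,
                 normalize = isTRUE(normalize),
                 max_merge_rounds = max_merge_rounds,
                 rotation_step = rotation_step),
            class = "pipeline_config")
}

#' Run the full segmentation pipeline
#'
#' Stage order: filter, normalize, voxel-downsample, k-means cluster, RANSAC
#' fit per cluster, merge overlapping fits to a fixpoint, detailed per-axis
#' fit, and (optionally) evaluation against ground truth and mesh/report
#' export. Deterministic for a fixed configuration and seed.
#'
#' @param input a [point_cloud()] or a path readable by
#'   [read_pointcloud()].
#' @param cfg a [pipeline_config()].
#' @param truth optional `ground_truth_aggregate` (or matrix of true
#'   centers, in the input frame) for evaluation.
#' @param template optional unit template mesh (defaults to the icosphere
#'   configured in `cfg$ransac`).
#' @param output_dir optional directory; when given, writes
#'   `components.obj`, `report.json`, and `clusters.csv` there.
#' @return an `aggseg_result`: list with `components` (fitted components in
#'   the working frame), `centers_input` (component centers mapped back to
#'   the input frame), `clusters`, `fits`, `transform`, `merge_history`,
#'   `evaluation` (or `NULL`), and `report` (the serializable report).
#' @export
run_pipeline <- function(input, cfg, truth = NULL, template = NULL,
                         output_dir = NULL) {
  cloud <- if (inherits(input, "point_cloud")) input else
    read_pointcloud(input)
  cloud <- filter_cloud(cloud, cfg$color_predicate, cfg$crop_box)
  if (n_points(cloud) == 0) stop("input cloud is empty after filtering")
  input_diagonal <- bbox_diagonal(cloud)

  if (cfg$normalize) {
    norm <- normalize_pointcloud(cloud)
    working <- norm$cloud
    transform <- norm$transform
    grid <- voxel_grid(cfg$voxel_resolution)
  } else {
    working <- cloud
    transform <- list(center = c(0, 0, 0), scale = 1)
    lo <- apply(working$positions, 2, min)
    hi <- apply(working$positions, 2, max)
    pad <- 1e-9 + 1e-9 * (hi - lo)
    grid <- voxel_grid(cfg$voxel_resolution, lo - pad, hi + pad)
  }
  working <- voxel_downsample(working, grid)

  rcfg <- cfg$ransac
  rcfg$initial_radius <- cfg$initial_radius * transform$scale
  if (is.null(template)) template <- icosphere(rcfg$template_subdivisions)

  if (cfg$k > n_points(working)) {
    stop("'k' exceeds the number of downsampled points")
  }
  clusters <- kmeans_cluster(working, cfg$k, derive_seed(cfg$seed, 1L))
  fits <- fit_all_clusters(clusters, rcfg, derive_seed(cfg$seed, 2L),
                           template, cfg$nonspherical)
  if (!any(vapply(fits, function(f) !is.null(f) && f$valid, TRUE))) {
    warning("no cluster produced a valid fit")
  }
  merged <- merge_to_fixpoint(clusters, fits, rcfg,
                              derive_seed(cfg$seed, 3L), cfg$alpha,
                              template, cfg$nonspherical,
                              max_rounds = cfg$max_merge_rounds)
  clusters <- merged$clusters
  fits <- merged$fits

  components <- list()
  for (i in seq_len(clusters$k)) {
    if (is.null(fits[[i]]) || !fits[[i]]$valid) next
    cl <- extract_cluster(clusters, i)
    components[[length(components) + 1]] <-
      detailed_fit(cl, fits[[i]], template, rcfg, cfg$rotation_step,
                   source_cluster = i)
  }

  centers_input <- if (length(components) > 0) {
    invert_transform_points(
      do.call(rbind, lapply(components, `[[`, "center")), transform)
  } else matrix(0, 0, 3)

  evaluation <- NULL
  if (!is.null(truth) && length(components) > 0) {
    evaluation <- evaluate_components(truth, centers_input, input_diagonal)
  }

  report <- build_report(cfg, components, centers_input, merged$history,
                         n_points(cloud), n_points(working), evaluation)
  result <- structure(list(components = components,
                           centers_input = centers_input,
                           clusters = clusters, fits = fits,
                           transform = transform,
                           merge_history = merged$history,
                           evaluation = evaluation, report = report,
                           template = template),
                      class = "aggseg_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (length(components) > 0) {
      write_component_meshes(components, template,
                             file.path(output_dir, "components.obj"),
                             format = "obj", transform = transform)
    }
    write_report(result, file.path(output_dir, "report.json"))
    utils::write.csv(data.frame(cluster = clusters$labels),
                     file.path(output_dir, "clusters.csv"),
                     row.names = FALSE)
  }
  result
}

#' @export
summary.aggseg_result <- function(object, ...) {
  rep <- object$report
  ev <- rep$evaluation
  df <- data.frame(
    N_v = rep$n_points_input, N_i = rep$config$k,
    N_e = if (is.null(ev)) NA_integer_ else ev$n_true,
    N_m = rep$n_components,
    M_d = if (is.null(ev)) NA_real_ else ev$m_d,
    M_s = if (is.null(ev)) NA_real_ else ev$m_s)
  rownames(df) <- "run"
  df
}

#' @export
print.aggseg_result <- function(x, ...) {
  cat(sprintf("<aggseg_result: %d components from %d final clusters>\n",
              length(x$components), x$clusters$k))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

build_report <- function(cfg, components, centers_input, history,
                         n_input, n_working, evaluation) {
  list(
    config = list(
      k = cfg$k, initial_radius = cfg$initial_radius, seed = cfg$seed,
      shape = cfg$shape, voxel_resolution = cfg$voxel_resolution,
      alpha = cfg$alpha,
      n_hypo = cfg$ransac$n_hypo, n_refi = cfg$ransac$n_refi,
      sample_fraction = cfg$ransac$sample_fraction,
      epsilon = cfg$ransac$epsilon,
      min_inlier_ratio = cfg$ransac$min_inlier_ratio,
      d_th1 = cfg$ransac$d_th1, d_th2 = cfg$ransac$d_th2,
      translation_step = cfg$ransac$translation_step,
      scale_factors = cfg$ransac$scale_factors),
    n_points_input = n_input,
    n_points_downsampled = n_working,
    merge_history = as.integer(history),
    n_components = length(components),
    components = lapply(seq_along(components), function(i) {
      cmp <- components[[i]]
      list(index = i, center = as.numeric(centers_input[i, ]),
           center_normalized = cmp$center,
           axis_scales = cmp$axis_scales,
           rotation = as.vector(cmp$rotation),
           chamfer = cmp$chamfer, source_cluster = cmp$source_cluster)
    }),
    evaluation = if (is.null(evaluation)) NULL else list(
      n_true = evaluation$n_true, n_found = evaluation$n_found,
      m_d = evaluation$m_d, m_s = evaluation$m_s))
}

#' Write a pipeline result report as JSON
#' @param result an `aggseg_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Sensitivity sweep over cluster count and initial radius
#'
#' Reruns the pipeline over a grid of cluster-count multipliers (applied to
#' the true component count) and initial-radius multipliers (applied to the
#' smallest true component radius), mirroring the stability protocol for
#' the two user-set parameters: `k` in 1-3x the component count, and radius
#' factors 0.7-1.3 of the smallest component.
#'
#' @param cloud the input [point_cloud()].
#' @param truth a `ground_truth_aggregate`.
#' @param base_cfg a [pipeline_config()] supplying all other parameters.
#' @param k_multipliers numeric multipliers on the true component count.
#' @param radius_multipliers numeric multipliers on the smallest true
#'   component radius.
#' @return a data.frame with one row per grid cell: `k_multiplier`,
#'   `radius_multiplier`, `k`, `initial_radius`, `n_true`, `n_found`,
#'   `m_d`, `m_s`.
#' @export
run_sensitivity_sweep <- function(cloud, truth, base_cfg,
                                  k_multipliers = c(1, 2, 3),
                                  radius_multipliers =
                                    c(0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3)) {
  n_e <- length(truth$components)
  r_min <- min(vapply(truth$components, function(cmp) min(cmp$radii), 0))
  grid <- expand.grid(k_multiplier = k_multipliers,
                      radius_multiplier = radius_multipliers)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_cfg
    cfg$k <- as.integer(round(grid$k_multiplier[i] * n_e))
    cfg$initial_radius <- grid$radius_multiplier[i] * r_min
    res <- run_pipeline(cloud, cfg, truth = truth)
    ev <- res$evaluation
    data.frame(k_multiplier = grid$k_multiplier[i],
               radius_multiplier = grid$radius_multiplier[i],
               k = cfg$k, initial_radius = cfg$initial_radius,
               n_true = n_e,
               n_found = length(res$components),
               m_d = if (is.null(ev)) NA_real_ else ev$m_d,
               m_s = if (is.null(ev)) NA_real_ else ev$m_s)
  })
  do.call(rbind, rows)
}
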