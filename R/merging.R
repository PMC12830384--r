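#' Overlap test for two fitted spheres
#'
#' Two spheres overlap when the distance between their centers is strictly
#' less than `alpha` times the sum of their radii; the operating value is
#' `alpha = 0.9` (centers closer than 90% of the radius sum).
#'
#' @param a,b [sphere_model()] objects.
#' @param alpha overlap fraction.
#' @return logical flag.
#' @export
spheres_overlap <- function(a, b, alpha = 0.9) {
  sqrt(sum((a$center - b$center)^2)) < alpha * (a$radius + b$radius)
}

#' Fit every cluster of a cluster set
#'
#' @param clusters a `cluster_set`.
#' @param cfg a [ransac_config()].
#' @param seed master seed; per-cluster seeds are derived.
#' @param template unit template mesh.
#' @param nonspherical optional [nonspherical_config()].
#' @return a list of length `k` holding `fit_result` objects or `NULL` for
#'   clusters where no valid hypothesis was found (or that were too small).
#' @export
fit_all_clusters <- function(clusters, cfg, seed = 1, template = NULL,
                             nonspherical = NULL) {
  if (is.null(template)) template <- icosphere(cfg$template_subdivisions)
  lapply(seq_len(clusters$k), function(i) {
    fit_component(extract_cluster(clusters, i), cfg,
                  derive_seed(seed, 301L, i), template, nonspherical)
  })
}

# overlap predicate between two fit results under the configured shape mode
fits_overlap <- function(fa, fb, alpha, template, nonspherical) {
  if (is.null(nonspherical)) {
    spheres_overlap(fa$sphere, fb$sphere, alpha)
  } else {
    ma <- transform_mesh(template, fa$sphere$center, fa$sphere$radius,
                         fa$rotation)
    mb <- transform_mesh(template, fb$sphere$center, fb$sphere$radius,
                         fb$rotation)
    nonspherical_merge_test(ma, mb, nonspherical)
  }
}

#' One round of overlap-driven cluster merging
#'
#' Builds the overlap graph over clusters with valid fits (spherical overlap
#' rule, or the inside-outside test for non-spherical templates), and for
#' every connected component of `m >= 2` overlapping fits pools those
#' clusters' points and re-clusters them with `k = m - 1` (a pair simply
#' becomes one merged cluster), then refits each new cluster. Unaffected
#' clusters, including ones without a fit, pass through untouched (no-fit
#' clusters are refitted so later rounds can pick them up).
#'
#' @param clusters a `cluster_set`.
#' @param fits fits aligned with `clusters` (from [fit_all_clusters()]).
#' @param cfg a [ransac_config()].
#' @param seed master seed for re-clustering and refitting.
#' @param alpha sphere overlap fraction.
#' @param template unit template mesh.
#' @param nonspherical optional [nonspherical_config()].
#' @return list with `clusters`, `fits`, and `changed` (TRUE iff any overlap
#'   edge existed).
#' @export
merge_step <- function(clusters, fits, cfg, seed = 1, alpha = 0.9,
                       template = NULL, nonspherical = NULL) {
  if (is.null(template)) template <- icosphere(cfg$template_subdivisions)
  valid <- which(vapply(fits, function(f) !is.null(f) && f$valid, TRUE))
  edges <- matrix(0L, 0, 2)
  if (length(valid) >= 2) {
    pairs <- utils::combn(valid, 2)
    hit <- apply(pairs, 2, function(p) {
      fits_overlap(fits[[p[1]]], fits[[p[2]]], alpha, template, nonspherical)
    })
    edges <- t(pairs[, hit, drop = FALSE])
  }
  if (nrow(edges) == 0) {
    return(list(clusters = clusters, fits = fits, changed = FALSE))
  }
  g <- igraph::make_empty_graph(n = clusters$k, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  groups <- split(seq_len(clusters$k), comp$membership)
  groups <- groups[vapply(groups, length, 1L) >= 2]

  labels <- clusters$labels
  new_labels <- integer(length(labels))
  new_fits <- list()
  next_id <- 0L
  grouped <- unlist(groups, use.names = FALSE)
  for (i in seq_len(clusters$k)) {
    if (i %in% grouped) next
    next_id <- next_id + 1L
    new_labels[labels == i] <- next_id
    if ((is.null(fits[[i]]) || !fits[[i]]$valid) && sum(labels == i) > 0) {
      # no-fit clusters get another chance each round with a fresh sub-seed
      cl <- point_cloud(clusters$cloud$positions[labels == i, , drop = FALSE])
      new_fits[[next_id]] <- fit_component(cl, cfg,
                                           derive_seed(seed, 204L, next_id),
                                           template, nonspherical)
    } else {
      new_fits[[next_id]] <- fits[[i]]
    }
  }
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    m <- length(grp)
    sel <- labels %in% grp
    sub <- point_cloud(clusters$cloud$positions[sel, , drop = FALSE])
    if (m == 2L) {
      sub_labels <- rep(1L, n_points(sub))
      k_new <- 1L
    } else {
      k_new <- m - 1L
      sub_set <- kmeans_cluster(sub, k_new, derive_seed(seed, 202L, gi))
      sub_labels <- sub_set$labels
    }
    for (j in seq_len(k_new)) {
      next_id <- next_id + 1L
      idx <- which(sel)[sub_labels == j]
      new_labels[idx] <- next_id
      cl <- point_cloud(clusters$cloud$positions[idx, , drop = FALSE])
      new_fits[[next_id]] <- fit_component(cl, cfg,
                                           derive_seed(seed, 203L, next_id),
                                           template, nonspherical)
    }
  }
  k <- next_id
  centers <- rowsum(clusters$cloud$positions,
                    factor(new_labels, levels = seq_len(k))) /
    tabulate(new_labels, nbins = k)
  out <- structure(list(labels = new_labels, k = k, centers = centers,
                        cloud = clusters$cloud),
                   class = "cluster_set")
  # pad fits for any empty trailing clusters (cannot occur, but keep aligned)
  length(new_fits) <- k
  list(clusters = out, fits = new_fits, changed = TRUE)
}

#' Iterate merging to a fixpoint
#'
#' Repeats [merge_step()] until no overlapping fits remain or `max_rounds`
#' is reached. Because each merge strictly decreases the cluster count,
#' termination is guaranteed within the initial `k` rounds (the default
#' cap); hitting the cap raises a warning.
#'
#' @inheritParams merge_step
#' @param max_rounds round cap (default: the current cluster count).
#' @param verbose emit a message with the cluster count per round.
#' @return list with `clusters`, `fits`, `rounds` (rounds actually run),
#'   and `history` (cluster count after each round).
#' @export
merge_to_fixpoint <- function(clusters, fits, cfg, seed = 1, alpha = 0.9,
                              template = NULL, nonspherical = NULL,
                              max_rounds = NULL, verbose = FALSE) {
  if (is.null(max_rounds)) max_rounds <- clusters$k
  if (max_rounds < 1) stop("'max_rounds' must be >= 1")
  history <- integer(0)
  rounds <- 0L
  repeat {
    if (rounds >= max_rounds) {
      warning("merge_to_fixpoint: round cap reached before fixpoint")
      break
    }
    step <- merge_step(clusters, fits, cfg, derive_seed(seed, 401L, rounds),
                       alpha, template, nonspherical)
    rounds <- rounds + 1L
    clusters <- step$clusters
    fits <- step$fits
    history <- c(history, clusters$k)
    if (verbose) {
      message(sprintf("merge round %d: %d clusters", rounds, clusters$k))
    }
    if (!step$changed) break
  }
  list(clusters = clusters, fits = fits, rounds = rounds, history = history)
}
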