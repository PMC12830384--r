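#' Configuration for non-spherical components
#'
#' Extensions used for ellipsoidal and slightly deformed component
#' templates: the inlier criterion generalizes from the point-to-sphere
#' distance to the proportion of template vertices near the cluster, the
#' hypothesis stage adds rotated variants, and the merge rule uses the
#' inside-outside vertex fraction (`2`% works well for ellipsoids, `10`%
#' for deformed shapes).
#'
#' @param vertex_inlier_threshold distance threshold for the generalized
#'   vertex inlier criterion (reuses the spherical `epsilon`).
#' @param min_vertex_inlier_fraction validity cutoff on the vertex inlier
#'   fraction (strict `>`), mirroring the spherical 50% rule.
#' @param merge_inside_percent merge threshold `n` in percent: components
#'   merge when more than `n`% of one's vertices lie inside the other.
#' @return a `nonspherical_config` list.
#' @export
nonspherical_config <- function(vertex_inlier_threshold = 0.015,
                                min_vertex_inlier_fraction = 0.5,
                                merge_inside_percent = 2) {
  stopifnot_scalar_pos(vertex_inlier_threshold, "vertex_inlier_threshold")
  stopifnot_scalar_pos(min_vertex_inlier_fraction,
                       "min_vertex_inlier_fraction")
  if (merge_inside_percent <= 0 || merge_inside_percent >= 100) {
    stop("'merge_inside_percent' must be in (0, 100)")
  }
  structure(list(vertex_inlier_threshold = vertex_inlier_threshold,
                 min_vertex_inlier_fraction = min_vertex_inlier_fraction,
                 merge_inside_percent = merge_inside_percent),
            class = "nonspherical_config")
}

#' Fraction of template vertices near a cluster
#'
#' For every vertex of the placed template, the distance to the nearest
#' cluster point is computed; the returned value is the fraction of
#' vertices whose distance is strictly below `threshold`. This is the
#' generalized inlier criterion for non-spherical templates; it is monotone
#' non-decreasing in `threshold`.
#'
#' @param placed_template a `component_mesh` already placed in the cluster
#'   frame.
#' @param cluster a `point_cloud` or n x 3 matrix.
#' @param threshold distance threshold.
#' @return fraction in `[0, 1]`.
#' @export
vertex_inlier_fraction <- function(placed_template, cluster, threshold) {
  v <- as_xyz_matrix(placed_template, "placed_template")
  p <- as_xyz_matrix(cluster, "cluster")
  if (nrow(v) == 0 || nrow(p) == 0) stop("both sets must be non-empty")
  mean(cpp_nn_dist(v, p) < threshold)
}

#' Rotation variants for hypotheses and detailed fitting
#'
#' The seven rotations evaluated as variants: the identity plus rotations
#' of `+/-angle` degrees about each coordinate axis, optionally composed
#' with a base rotation.
#'
#' @param base 3 x 3 base rotation the variants are composed onto.
#' @param angle rotation increment in degrees (default 10).
#' @return a list of 7 rotation matrices; the first is `base` itself.
#' @export
rotated_hypotheses <- function(base = diag(3), angle = 10) {
  out <- list(base)
  for (ax in 1:3) {
    for (sgn in c(1, -1)) {
      out[[length(out) + 1]] <- axis_rotation(ax, sgn * angle) %*% base
    }
  }
  out
}

axis_rotation <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
         matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, byrow = TRUE),
         matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, byrow = TRUE),
         matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Fraction of one mesh's vertices strictly inside another
#'
#' Inside/outside is decided by ray-crossing parity against the watertight
#' mesh `b`; vertices lying on `b`'s surface (within `surface_tol`) count as
#' not inside, so coincident meshes have an inside fraction of 0.
#'
#' @param a,b placed `component_mesh` objects; `b` must be watertight.
#' @param surface_tol on-surface tolerance.
#' @return fraction of `a`'s vertices strictly inside `b`.
#' @export
inside_fraction <- function(a, b, surface_tol = 1e-9) {
  wt <- is_watertight(b)
  if (!isTRUE(wt)) {
    stop(sprintf("mesh 'b' is not watertight: %s", attr(wt, "defect")))
  }
  mean(cpp_points_in_mesh(a$vertices, b$vertices, b$faces, surface_tol))
}

#' Inside-outside merge test for non-spherical components
#'
#' Two placed components are considered overlapping when more than
#' `merge_inside_percent`% of either one's vertices lie strictly inside the
#' other. The test is symmetric.
#'
#' @param a,b placed `component_mesh` objects.
#' @param cfg a [nonspherical_config()].
#' @return logical flag.
#' @export
nonspherical_merge_test <- function(a, b, cfg = nonspherical_config()) {
  max(inside_fraction(a, b), inside_fraction(b, a)) >
    cfg$merge_inside_percent / 100
}
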