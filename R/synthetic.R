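#' Generate a ground-truthed synthetic aggregate
#'
#' Places `n_components` near-spherical components by seeded sequential
#' rejection sampling around a central vertical axis, so that each new
#' component touches an already-placed neighbor (center distance drawn in
#' `[0.98, 1.02]` of the sum of effective radii) while no pair
#' interpenetrates beyond the `0.95 x sum-of-radii` tolerance. This emulates
#' the compact packing of a grape bunch without physical simulation.
#'
#' @param n_components number of components (>= 1).
#' @param radius_range length-2 positive range the base radius is drawn from
#'   (dimensionless; the pipeline later applies its own bounding-box
#'   normalization to any input cloud).
#' @param shape `"sphere"`, `"ellipsoid"` (one axis elongated by a factor in
#'   `[1.2, 1.4]`, randomly rotated), or `"deformed"` (sphere with a
#'   low-frequency radial bump field, amplitude 10% of the radius).
#' @param seed integer seed; the same seed reproduces the same aggregate.
#' @param noise_sd,occlusion_fraction,density_per_component stored sampling
#'   parameters used by [sample_surface()]: isotropic noise standard
#'   deviation, fraction of each component's surface removed as an occlusion
#'   cap, and surface sampling density in points per unit area.
#' @return a `ground_truth_aggregate`: list of components (each with
#'   `center`, `radii`, `rotation`, and for deformed shapes a `bump` field)
#'   plus the sampling parameters.
#' @export
generate_packing <- function(n_components, radius_range = c(0.08, 0.15),
                             shape = c("sphere", "ellipsoid", "deformed"),
                             seed = 1, noise_sd = 0.005,
                             occlusion_fraction = 0.2,
                             density_per_component = 10000) {
  shape <- match.arg(shape)
  if (n_components < 1) stop("'n_components' must be >= 1")
  if (radius_range[1] <= 0 || radius_range[1] > radius_range[2]) {
    stop("'radius_range' must satisfy 0 < min <= max")
  }
  comps <- with_seed(seed, {
    # one base radius per aggregate with +/-10% within-bunch variation:
    # components of one aggregate (berries of one bunch) are near-uniform
    # in size, while the base radius spans the configured range across
    # aggregates; every drawn radius stays inside radius_range
    r_lo <- radius_range[1] / 0.9
    r_hi <- radius_range[2] / 1.1
    if (r_lo > r_hi) r_lo <- r_hi <- mean(radius_range)  # narrow range
    r_base <- runif(1, r_lo, r_hi)
    make_component <- function() {
      r <- min(max(r_base * runif(1, 0.9, 1.1), radius_range[1]),
               radius_range[2])
      if (shape == "sphere") {
        list(center = c(0, 0, 0), radii = rep(r, 3), rotation = diag(3))
      } else if (shape == "ellipsoid") {
        radii <- c(r, r, r * runif(1, 1.2, 1.4))
        list(center = c(0, 0, 0), radii = radii,
             rotation = random_rotation())
      } else {
        list(center = c(0, 0, 0), radii = rep(r, 3), rotation = diag(3),
             bump = random_bump_field(amplitude = 0.1))
      }
    }
    eff_radius <- function(cmp) mean(cmp$radii)
    # columnar bunch: growth is biased down a central vertical axis with
    # the span proportional to the component size (a bunch of bigger
    # berries is itself bigger); once the span fills, the bunch thickens
    # sideways, like a grape bunch
    z_span_max <- 18 * r_base
    lat_max <- 6 * r_base
    comps <- list(make_component())
    while (length(comps) < n_components) {
      cand <- make_component()
      placed <- FALSE
      for (attempt in 1:500) {
        if (runif(1) < 0.7) {
          # grow the tip: anchor on one of the lowest-placed components
          z <- vapply(comps, function(cmp) cmp$center[3], 0)
          low <- order(z)[seq_len(min(3L, length(comps)))]
          anchor <- comps[[low[sample.int(length(low), 1)]]]
        } else {
          anchor <- comps[[sample.int(length(comps), 1)]]
        }
        dir <- c(rnorm(2, 0, 0.55), rnorm(1, -1.6, 0.55))
        dir <- dir / sqrt(sum(dir^2))
        gap <- runif(1, 0.98, 1.02)
        center <- anchor$center +
          dir * gap * (eff_radius(anchor) + eff_radius(cand))
        if (sqrt(sum(center[1:2]^2)) > lat_max) next
        zs <- c(vapply(comps, function(cmp) cmp$center[3], 0), center[3])
        if (diff(range(zs)) > z_span_max) next
        ok <- TRUE
        for (other in comps) {
          d <- sqrt(sum((center - other$center)^2))
          if (d < 0.95 * (eff_radius(cand) + eff_radius(other))) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          cand$center <- center
          comps[[length(comps) + 1]] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("packing failed after bounded retries; try fewer components")
      }
    }
    comps
  })
  structure(list(components = comps, shape = shape, noise_sd = noise_sd,
                 occlusion_fraction = occlusion_fraction,
                 density_per_component = density_per_component,
                 seed = seed),
            class = "ground_truth_aggregate")
}

#' @export
print.ground_truth_aggregate <- function(x, ...) {
  cat(sprintf("<ground_truth_aggregate: %d %s components>\n",
              length(x$components), x$shape))
  invisible(x)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_bump_field <- function(amplitude = 0.1, n_lobes = 5, sigma = 0.6) {
  dirs <- matrix(rnorm(3 * n_lobes), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  w <- runif(n_lobes, -1, 1)
  list(dirs = dirs, weights = w, sigma = sigma, amplitude = amplitude)
}

# radial perturbation factor (1 + bump) for unit directions u (n x 3)
bump_factor <- function(u, bump) {
  if (is.null(bump)) return(rep(1, nrow(u)))
  g <- u %*% t(bump$dirs)                   # cosine to each lobe axis
  val <- exp(-(1 - g) / bump$sigma) %*% bump$weights
  peak <- max(abs(val), 1e-12)
  1 + bump$amplitude * as.vector(val) / peak
}

# radius of a component along unit directions u in its local frame
component_radius <- function(cmp, u) {
  base <- sqrt(1 / rowSums(sweep(u, 2, cmp$radii, "/")^2))  # ellipsoid radius
  base * bump_factor(u, cmp$bump)
}

# TRUE for points strictly inside the component surface (scaled by shrink)
component_contains <- function(points, cmp, shrink = 1) {
  local <- sweep(points, 2, cmp$center) %*% cmp$rotation  # R^T (p - c)
  d <- sqrt(rowSums(local^2))
  u <- local / pmax(d, 1e-12)
  d < shrink * component_radius(cmp, u) - 1e-12
}

#' Sample an SfM-like point cloud from a synthetic aggregate
#'
#' Draws points uniformly on each component's surface, removes points that
#' fall inside a neighboring component (contact occlusion), removes a random
#' spherical-cap region covering `occlusion_fraction` of each component's
#' surface (camera occlusion), and finally adds isotropic Gaussian noise.
#' Contact occlusion is applied before the cap, which only matters for the
#' reported retention statistics.
#'
#' @param aggregate a [generate_packing()] result.
#' @param seed integer seed.
#' @return a list with `cloud` (a [point_cloud()] carrying a per-point
#'   `"component"` attribute), `truth` (the unchanged aggregate), and
#'   `retention` (per-component fraction of pre-occlusion points kept).
#' @export
sample_surface <- function(aggregate, seed = 1) {
  comps <- aggregate$components
  out <- with_seed(seed, {
    pts <- list()
    labels <- list()
    kept_frac <- numeric(length(comps))
    for (i in seq_along(comps)) {
      cmp <- comps[[i]]
      area <- ellipsoid_area(cmp$radii)
      n <- max(20L, round(aggregate$density_per_component * area))
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- component_radius(cmp, u)
      local <- u * r
      world <- sweep(local %*% t(cmp$rotation), 2, cmp$center, "+")
      # contact occlusion: drop points inside any other component
      keep <- rep(TRUE, n)
      for (j in seq_along(comps)) {
        if (j == i) next
        near <- sqrt(sum((cmp$center - comps[[j]]$center)^2)) <
          mean(cmp$radii) + max(comps[[j]]$radii) * 1.2
        if (near) keep <- keep & !component_contains(world, comps[[j]])
      }
      n_after_contact <- sum(keep)
      # cap occlusion: remove a random spherical cap of the surface
      f <- aggregate$occlusion_fraction
      if (f > 0) {
        axis <- rnorm(3)
        axis <- axis / sqrt(sum(axis^2))
        keep <- keep & (u %*% axis < 1 - 2 * f)
      }
      kept_frac[i] <- if (n_after_contact > 0) sum(keep) / n_after_contact else 0
      if (any(keep)) {
        pts[[length(pts) + 1]] <- world[keep, , drop = FALSE]
        labels[[length(labels) + 1]] <- rep(i, sum(keep))
      }
    }
    if (length(pts) == 0) stop("all sampled points were occluded")
    pos <- do.call(rbind, pts)
    if (aggregate$noise_sd > 0) {
      pos <- pos + matrix(rnorm(length(pos), sd = aggregate$noise_sd),
                          ncol = 3)
    }
    list(pos = pos, labels = unlist(labels), kept = kept_frac)
  })
  cloud <- point_cloud(out$pos)
  attr(cloud, "component") <- out$labels
  list(cloud = cloud, truth = aggregate, retention = out$kept)
}

# Thomsen's approximation (exact for spheres)
ellipsoid_area <- function(radii) {
  p <- 1.6075
  a <- radii[1]; b <- radii[2]; c <- radii[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' True component centers of an aggregate
#' @param aggregate a `ground_truth_aggregate`.
#' @return n x 3 matrix of centers.
#' @export
truth_centers <- function(aggregate) {
  do.call(rbind, lapply(aggregate$components, `[[`, "center"))
}

#' Write / read ground truth as JSON
#'
#' @param aggregate a `ground_truth_aggregate`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the aggregate (read).
#' @export
write_ground_truth <- function(aggregate, path) {
  obj <- list(
    shape = aggregate$shape,
    noise_sd = aggregate$noise_sd,
    occlusion_fraction = aggregate$occlusion_fraction,
    density_per_component = aggregate$density_per_component,
    seed = aggregate$seed,
    components = lapply(aggregate$components, function(cmp) {
      out <- list(center = cmp$center, radii = cmp$radii,
                  rotation = as.vector(cmp$rotation))
      if (!is.null(cmp$bump)) {
        out$bump <- list(dirs = as.vector(cmp$bump$dirs),
                         weights = cmp$bump$weights,
                         sigma = cmp$bump$sigma,
                         amplitude = cmp$bump$amplitude)
      }
      out
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  comps <- lapply(obj$components, function(rec) {
    cmp <- list(center = num(rec$center), radii = num(rec$radii),
                rotation = matrix(num(rec$rotation), 3, 3))
    if (!is.null(rec$bump)) {
      cmp$bump <- list(dirs = matrix(num(rec$bump$dirs), ncol = 3),
                       weights = num(rec$bump$weights),
                       sigma = num(rec$bump$sigma),
                       amplitude = num(rec$bump$amplitude))
    }
    cmp
  })
  structure(list(components = comps, shape = obj$shape,
                 noise_sd = obj$noise_sd,
                 occlusion_fraction = obj$occlusion_fraction,
                 density_per_component = obj$density_per_component,
                 seed = obj$seed),
            class = "ground_truth_aggregate")
}
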