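# internal helpers shared across modules

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Sub-seeds for independent stages (per hypothesis, per cluster, per merge
#' round) are derived by a fixed counter scheme so that adding hypotheses or
#' clusters does not shift unrelated random draws. The result is always a
#' valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param ... integer counters identifying the stage and index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  x <- as.numeric(master) %% m
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) * 7919 + 1) %% m
  }
  as.integer(x)
}

as_xyz_matrix <- function(x, arg = "points") {
  if (inherits(x, "point_cloud")) x <- x$positions
  if (inherits(x, "component_mesh")) x <- x$vertices
  if (is.null(dim(x))) {
    if (length(x) == 3) x <- matrix(x, nrow = 1) else
      stop(sprintf("'%s' must be an n x 3 matrix of coordinates", arg))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(sprintf("'%s' must have 3 columns", arg))
  storage.mode(x) <- "double"
  x
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name))
  }
}
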