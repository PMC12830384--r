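#' Optimal correspondence between true and recovered components
#'
#' One-to-one assignment minimizing the total center-to-center distance
#' (Hungarian algorithm); the smaller of the two sets is matched completely
#' and the surplus on the other side is reported as unmatched.
#'
#' @param truth a `ground_truth_aggregate` or n x 3 matrix of true centers.
#' @param found a list of `fitted_component`s or m x 3 matrix of recovered
#'   centers.
#' @return a data.frame with columns `truth`, `found` (indices), and
#'   `distance`, one row per matched pair, with attributes
#'   `unmatched_truth` and `unmatched_found`.
#' @export
match_components <- function(truth, found) {
  tc <- centers_of(truth)
  fc <- centers_of(found)
  n <- nrow(tc); m <- nrow(fc)
  if (n == 0 || m == 0) stop("both component sets must be non-empty")
  cost <- matrix(0, n, m)
  for (i in seq_len(n)) {
    cost[i, ] <- sqrt(colSums((t(fc) - tc[i, ])^2))
  }
  sq <- max(n, m)
  padded <- matrix(0, sq, sq)
  padded[seq_len(n), seq_len(m)] <- cost
  assign <- cpp_hungarian(padded)
  pairs <- data.frame(truth = seq_len(sq), found = assign)
  pairs <- pairs[pairs$truth <= n & pairs$found <= m, , drop = FALSE]
  pairs$distance <- cost[cbind(pairs$truth, pairs$found)]
  pairs <- pairs[order(pairs$truth), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "unmatched_truth") <- setdiff(seq_len(n), pairs$truth)
  attr(pairs, "unmatched_found") <- setdiff(seq_len(m), pairs$found)
  pairs
}

centers_of <- function(x) {
  if (inherits(x, "ground_truth_aggregate")) return(truth_centers(x))
  if (is.list(x) && !is.data.frame(x) && is.null(dim(x))) {
    return(do.call(rbind, lapply(x, function(cmp) {
      if (inherits(cmp, "fitted_component")) cmp$center
      else if (inherits(cmp, "fit_result")) cmp$sphere$center
      else as.numeric(cmp)
    })))
  }
  as_xyz_matrix(x, "centers")
}

#' Evaluate recovered components against ground truth
#'
#' Computes the recovered component count and the mean (`m_d`) and sample
#' standard deviation (`m_s`) of the matched center-to-center distances,
#' each normalized by the diagonal of the bounding box covering the entire
#' input model.
#'
#' @inheritParams match_components
#' @param diagonal bounding-box diagonal of the input (pre-normalization)
#'   model, used for normalization.
#' @return an `evaluation_report`: list with `n_true`, `n_found`, `m_d`,
#'   `m_s`, `matched` (the pair table), and `diagonal`.
#' @export
evaluate_components <- function(truth, found, diagonal) {
  stopifnot_scalar_pos(diagonal, "diagonal")
  pairs <- match_components(truth, found)
  if (nrow(pairs) == 0) stop("no matched components; metrics undefined")
  d <- pairs$distance / diagonal
  structure(list(n_true = nrow(centers_of(truth)),
                 n_found = nrow(centers_of(found)),
                 m_d = mean(d),
                 m_s = if (length(d) > 1) sd(d) else NA_real_,
                 matched = pairs, diagonal = diagonal),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Component recovery report\n")
  cat(sprintf("  N_e (true components)      : %d\n", x$n_true))
  cat(sprintf("  N_m (recovered components) : %d\n", x$n_found))
  cat(sprintf("  M_d (mean center distance) : %.6f\n", x$m_d))
  cat(sprintf("  M_s (sd center distance)   : %s\n",
              if (is.na(x$m_s)) "NA" else sprintf("%.6f", x$m_s)))
  cat(sprintf("  matched pairs: %d; unmatched truth: %d; unmatched found: %d\n",
              nrow(x$matched), length(attr(x$matched, "unmatched_truth")),
              length(attr(x$matched, "unmatched_found"))))
  invisible(x)
}
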