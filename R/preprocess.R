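# Distribution-aware preprocessing. The pipeline keeps two branches:
# the variance phenotype is computed on non-normalized log2 data (quantile
# normalization would erase distribution-level group differences by
# construction), while differential expression runs on quantile-normalized
# data.

#' Log2-transform a linear-scale expression matrix
#'
#' Each value is replaced by `log2(max(value, floor))`. Applying the
#' transform to an already-log2 matrix is an error (double-transform guard).
#'
#' @param x a linear-scale [expression_matrix()].
#' @param floor positive floor applied before taking logs; near-zero or
#'   negative summarized intensities are clamped to it. The number of floored
#'   cells is recorded in the `n_floored` attribute and reported via
#'   `message()`.
#' @return A log2-scale `expr_matrix`.
#' @export
log2_transform <- function(x, floor = 2^-4) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "linear") {
    stop("matrix is already on the log2 scale; refusing to double-transform")
  }
  if (!is.numeric(floor) || floor <= 0) stop("`floor` must be positive")
  n_floored <- sum(x$values < floor)
  if (n_floored > 0) {
    message(sprintf("log2_transform: floored %d cell(s) below %g",
                    n_floored, floor))
  }
  out <- expression_matrix(log2(pmax(x$values, floor)), "log2")
  attr(out, "n_floored") <- n_floored
  out
}

#' Present-call filter defining the analysis background
#'
#' Retains probes called present in at least (or more than, when
#' `inclusive = FALSE`) `min_present_samples` samples. The retained set is
#' the background universe for differential expression, list overlap, and
#' enrichment.
#'
#' @param presence logical presence matrix (probes x samples).
#' @param min_present_samples present-count threshold (default 50).
#' @param inclusive if `TRUE` (default) the threshold is "at least".
#' @return Character vector of retained probe ids, in input order.
#' @examples
#' calls <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
#'                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' present_filter(calls, min_present_samples = 1)
#' @export
present_filter <- function(presence, min_present_samples = 50,
                           inclusive = TRUE) {
  validate_presence(presence)
  if (min_present_samples < 0 || min_present_samples > ncol(presence)) {
    stop(sprintf(
      "min_present_samples (%d) must be between 0 and the sample count (%d)",
      min_present_samples, ncol(presence)
    ))
  }
  counts <- rowSums(presence)
  keep <- if (inclusive) counts >= min_present_samples else counts > min_present_samples
  rownames(presence)[keep]
}

#' Quantile normalization (rank-mean algorithm)
#'
#' Forces every sample's expression distribution to be identical: sort each
#' sample, average across samples at each rank, and re-assign the averaged
#' values by each sample's original ranks. Tied values within a sample
#' receive the mean of the reference values at the ranks they occupy, so the
#' result is deterministic and order-independent.
#'
#' After this operation the per-sample overall variance is constant across
#' samples, which is exactly why the variance phenotype must be computed on
#' non-normalized data.
#'
#' @param x an [expression_matrix()] with at least two samples.
#' @return An `expr_matrix` on the same scale with identical per-sample
#'   distributions.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (ncol(v) < 2) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(v, 2, sort))
  out <- v
  for (s in seq_len(ncol(v))) {
    y <- numeric(nrow(v))
    y[order(v[, s])] <- ref
    # ties: average the reference values over the occupied rank positions
    out[, s] <- stats::ave(y, v[, s], FUN = mean)
  }
  expression_matrix(out, x$scale)
}
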