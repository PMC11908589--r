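# Histogram representation of a pipeline.
#
# A pipeline is represented by one normalized histogram per nucleus
# feature. Feature values are first mapped to [0, 1] with shared
# normalization bounds (the min/max over all reference and validation
# data), binned into n_bin equal-width bins, and each column is divided
# by the number of in-range values so it sums to 1. Values falling
# outside the reference range are dropped before binning but still
# lower the in-range count, which is exactly how out-of-range drift
# shows up in the distances.

#' Per-feature normalization bounds
#'
#' Column-wise minimum and maximum over all supplied feature matrices.
#' These bounds anchor the `[0, 1]` scale on which every histogram is
#' built; in calibration they are computed over the union of reference
#' and validation matrices.
#'
#' @param matrices A feature matrix or list of feature matrices with
#'   identical column sets.
#' @return A `normalization_bounds` object with `lower`, `upper`,
#'   and a `degenerate` flag per feature (`lower == upper`).
#' @export
compute_bounds <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!is.list(matrices) || length(matrices) == 0L) {
    abort("`matrices` must be a non-empty feature matrix or list of them.")
  }
  ids <- colnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(colnames(m), ids)) {
      abort("All matrices must share identical feature columns in order.")
    }
  }
  lower <- do.call(pmin, lapply(matrices, function(m) apply(m, 2, min)))
  upper <- do.call(pmax, lapply(matrices, function(m) apply(m, 2, max)))
  structure(
    list(lower = lower, upper = upper,
         degenerate = lower == upper, feature_ids = ids),
    class = "normalization_bounds"
  )
}

#' Map a feature matrix to its normalized histogram representation
#'
#' Per feature `l`: values are rescaled by the bounds,
#' `(v - lower_l) / (upper_l - lower_l)`, values outside `[0, 1]` are
#' dropped, the rest are counted into `n_bin` equal-width, half-open
#' bins (the last bin closed so that the upper bound itself is counted),
#' and the column is divided by the retained count so it sums to 1.
#' A degenerate feature, or one whose values all fall out of range, is
#' represented by a uniform column and flagged with a warning — the
#' anomaly then surfaces as a QC signal rather than an error.
#'
#' @param C Numeric matrix, one row per nucleus, columns named by
#'   feature.
#' @param bounds A [compute_bounds()] object matching `C`'s columns.
#' @param n_bin Number of bins (default 100).
#' @return A `distribution_matrix`: an `n_bin x n_f` column-stochastic
#'   matrix with attributes `in_range_counts` and `uniform_cols`.
#' @export
to_distribution <- function(C, bounds, n_bin = 100L) {
  stopifnot(inherits(bounds, "normalization_bounds"))
  if (!is_count(n_bin) || n_bin < 2) abort("`n_bin` must be an integer >= 2.")
  n_bin <- as.integer(n_bin)
  if (!identical(colnames(C), bounds$feature_ids)) {
    abort("`C`'s feature columns do not match `bounds`.")
  }
  n_f <- ncol(C)
  out <- matrix(0, nrow = n_bin, ncol = n_f,
                dimnames = list(NULL, colnames(C)))
  in_range <- integer(n_f)
  uniform <- logical(n_f)
  for (l in seq_len(n_f)) {
    if (bounds$degenerate[l]) {
      out[, l] <- 1 / n_bin
      uniform[l] <- TRUE
      next
    }
    v <- (C[, l] - bounds$lower[l]) / (bounds$upper[l] - bounds$lower[l])
    v <- v[v >= 0 & v <= 1]
    in_range[l] <- length(v)
    if (length(v) == 0L) {
      out[, l] <- 1 / n_bin
      uniform[l] <- TRUE
      next
    }
    idx <- pmin(floor(v * n_bin) + 1L, n_bin)  # value 1.0 -> last bin
    out[, l] <- tabulate(idx, nbins = n_bin) / length(v)
  }
  if (any(uniform)) {
    warn(sprintf(
      "%d feature(s) degenerate or fully out of range; their histograms were set to uniform (%s).",
      sum(uniform),
      paste(head(colnames(C)[uniform], 5), collapse = ", ")),
      class = "slideqc_degenerate_feature")
  }
  structure(out, class = c("distribution_matrix", "matrix"),
            n_bin = n_bin, in_range_counts = in_range,
            uniform_cols = uniform)
}

#' Feature reduction matrix
#'
#' Encodes the assignment from the full feature set to a selected
#' subset as an ordered list of source-feature indices (the sparse form
#' of the 0/1 assignment matrix: each selected feature is one column
#' with a single 1).
#'
#' @param idx Integer indices of the selected source features (unique).
#' @param n_feat_in Total number of source features.
#' @param scores Optional per-selected-feature score (selection
#'   statistic), kept for reporting.
#' @return A `reduction_matrix` object.
#' @export
reduction_matrix <- function(idx, n_feat_in, scores = NULL) {
  idx <- as.integer(idx)
  assert_count(n_feat_in, "n_feat_in")
  if (anyDuplicated(idx) || any(idx < 1L | idx > n_feat_in)) {
    abort("`idx` must be unique indices in 1..n_feat_in.")
  }
  structure(list(idx = idx, n_feat_in = as.integer(n_feat_in),
                 scores = scores),
            class = "reduction_matrix")
}

#' Identity reduction (no feature selection)
#' @param n_feat Number of features.
#' @return A `reduction_matrix` selecting every feature in order.
#' @export
identity_reduction <- function(n_feat) {
  reduction_matrix(seq_len(n_feat), n_feat)
}

#' @export
print.reduction_matrix <- function(x, ...) {
  cat(sprintf("<reduction_matrix: %d of %d features>\n",
              length(x$idx), x$n_feat_in))
  invisible(x)
}

#' Apply a feature reduction
#'
#' Selects (and possibly permutes) the columns of a feature matrix or a
#' distribution matrix according to the assignment. Histogramming and
#' reduction commute: `to_distribution(apply_reduction(C, P))` equals
#' `apply_reduction(to_distribution(C), P)`.
#'
#' @param obj A feature matrix or `distribution_matrix`.
#' @param P A [reduction_matrix()] whose input dimension matches
#'   `obj`'s feature count.
#' @return The reduced object, same kind as the input.
#' @export
apply_reduction <- function(obj, P) {
  stopifnot(inherits(P, "reduction_matrix"))
  if (ncol(obj) != P$n_feat_in) {
    abort(sprintf("Reduction expects %d input features, object has %d columns.",
                  P$n_feat_in, ncol(obj)))
  }
  out <- obj[, P$idx, drop = FALSE]
  if (inherits(obj, "distribution_matrix")) {
    attr(out, "n_bin") <- attr(obj, "n_bin")
    attr(out, "in_range_counts") <- attr(obj, "in_range_counts")[P$idx]
    attr(out, "uniform_cols") <- attr(obj, "uniform_cols")[P$idx]
    class(out) <- class(obj)
  }
  out
}
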