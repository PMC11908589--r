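# Distances between feature distributions.
#
# Per-feature histogram distances, each bounded in [0, 1], aggregated
# over features into a single pipeline distance. The argmax feature of
# the per-feature distances is always reported: under the max
# aggregator the final distance is determined by a single feature,
# which is what makes the measure interpretable.

#' Distance specification
#'
#' @param omega Per-feature histogram distance: one of `"wasserstein"`,
#'   `"bhattacharyya"`, `"jensen_shannon"`.
#' @param aggregator Aggregation over features: one of `"max"`,
#'   `"mean"`, `"median"`.
#' @return A `distance_spec` object.
#' @export
distance_spec <- function(omega = c("wasserstein", "bhattacharyya",
                                    "jensen_shannon"),
                          aggregator = c("max", "mean", "median")) {
  structure(list(omega = match.arg(omega),
                 aggregator = match.arg(aggregator)),
            class = "distance_spec")
}

check_histogram_pair <- function(f, f2) {
  if (length(f) != length(f2)) {
    abort("Histograms must have the same number of bins.")
  }
  if (length(f) < 2L) abort("Histograms need at least 2 bins.")
}

#' 1-Wasserstein distance between binned distributions
#'
#' Earth mover's distance between two discrete distributions supported
#' on the bin centers of `[0, 1]`; computed as the mean absolute
#' difference of cumulative sums scaled by the bin width. Bounded by
#' `(n_bin - 1) / n_bin < 1`.
#'
#' @param f,f2 Column-stochastic histogram vectors of equal length.
#' @return A scalar in `[0, 1]`.
#' @export
dist_wasserstein <- function(f, f2) {
  check_histogram_pair(f, f2)
  sum(abs(cumsum(f - f2))) / length(f)
}

#' Bounded Bhattacharyya (Hellinger-form) distance
#'
#' `sqrt(1 - BC)` with Bhattacharyya coefficient
#' `BC = sum(sqrt(f * f2))`. The Hellinger form is used because the raw
#' `-log(BC)` divergence is unbounded while a `[0, 1]` codomain is
#' required for the weighted comparisons downstream.
#'
#' @inheritParams dist_wasserstein
#' @return A scalar in `[0, 1]`; 1 exactly for disjoint supports.
#' @export
dist_bhattacharyya <- function(f, f2) {
  check_histogram_pair(f, f2)
  bc <- sum(sqrt(f * f2))
  sqrt(max(0, 1 - min(bc, 1)))
}

#' Jensen-Shannon distance
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms,
#' a metric bounded by 1 (`0 * log 0` terms are 0).
#'
#' @inheritParams dist_wasserstein
#' @return A scalar in `[0, 1]`; 1 exactly for disjoint supports.
#' @export
dist_jensen_shannon <- function(f, f2) {
  check_histogram_pair(f, f2)
  m <- (f + f2) / 2
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / q[nz]))
  }
  jsd <- (kl(f, m) + kl(f2, m)) / 2
  sqrt(max(0, min(jsd, 1)))
}

omega_fun <- function(omega) {
  switch(omega,
         wasserstein = dist_wasserstein,
         bhattacharyya = dist_bhattacharyya,
         jensen_shannon = dist_jensen_shannon,
         abort(sprintf("Unknown omega '%s'.", omega)))
}

aggregate_fun <- function(aggregator) {
  switch(aggregator,
         max = max, mean = mean, median = median,
         abort(sprintf("Unknown aggregator '%s'.", aggregator)))
}

#' Distance between two pipeline representations
#'
#' Applies the per-feature histogram distance `omega` column by column
#' and aggregates with `g`. The feature attaining the maximum
#' per-feature distance is always reported (ties to the lowest index):
#' it is the drift attribution signal.
#'
#' @param F1,F2 `distribution_matrix` objects (or plain column-
#'   stochastic matrices) of identical shape and feature order.
#' @param spec A [distance_spec()].
#' @return A list of class `distance_result` with `value`,
#'   `per_feature` (named vector) and `argmax_feature`.
#' @export
distribution_distance <- function(F1, F2, spec = distance_spec()) {
  stopifnot(inherits(spec, "distance_spec"))
  if (!identical(dim(F1), dim(F2))) {
    abort("Distribution matrices must have identical shapes.")
  }
  if (!is.null(colnames(F1)) && !is.null(colnames(F2)) &&
      !identical(colnames(F1), colnames(F2))) {
    abort("Distribution matrices must share feature order.")
  }
  w <- omega_fun(spec$omega)
  per_feature <- vapply(seq_len(ncol(F1)),
                        function(l) w(F1[, l], F2[, l]), numeric(1))
  names(per_feature) <- colnames(F1)
  arg <- which.max(per_feature)
  structure(
    list(value = aggregate_fun(spec$aggregator)(per_feature),
         per_feature = per_feature,
         argmax_feature = if (!is.null(names(per_feature)))
           names(per_feature)[arg] else arg),
    class = "distance_result"
  )
}
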