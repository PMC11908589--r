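# Per-reference feature selection.
#
# Each reference pipeline gets its own reduction matrix, chosen by a
# one-versus-all binary problem on the stacked nuclei of all
# references: does this nucleus come from reference i or not? Two
# univariate selectors are provided: chi-squared scores on the
# min-max-normalized (hence non-negative) feature totals, and a greedy
# minimum-redundancy maximum-relevance scheme whose importance is the
# quotient of the F-statistic relevance by the mean absolute Pearson
# redundancy against already-selected features.

#' Stack per-reference feature matrices and min-max normalize
#'
#' Rows are stacked in reference order and each column is min-max
#' normalized over all stacked rows. A constant column is mapped to all
#' zeros with a warning. One-versus-all labels are recoverable from the
#' stored per-row reference identifiers.
#'
#' @param feature_matrices Named list, one feature matrix per reference.
#' @return A `stacked_training_set` with `X_norm`, `ref_of_row`,
#'   `references` and `constant_cols`.
#' @export
stack_and_normalize <- function(feature_matrices) {
  if (!is.list(feature_matrices) || length(feature_matrices) < 2L) {
    abort("`feature_matrices` must be a list with one matrix per reference (>= 2).")
  }
  if (is.null(names(feature_matrices)) || anyDuplicated(names(feature_matrices))) {
    abort("`feature_matrices` must carry unique reference names.")
  }
  ids <- colnames(feature_matrices[[1]])
  for (m in feature_matrices) {
    if (!identical(colnames(m), ids)) {
      abort("All feature matrices must share identical columns in order.")
    }
  }
  X <- do.call(rbind, feature_matrices)
  ref_of_row <- rep(names(feature_matrices),
                    vapply(feature_matrices, nrow, integer(1)))
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  constant <- span == 0
  span[constant] <- 1
  X_norm <- sweep(sweep(X, 2, lo, "-"), 2, span, "/")
  X_norm[, constant] <- 0
  if (any(constant)) {
    warn(sprintf("%d constant feature column(s) normalized to zero (%s).",
                 sum(constant),
                 paste(head(ids[constant], 5), collapse = ", ")))
  }
  structure(
    list(X_norm = X_norm, ref_of_row = ref_of_row,
         references = names(feature_matrices), constant_cols = constant),
    class = "stacked_training_set"
  )
}

# Chi-squared score of non-negative per-class feature totals against a
# binary label: observed totals per class vs totals expected under the
# class priors, one degree of freedom.
chi2_scores <- function(X, y) {
  n <- nrow(X)
  p1 <- mean(y)
  obs1 <- colSums(X[y, , drop = FALSE])
  tot <- colSums(X)
  obs0 <- tot - obs1
  exp1 <- tot * p1
  exp0 <- tot * (1 - p1)
  stat <- ifelse(tot > 0,
                 (obs1 - exp1)^2 / pmax(exp1, .Machine$double.eps) +
                   (obs0 - exp0)^2 / pmax(exp0, .Machine$double.eps),
                 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p)
}

# Two-group one-way ANOVA F statistic per column.
f_scores <- function(X, y) {
  n <- nrow(X)
  n1 <- sum(y); n0 <- n - n1
  m1 <- colSums(X[y, , drop = FALSE]) / n1
  m0 <- colSums(X[!y, , drop = FALSE]) / n0
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  sst <- colSums(sweep(X, 2, m, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  msw <- ssw / (n - 2)
  ifelse(msw > 0, ssb / msw, ifelse(ssb > 0, Inf, 0))
}

#' Chi-squared one-versus-all feature selection
#'
#' Scores every feature's non-negative totals against the binary
#' "comes from reference `reference_id`" label with a chi-squared
#' statistic and retains the `n_sel` features with the lowest p-values
#' (ties broken by ascending feature index).
#'
#' @param set A [stack_and_normalize()] result.
#' @param reference_id Reference whose one-versus-all labels to use.
#' @param n_sel Number of features to retain (`<= n_feat`).
#' @return A [reduction_matrix()].
#' @export
select_chi2 <- function(set, reference_id, n_sel) {
  stopifnot(inherits(set, "stacked_training_set"))
  n_feat <- ncol(set$X_norm)
  assert_count(n_sel, "n_sel")
  if (n_sel > n_feat) abort("`n_sel` cannot exceed the feature count.")
  if (!reference_id %in% set$references) {
    abort(sprintf("Unknown reference '%s'.", reference_id))
  }
  y <- set$ref_of_row == reference_id
  sc <- chi2_scores(set$X_norm, y)
  ord <- order(sc$p, seq_len(n_feat))
  keep <- ord[seq_len(n_sel)]
  reduction_matrix(keep, n_feat, scores = sc$stat[keep])
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection: the first feature maximizes the
#' F-statistic against the one-versus-all label; each subsequent step
#' picks the feature maximizing `F(l) / mean(|cor(l, s)|)` over features
#' `s` already selected (redundancy floored to avoid division by zero on
#' uncorrelated candidates). Ties break by ascending feature index.
#'
#' @inheritParams select_chi2
#' @return A [reduction_matrix()] listing features in selection order.
#' @export
select_mrmr <- function(set, reference_id, n_sel) {
  stopifnot(inherits(set, "stacked_training_set"))
  n_feat <- ncol(set$X_norm)
  assert_count(n_sel, "n_sel")
  if (n_sel > n_feat) abort("`n_sel` cannot exceed the feature count.")
  if (!reference_id %in% set$references) {
    abort(sprintf("Unknown reference '%s'.", reference_id))
  }
  y <- set$ref_of_row == reference_id
  relevance <- f_scores(set$X_norm, y)

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(n_feat)
  # Correlations computed lazily against the growing selected set.
  abs_cor_sum <- numeric(n_feat)
  while (length(selected) < n_sel) {
    if (length(selected) == 0L) {
      importance <- relevance
    } else {
      redundancy <- pmax(abs_cor_sum[remaining] / length(selected), 1e-12)
      importance <- rep(-Inf, n_feat)
      importance[remaining] <- relevance[remaining] / redundancy
    }
    cand <- if (length(selected) == 0L) remaining else remaining
    best <- cand[which.max(importance[cand])]  # which.max: first max, asc. index
    selected <- c(selected, best)
    scores <- c(scores, importance[best])
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0L) {
      cc <- suppressWarnings(
        abs(cor(set$X_norm[, remaining, drop = FALSE],
                set$X_norm[, best])))
      cc[is.na(cc)] <- 0  # constant columns carry no redundancy signal
      abs_cor_sum[remaining] <- abs_cor_sum[remaining] + as.numeric(cc)
    }
  }
  reduction_matrix(selected, n_feat, scores = scores)
}
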