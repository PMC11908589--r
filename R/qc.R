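# Scoring an input batch against a calibrated module.
#
# A batch S is encoded by a signed, weighted distance to every
# reference: d_j(S) = d(R_j, f(phi(S)) P_j) / alpha_j - 1, negative
# exactly when S sits inside reference j's weight. Compatibility with a
# tested reference i is the fraction of constraints satisfied (d_i < 0,
# d_j >= 0 for j != i); quality blends closeness to i with remoteness
# from the others through the balancing coefficient beta.

#' Signed weighted distance vector of a batch
#'
#' Represents the batch under the module bounds and each reference's
#' reduction, computes the distribution distance to each reference and
#' rescales it by the reference weight: `d_j = raw / alpha_j - 1`,
#' with values in `[-1, 1/alpha_j - 1]`.
#'
#' @param S A `wsi_batch` to score (all of its WSIs are used; the
#'   per-WSI nucleus quota is `floor(n_nuc / n_wsi)`).
#' @param module A calibrated [calibrate()] module.
#' @param seed Optional seed for nuclei sampling; defaults to the
#'   module's calibration seed.
#' @return A tibble with one row per reference: `reference`, `raw`,
#'   `alpha`, `d`, `argmax_feature`.
#' @export
distance_vector <- function(S, module, seed = NULL) {
  stopifnot(inherits(module, "qc_module"))
  if (any(module$alpha == 0)) {
    abort("Module has a zero reference weight; recalibrate or merge references.")
  }
  params <- module$params
  spec_seed <- seed %||% params$seed
  spec <- params_to_selection_spec(params, seed = spec_seed)
  C <- extract_feature_matrix(S, spec)
  F_S <- to_distribution(C, module$bounds, module$n_bin)
  rows <- lapply(seq_along(module$references), function(j) {
    ref <- module$references[[j]]
    res <- distribution_distance(ref$R, apply_reduction(F_S, ref$P),
                                 module$distance_spec)
    tibble(reference = ref$id, raw = res$value, alpha = ref$alpha,
           d = res$value / ref$alpha - 1,
           argmax_feature = res$argmax_feature)
  })
  dplyr::bind_rows(rows)
}

#' Compatibility of a batch with a tested reference
#'
#' Fraction of the `n_ref` constraints satisfied: the tested
#' reference's signed distance is negative (similarity) and every other
#' signed distance is non-negative (dissimilarity). A batch is
#' compatible when the fraction is exactly 1.
#'
#' @param d Numeric vector of signed weighted distances.
#' @param i Index of the tested reference in `d`.
#' @return A scalar in `{0, 1/n_ref, ..., 1}`.
#' @export
compatibility <- function(d, i) {
  n <- length(d)
  if (i < 1 || i > n) abort("`i` must index a reference.")
  (sum(d[i] < 0) + sum(d[-i] >= 0)) / n
}

#' Quality of a batch for a tested reference
#'
#' `Q = beta * Q_r + (1 - beta) * Q_rbar`, where
#' `Q_r = max(0, -d_i)` rewards closeness to the tested reference and
#' `Q_rbar = mean over j != i of (alpha_j / (1 - alpha_j)) * max(0, d_j)`
#' rewards remoteness from the others (each term bounded by 1 because
#' `d_j <= 1/alpha_j - 1`). `Q` is 0 exactly when no constraint is
#' satisfied.
#'
#' @param d Numeric vector of signed weighted distances.
#' @param i Index of the tested reference.
#' @param alphas Reference weights, in `(0, 1)` (a weight of exactly 1
#'   makes the dissimilarity coefficient undefined and is rejected).
#' @param beta Balancing coefficient in `[0, 1]`.
#' @return A list with `Q`, `Q_similar`, `Q_dissimilar`.
#' @export
quality <- function(d, i, alphas, beta) {
  n <- length(d)
  if (length(alphas) != n) abort("`alphas` must match `d` in length.")
  if (i < 1 || i > n) abort("`i` must index a reference.")
  if (beta < 0 || beta > 1) abort("`beta` must be in [0, 1].")
  if (any(alphas[-i] >= 1)) {
    abort("A reference weight of 1 (or more) makes the dissimilarity coefficient undefined; module invalid.")
  }
  if (any(alphas <= 0)) {
    abort("Reference weights must be positive; module invalid.")
  }
  q_r <- max(0, -d[i])
  coef <- alphas[-i] / (1 - alphas[-i])
  q_rbar <- mean(coef * pmax(0, d[-i]))
  list(Q = beta * q_r + (1 - beta) * q_rbar,
       Q_similar = q_r, Q_dissimilar = q_rbar)
}

#' Score a batch against a calibrated module
#'
#' Computes the distance vector once, then the compatibility and
#' quality for the tested reference (or for every reference when none
#' is given).
#'
#' @inheritParams distance_vector
#' @param reference Identifier of the tested reference; `NULL` scores
#'   every reference.
#' @param batch_id Optional label attached to the report rows.
#' @return A `qc_report` tibble, one row per tested reference:
#'   `batch_id`, `reference`, `compatibility`, `quality`,
#'   `quality_similar`, `quality_dissimilar`, `d`, `argmax_feature`.
#'   The full distance vector is attached as attribute
#'   `"distance_vector"`.
#' @export
qc_batch <- function(S, module, reference = NULL, seed = NULL,
                     batch_id = attr(S, "pipeline_id") %||% "batch") {
  dv <- distance_vector(S, module, seed = seed)
  tested <- if (is.null(reference)) module$ref_ids else reference
  idx <- match(tested, module$ref_ids)
  if (anyNA(idx)) {
    abort(sprintf("Unknown reference '%s'.", tested[is.na(idx)][1]))
  }
  rows <- lapply(idx, function(i) {
    q <- quality(dv$d, i, dv$alpha, module$beta)
    tibble(batch_id = batch_id, reference = module$ref_ids[i],
           compatibility = compatibility(dv$d, i),
           quality = q$Q, quality_similar = q$Q_similar,
           quality_dissimilar = q$Q_dissimilar,
           d = dv$d[i], argmax_feature = dv$argmax_feature[i])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "distance_vector") <- dv
  class(out) <- unique(c("qc_report", class(out)))
  out
}

#' Best-reference assignment of a batch
#'
#' Among references with compatibility exactly 1, returns the one with
#' maximal quality (ties to the lowest reference index). When no
#' reference is compatible the batch represents an unknown preparation:
#' an explicit alert is raised and the assignment is `NA` — a new
#' reference should be integrated into the module.
#'
#' @inheritParams distance_vector
#' @return A list with `assigned` (reference id or `NA`), `quality`,
#'   `compatible` (ids with compatibility 1) and the per-reference
#'   `report`.
#' @export
best_reference <- function(S, module, seed = NULL) {
  rep <- qc_batch(S, module, reference = NULL, seed = seed)
  ok <- which(rep$compatibility == 1)
  if (length(ok) == 0L) {
    qc_alert("No reference is compatible with this batch; a new reference should be integrated into the QC module.",
             code = "no_compatible_reference")
    return(list(assigned = NA_character_, quality = NA_real_,
                compatible = character(0), report = rep))
  }
  best <- ok[which.max(rep$quality[ok])]
  list(assigned = rep$reference[best], quality = rep$quality[best],
       compatible = rep$reference[ok], report = rep)
}

#' Score a WSI stream in contiguous batches
#'
#' Cuts the stream into contiguous, non-overlapping batches of `n_wsi`
#' WSIs (in order of first appearance; a trailing remainder is dropped
#' with a warning) and scores each against the module.
#'
#' @param stream A `wsi_batch` holding the stream's nuclei rows.
#' @param module A calibrated module.
#' @param reference Tested reference id; `NULL` scores all references
#'   per batch.
#' @param n_wsi Batch size in WSIs (defaults to the module's
#'   calibrated `n_wsi`).
#' @param seed Base seed; each batch uses a derived seed.
#' @return A `qc_stream` tibble: the per-batch [qc_batch()] rows with a
#'   `batch_index` column.
#' @export
qc_stream <- function(stream, module, reference = NULL,
                      n_wsi = module$params$n_wsi, seed = NULL) {
  ids <- wsi_ids_in_order(stream)
  n_batches <- length(ids) %/% n_wsi
  if (n_batches == 0L) {
    abort(sprintf("Stream has %d WSIs, fewer than one batch of %d.",
                  length(ids), n_wsi))
  }
  dropped <- length(ids) - n_batches * n_wsi
  if (dropped > 0L) {
    warn(sprintf("Trailing remainder of %d WSI(s) dropped (batches of %d).",
                 dropped, n_wsi))
  }
  base_seed <- seed %||% module$params$seed
  out <- lapply(seq_len(n_batches), function(b) {
    keep_ids <- ids[((b - 1L) * n_wsi + 1L):(b * n_wsi)]
    sub <- stream[stream$wsi_id %in% keep_ids, , drop = FALSE]
    sub <- restore_batch_attrs(sub, stream)
    rep <- qc_batch(sub, module, reference = reference,
                    seed = derive_seed(base_seed, b),
                    batch_id = sprintf("batch_%03d", b))
    rep$batch_index <- b
    rep
  })
  out <- dplyr::bind_rows(out)
  class(out) <- unique(c("qc_stream", class(out)))
  out
}
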