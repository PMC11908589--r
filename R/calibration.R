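# Calibration of the QC module.
#
# Each reference pipeline i is represented by a tuple (R_i, P_i,
# alpha_i): its histogram representation under its own reduction
# matrix, and a weight alpha_i — the distance at which a pipeline is
# deemed dissimilar from i. Weights are set by opposing every reference
# to a validation set of pipelines with matching characteristics:
# alpha_i is the smallest distance from R_i to any foreign validation
# pipeline, so the dissimilarity constraint holds for every validation
# batch by construction. Whether each reference's own validation batch
# falls inside its weight (the diagonal constraint) is what calibration
# can fail, and is reported.

# Extract feature matrices for a list of batches under shared selection
# parameters; one derived seed per batch for independent sampling.
extract_cohort <- function(batches, params, seed_offset = 0L) {
  lapply(seq_along(batches), function(i) {
    b <- batch_head(batches[[i]], params$n_wsi)
    spec <- params_to_selection_spec(
      params, seed = derive_seed(params$seed, seed_offset + i))
    extract_feature_matrix(b, spec)
  })
}

ref_ids_of <- function(batches) {
  ids <- names(batches)
  if (is.null(ids)) {
    ids <- vapply(seq_along(batches), function(i) {
      attr(batches[[i]], "pipeline_id") %||% sprintf("reference_%d", i)
    }, character(1))
  }
  if (anyDuplicated(ids)) abort("Reference identifiers must be unique.")
  ids
}

#' Reference weights from a cross-distance matrix
#'
#' `alpha_i = min over j != i of D[i, j]`, where `D[i, j]` is the
#' distance between reference representation `i` and validation
#' pipeline `j` represented under reference `i`'s reduction. When merge
#' groups are supplied, distances between members of the same group are
#' excluded from the minimum (merged pipelines are one entity). A zero
#' weight means two pipelines are indistinguishable and raises a
#' calibration alert.
#'
#' @param D Square cross-distance matrix (rows: references, columns:
#'   validation pipelines, matched order).
#' @param merge_groups Optional list of integer index vectors to treat
#'   as single entities.
#' @return Numeric vector of weights.
#' @export
compute_weights <- function(D, merge_groups = NULL) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 2L) {
    abort("`D` must be a square matrix with at least 2 references.")
  }
  n <- nrow(D)
  group_of <- seq_len(n)
  if (!is.null(merge_groups)) {
    for (k in seq_along(merge_groups)) {
      g <- as.integer(merge_groups[[k]])
      if (any(g < 1L | g > n)) abort("Merge group indexes a missing reference.")
      group_of[g] <- n + k
    }
  }
  alpha <- vapply(seq_len(n), function(i) {
    foreign <- which(group_of != group_of[i])
    if (length(foreign) == 0L) {
      abort("A merge group swallows every reference; no foreign pipeline remains.")
    }
    min(D[i, foreign])
  }, numeric(1))
  if (any(alpha == 0)) {
    qc_alert(sprintf(
      "Zero reference weight for %s: two pipelines are indistinguishable.",
      paste(which(alpha == 0), collapse = ", ")),
      code = "alpha_zero")
  }
  alpha
}

#' Calibrate a QC module from reference and validation batches
#'
#' Executes the calibration stages in order: nuclei extraction for
#' every batch, normalization bounds over all reference and validation
#' matrices jointly, per-reference one-versus-all feature selection
#' over the stacked reference nuclei, reference representations,
#' cross-distances and weights. The diagonal constraint — each
#' reference's own validation batch closer than its weight — is checked
#' and any violation raises a QC alert (the preparation, or the
#' reference set, should be reconsidered); calibration still completes
#' so the report can be inspected.
#'
#' @param ref_batches Named list of `wsi_batch`, one per reference.
#' @param val_batches Named list of `wsi_batch`, one per reference, in
#'   matching order (`n_val = n_ref`); validation pipeline `i` must
#'   share reference `i`'s characteristics.
#' @param params A [param_combination()].
#' @param beta Balancing coefficient in `[0, 1]` between similarity to
#'   the tested reference and dissimilarity from the others in the
#'   quality measure (default 0.7).
#' @param n_bin Histogram bin count (default 100).
#' @return A `qc_module` with per-reference tuples, bounds, the
#'   cross-distance matrix `D`, weights, and the diagonal report.
#' @export
calibrate <- function(ref_batches, val_batches, params, beta = 0.7,
                      n_bin = 100L) {
  stopifnot(inherits(params, "param_combination"))
  if (length(ref_batches) != length(val_batches)) {
    abort("Need exactly one validation batch per reference (n_val = n_ref).")
  }
  if (length(ref_batches) < 2L) abort("At least 2 references are required.")
  if (beta < 0 || beta > 1) abort("`beta` must be in [0, 1].")

  ids <- ref_ids_of(ref_batches)
  ref_mats <- extract_cohort(ref_batches, params, seed_offset = 0L)
  val_mats <- extract_cohort(val_batches, params, seed_offset = 1000L)
  names(ref_mats) <- ids
  calibrate_from_matrices(ref_mats, val_mats, ids, params, beta, n_bin)
}

# Core calibration once feature matrices are extracted; shared with the
# grid search, which caches extractions across combinations.
calibrate_from_matrices <- function(ref_mats, val_mats, ids, params,
                                    beta, n_bin) {
  n_ref <- length(ref_mats)
  bounds <- compute_bounds(c(ref_mats, val_mats))
  spec <- distance_spec(params$omega, params$aggregator)

  if (params$sel_method == "none") {
    reductions <- replicate(n_ref, identity_reduction(ncol(ref_mats[[1]])),
                            simplify = FALSE)
  } else {
    train <- stack_and_normalize(ref_mats)
    selector <- switch(params$sel_method,
                       chi2 = select_chi2, mrmr = select_mrmr)
    reductions <- lapply(ids, function(id) {
      selector(train, id, params$n_sel)
    })
  }

  F_ref <- lapply(ref_mats, to_distribution, bounds = bounds, n_bin = n_bin)
  F_val <- lapply(val_mats, to_distribution, bounds = bounds, n_bin = n_bin)
  R <- lapply(seq_len(n_ref), function(i) {
    apply_reduction(F_ref[[i]], reductions[[i]])
  })

  D <- matrix(NA_real_, n_ref, n_ref, dimnames = list(ids, ids))
  for (i in seq_len(n_ref)) {
    for (j in seq_len(n_ref)) {
      D[i, j] <- distribution_distance(
        R[[i]], apply_reduction(F_val[[j]], reductions[[i]]), spec)$value
    }
  }

  alerts <- character(0)
  alpha <- withCallingHandlers(
    compute_weights(D),
    slideqc_alert = function(w) {
      alerts <<- c(alerts, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(alpha >= 1)) {
    msg <- sprintf(
      "Saturated reference weight (alpha = 1) for %s: the quality measure's dissimilarity coefficient is undefined for this module.",
      paste(ids[alpha >= 1], collapse = ", "))
    alerts <- c(alerts, msg)
    qc_alert(msg, code = "alpha_saturated")
  }
  diagonal_ok <- diag(D) < alpha
  if (!all(diagonal_ok)) {
    bad <- ids[!diagonal_ok]
    msg <- sprintf(
      "Diagonal quality constraint violated for %s: the preparation (or the reference set) should be reconsidered.",
      paste(bad, collapse = ", "))
    alerts <- c(alerts, msg)
    qc_alert(msg, code = "diagonal_violation")
  }
  if (any(alpha == 0)) {
    qc_alert(alerts[1], code = "alpha_zero")  # re-signal after capture
  }

  references <- lapply(seq_len(n_ref), function(i) {
    list(id = ids[i], R = R[[i]], P = reductions[[i]], alpha = alpha[i],
         diagonal_distance = D[i, i], diagonal_ok = diagonal_ok[i])
  })
  names(references) <- ids
  structure(
    list(references = references, ref_ids = ids, bounds = bounds,
         n_bin = as.integer(n_bin), distance_spec = spec, params = params,
         beta = beta, D = D, alpha = setNames(alpha, ids),
         merge_groups = NULL, alerts = alerts),
    class = "qc_module"
  )
}

#' @export
print.qc_module <- function(x, ...) {
  cat(sprintf("<qc_module: %d references, omega=%s, g=%s, n_bin=%d, beta=%.2f>\n",
              length(x$references), x$distance_spec$omega,
              x$distance_spec$aggregator, x$n_bin, x$beta))
  cat("  weights:",
      paste(sprintf("%s=%.4f", x$ref_ids, x$alpha), collapse = ", "), "\n")
  if (length(x$alerts) > 0) {
    cat("  ALERTS:\n")
    for (a in x$alerts) cat("   -", a, "\n")
  }
  invisible(x)
}

#' Merge references into a single entity for weighting
#'
#' When two references are near-clones (for instance two pipelines
#' differing only in a very similar coloration), their mutual distance
#' drives both weights toward zero and no batch can satisfy the
#' dissimilarity constraints. Merging treats the named references as
#' one entity in the weight minimum: their mutual distances are
#' excluded and each member's weight becomes its distance to the
#' nearest non-member. Representations are unchanged.
#'
#' @param module A calibrated `qc_module`.
#' @param ids Two or more reference identifiers (or indices) to merge.
#' @return The module with recomputed weights and the merge recorded.
#' @export
merge_references <- function(module, ids) {
  stopifnot(inherits(module, "qc_module"))
  if (is.character(ids)) {
    idx <- match(ids, module$ref_ids)
    if (anyNA(idx)) {
      abort(sprintf("Unknown reference id(s): %s.",
                    paste(ids[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(ids)
    if (any(idx < 1L | idx > length(module$ref_ids))) {
      abort("Reference index out of range.")
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) < 2L) abort("Merging needs at least 2 references.")
  if (length(idx) == length(module$ref_ids)) {
    abort("Cannot merge all references: no foreign pipeline would remain.")
  }
  groups <- c(module$merge_groups, list(idx))
  alpha <- compute_weights(module$D, merge_groups = groups)
  module$merge_groups <- groups
  module$alpha <- setNames(alpha, module$ref_ids)
  for (i in seq_along(module$references)) {
    module$references[[i]]$alpha <- alpha[i]
    module$references[[i]]$diagonal_ok <- module$D[i, i] < alpha[i]
  }
  module
}
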