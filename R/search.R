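# Grid-search validation of the QC-module parameters.
#
# The searched space is the Cartesian product of the Table-of-tested-
# parameters values under two conventions: the nuclei-selection
# composition enumerates the interior-filter options (absent, two tau
# values) crossed with the stratified sampler (off/on), the empty
# composition being a legal value (plain random sampling); and the
# feature-selection configurations are the two methods crossed with
# the finite n_sel values, plus the single no-selection configuration
# (all features, identity reduction). With one seed this enumerates
# 3 * 3 * 6 * 3 * 3 * 9 = 4374 combinations on the default grid.

#' Feature-selection configurations of a grid
#'
#' Enumerates the configurations of the feature-selection stage: every
#' method crossed with every `n_sel` value (including `"all"`), then
#' collapses the method-indifferent `"all"` rows into the single
#' no-selection configuration used by the search.
#'
#' @param methods Feature-selection methods (default chi2, mrmr).
#' @param n_sel_values Finite `n_sel` values (default 10, 20, 50, 100);
#'   `"all"` is always included.
#' @return A tibble of collapsed configurations (`sel_method`,
#'   `n_sel`), with the pre-collapse count in attribute
#'   `"n_raw_configs"`.
#' @export
feature_selection_configs <- function(methods = c("chi2", "mrmr"),
                                      n_sel_values = c(10L, 20L, 50L, 100L)) {
  raw <- tidyr::crossing(sel_method = methods,
                         n_sel = c(n_sel_values, NA_integer_))
  collapsed <- dplyr::bind_rows(
    tidyr::crossing(sel_method = methods, n_sel = n_sel_values),
    tibble(sel_method = "none", n_sel = NA_integer_)
  )
  attr(collapsed, "n_raw_configs") <- nrow(raw)
  collapsed
}

#' Enumerate the validation grid
#'
#' Builds the full set of parameter combinations searched by
#' validation, as a tibble with one row per combination and one column
#' per parameter (plus the composite `nuc_selection` label used in
#' frequency counts). A single seed is used for the whole grid; seed
#' variability is explored later by the refinement step.
#'
#' @param n_wsi,n_nuc Value lists for the representation stage
#'   (defaults 10/20/30 WSIs and 1e3/1e4/1e5 nuclei).
#' @param intern_tau Interior-filter options; `NA` is "absent"
#'   (defaults NA, 0.2, 0.4).
#' @param use_distrib Stratified-sampler options (defaults off, on).
#' @param omega,aggregator Measure-stage value lists.
#' @param sel_methods,n_sel_values Feature-stage value lists, expanded
#'   by [feature_selection_configs()].
#' @param seed The single grid seed.
#' @return A tibble of combinations in enumeration order.
#' @export
enumerate_grid <- function(n_wsi = c(10L, 20L, 30L),
                           n_nuc = c(1e3, 1e4, 1e5),
                           intern_tau = c(NA, 0.2, 0.4),
                           use_distrib = c(FALSE, TRUE),
                           omega = c("wasserstein", "bhattacharyya",
                                     "jensen_shannon"),
                           aggregator = c("max", "mean", "median"),
                           sel_methods = c("chi2", "mrmr"),
                           n_sel_values = c(10L, 20L, 50L, 100L),
                           seed = 1L) {
  fs <- feature_selection_configs(sel_methods, n_sel_values)
  grid <- tidyr::crossing(
    n_wsi = as.integer(n_wsi), n_nuc = as.integer(n_nuc),
    tidyr::crossing(intern_tau = as.numeric(intern_tau),
                    use_distrib = use_distrib),
    omega = omega, aggregator = aggregator, fs, seed = as.integer(seed)
  )
  grid$nuc_selection <- mapply(nuc_selection_label,
                               grid$intern_tau, grid$use_distrib)
  grid$combination <- seq_len(nrow(grid))
  grid
}

#' Convert a grid row to a parameter combination
#'
#' @param row A one-row tibble from [enumerate_grid()] (or a search
#'   result set).
#' @param seed Optional seed overriding the row's.
#' @return A [param_combination()].
#' @export
grid_row_to_params <- function(row, seed = NULL) {
  param_combination(
    n_wsi = row$n_wsi, n_nuc = row$n_nuc, intern_tau = row$intern_tau,
    use_distrib = row$use_distrib, omega = row$omega,
    aggregator = row$aggregator, sel_method = row$sel_method,
    n_sel = row$n_sel, seed = seed %||% row$seed)
}

#' Validation accuracy of a calibrated module
#'
#' Fraction of references whose own validation batch satisfies the
#' diagonal quality constraint (distance below the reference weight).
#' The cross constraints hold by construction of the weights, so the
#' module is valid — every validation pipeline compatible with its
#' reference — exactly when the accuracy is 1.
#'
#' @param module A calibrated `qc_module` (its stored cross-distance
#'   matrix comes from the calibration validation batches).
#' @return A scalar in `[0, 1]`.
#' @export
validation_accuracy <- function(module) {
  stopifnot(inherits(module, "qc_module"))
  mean(diag(module$D) < module$alpha)
}

#' Validation error of a calibrated module
#'
#' One minus the worst normalized margin by which a diagonal distance
#' undercuts the foreign distances: columns of the cross-distance
#' matrix are min-max normalized, and the error is
#' `1 - min over i of min over j != i of (Dn[i, j] - Dn[i, i])`.
#' Smaller is better; it ranks valid modules by how much slack their
#' constraints have. A degenerate column (all distances equal) is set
#' to zeros with a warning.
#'
#' @inheritParams validation_accuracy
#' @return A scalar (typically in `[0, 2]`; `<= 1` when every diagonal
#'   is column-minimal).
#' @export
validation_error <- function(module) {
  stopifnot(inherits(module, "qc_module"))
  normalized_margin_error(module$D)
}

# Error from a raw cross-distance matrix; split out for direct testing.
normalized_margin_error <- function(D) {
  n <- nrow(D)
  lo <- apply(D, 2, min)
  hi <- apply(D, 2, max)
  span <- hi - lo
  degen <- span == 0
  if (any(degen)) {
    warn(sprintf("%d degenerate column(s) in the distance matrix normalized to zero.",
                 sum(degen)))
    span[degen] <- 1
  }
  Dn <- sweep(sweep(D, 2, lo, "-"), 2, span, "/")
  Dn[, degen] <- 0
  margins <- vapply(seq_len(n), function(i) {
    min(Dn[i, -i] - Dn[i, i])
  }, numeric(1))
  1 - min(margins)
}

#' Evaluate every combination of a grid
#'
#' Calibrates a module for each combination and records its accuracy
#' and error. Nuclei extraction is cached across combinations that
#' share the extraction-stage parameters (slide count, nucleus count,
#' selection composition, seed), which is what makes the full grid
#' affordable. Alerts raised by individual calibrations are captured
#' into the records rather than interrupting the sweep.
#'
#' @param ref_batches,val_batches As in [calibrate()].
#' @param grid A tibble from [enumerate_grid()].
#' @param beta,n_bin Passed to the calibrations.
#' @param progress Print a line every `progress` combinations (0 = off).
#' @return The grid with `A`, `E` and `n_alerts` columns appended.
#' @export
evaluate_grid <- function(ref_batches, val_batches, grid, beta = 0.7,
                          n_bin = 100L, progress = 0L) {
  ids <- ref_ids_of(ref_batches)
  cache <- new.env(parent = emptyenv())
  A <- E <- numeric(nrow(grid))
  n_alerts <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    row <- grid[r, ]
    params <- grid_row_to_params(row)
    key <- paste(row$n_wsi, row$n_nuc, row$nuc_selection, row$seed, sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- suppressWarnings(list(
        ref = extract_cohort(ref_batches, params, seed_offset = 0L),
        val = extract_cohort(val_batches, params, seed_offset = 1000L)))
      names(cache[[key]]$ref) <- ids
    }
    mats <- cache[[key]]
    module <- withCallingHandlers(
      suppressWarnings(
        calibrate_from_matrices(mats$ref, mats$val, ids, params, beta, n_bin)),
      slideqc_alert = function(w) invokeRestart("muffleWarning"))
    A[r] <- validation_accuracy(module)
    E[r] <- suppressWarnings(validation_error(module))
    n_alerts[r] <- length(module$alerts)
    if (progress > 0L && r %% progress == 0L) {
      inform(sprintf("evaluated %d / %d combinations", r, nrow(grid)))
    }
  }
  grid$A <- A
  grid$E <- E
  grid$n_alerts <- n_alerts
  grid
}

#' Rank evaluated combinations and refine by seed stability
#'
#' Applies the three selection steps to evaluated records, then the
#' seed-stability refinement:
#' 1. keep the valid combinations (`A == 1`) — the set `theta_star`;
#' 2. keep the `min(k1, ceiling(0.05 * |theta_star|))` lowest-error
#'    combinations (ties by enumeration order) — the set `omega`;
#' 3. compute per-parameter value frequencies over `omega`,
#'    `H(theta) = sum_p h_p(theta_p)`, the objective
#'    `T = 1 - E + H`, and keep the `k2` highest-T combinations —
#'    the set `omega_minus`.
#' Refinement re-evaluates each survivor under fresh seeds and retains
#' those valid for every seed (`omega_star`). An empty `theta_star` or
#' `omega_star` raises a QC alert: the reference and validation sets
#' (or the processing pipeline) should be reconsidered.
#'
#' @param records Evaluated grid (tibble with `A`, `E` and the
#'   parameter columns, in enumeration order).
#' @param k1 Cap on the error-filtered set (default 150).
#' @param k2 Cap on the objective-filtered set (default 20).
#' @param error_fraction Fraction of the valid set eligible for the
#'   error filter; the effective cut is
#'   `min(k1, ceiling(error_fraction * |theta_star|))`. The default
#'   0.05 reproduces the full-scale behaviour; reduced exploratory
#'   grids may set 1 so `k1` alone binds.
#' @param refine_fn Function `(params, seed) -> accuracy` used by the
#'   refinement; `NULL` with `refinement_seeds = 0` skips refinement
#'   (then `omega_star = omega_minus`).
#' @param refinement_seeds Number of fresh seeds (default 10).
#' @param seed Base seed from which the fresh seeds are derived.
#' @return A `search_result` list with `records`, `theta_star`,
#'   `omega`, `omega_minus`, `omega_star`, `frequencies` and `alerts`.
#' @export
rank_and_refine <- function(records, k1 = 150L, k2 = 20L,
                            refine_fn = NULL, refinement_seeds = 10L,
                            seed = 1L, error_fraction = 0.05) {
  if (k1 < 1L || k2 < 1L) abort("`k1` and `k2` must be at least 1.")
  alerts <- character(0)

  theta_star <- records[records$A == 1, , drop = FALSE]
  if (nrow(theta_star) == 0L) {
    msg <- "No valid combination (theta_star empty): reconsider the reference and validation sets or the processing pipeline."
    qc_alert(msg, code = "empty_theta_star")
    return(structure(list(records = records, theta_star = theta_star,
                          omega = theta_star, omega_minus = theta_star,
                          omega_star = theta_star, frequencies = NULL,
                          alerts = msg),
                     class = "search_result"))
  }

  k_eff <- min(k1, ceiling(error_fraction * nrow(theta_star)))
  ord <- order(theta_star$E)  # stable: ties keep enumeration order
  omega <- theta_star[ord[seq_len(min(k_eff, nrow(theta_star)))], ,
                      drop = FALSE]

  fields <- search_param_fields()
  freqs <- lapply(fields, function(p) {
    tab <- table(as.character(omega[[p]]), useNA = "ifany")
    tab / nrow(omega)
  })
  names(freqs) <- fields
  H <- vapply(seq_len(nrow(omega)), function(r) {
    sum(vapply(fields, function(p) {
      key <- as.character(omega[[p]][r])
      if (is.na(key)) key <- NA_character_
      as.numeric(freqs[[p]][match(key, names(freqs[[p]]))])
    }, numeric(1)))
  }, numeric(1))
  omega$H <- H
  omega$T_obj <- 1 - omega$E + omega$H
  ord_t <- order(-omega$T_obj)
  omega_minus <- omega[ord_t[seq_len(min(k2, nrow(omega)))], , drop = FALSE]

  if (is.null(refine_fn) || refinement_seeds < 1L) {
    omega_star <- omega_minus
    omega_star$n_stable_seeds <- NA_integer_
  } else {
    seeds <- vapply(seq_len(refinement_seeds),
                    function(s) derive_seed(seed, 5000L + s), integer(1))
    stable <- vapply(seq_len(nrow(omega_minus)), function(r) {
      params_base <- grid_row_to_params(omega_minus[r, ])
      sum(vapply(seeds, function(s) {
        p <- grid_row_to_params(omega_minus[r, ], seed = s)
        refine_fn(p, s) == 1
      }, logical(1)))
    }, numeric(1))
    omega_minus$n_stable_seeds <- as.integer(stable)
    omega_star <- omega_minus[stable == refinement_seeds, , drop = FALSE]
  }

  if (nrow(omega_star) == 0L) {
    msg <- "No seed-stable combination (omega_star empty): reconsider the reference and validation sets or the processing pipeline."
    alerts <- c(alerts, msg)
    qc_alert(msg, code = "empty_omega_star")
  }
  structure(
    list(records = records, theta_star = theta_star, omega = omega,
         omega_minus = omega_minus, omega_star = omega_star,
         frequencies = freqs, alerts = alerts),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result: |Theta|=%d |Theta*|=%d |Omega|=%d |Omega-|=%d |Omega*|=%d>\n",
    nrow(x$records), nrow(x$theta_star), nrow(x$omega),
    nrow(x$omega_minus), nrow(x$omega_star)))
  if (length(x$alerts)) for (a in x$alerts) cat("  ALERT:", a, "\n")
  invisible(x)
}

#' Retain a final combination and its calibrated module
#'
#' After ranking and refinement, a final combination is retained and
#' its QC module calibrated. Candidates are scanned in priority order —
#' seed-stable survivors first, then the objective-filtered set, then
#' the error-filtered set — and the first whose calibrated module has
#' usable weights (strictly inside `(0, 1)`; a zero weight means two
#' pipelines are indistinguishable, a saturated weight of 1 leaves the
#' quality measure's dissimilarity coefficient undefined) is retained.
#' Skipped candidates are reported.
#'
#' @param result A [rank_and_refine()] or [grid_search()] result.
#' @param ref_batches,val_batches As in [calibrate()].
#' @param beta,n_bin Passed to [calibrate()].
#' @return A list with `module`, `params`, `combination` (the retained
#'   row) and `skipped` (combination ids rejected for unusable
#'   weights).
#' @export
retain_module <- function(result, ref_batches, val_batches, beta = 0.7,
                          n_bin = 100L) {
  stopifnot(inherits(result, "search_result"))
  theta_by_e <- result$theta_star[order(result$theta_star$E), , drop = FALSE]
  sets <- list(result$omega_star, result$omega_minus, result$omega,
               theta_by_e)
  cand <- dplyr::distinct(
    dplyr::bind_rows(lapply(sets, function(s) {
      s[names(s) %in% names(result$records)]
    })),
    .data$combination, .keep_all = TRUE)
  skipped <- integer(0)
  for (r in seq_len(nrow(cand))) {
    params <- grid_row_to_params(cand[r, ])
    module <- withCallingHandlers(
      suppressWarnings(
        calibrate(ref_batches, val_batches, params, beta = beta,
                  n_bin = n_bin)),
      slideqc_alert = function(w) invokeRestart("muffleWarning"))
    if (all(module$alpha > 0 & module$alpha < 1)) {
      return(list(module = module, params = params,
                  combination = cand[r, ], skipped = skipped))
    }
    skipped <- c(skipped, cand$combination[r])
  }
  qc_alert("No candidate combination yields usable reference weights; reconsider the reference and validation sets.",
           code = "no_usable_module")
  list(module = NULL, params = NULL, combination = NULL, skipped = skipped)
}

#' Full grid search over a cohort
#'
#' Convenience wrapper: enumerates (or accepts) a grid, evaluates every
#' combination on the reference/validation cohort, ranks, and refines
#' by seed stability, recalibrating each finalist under fresh seeds.
#'
#' @inheritParams evaluate_grid
#' @inheritParams rank_and_refine
#' @param grid A grid tibble; `NULL` enumerates the default grid.
#' @return A `search_result`.
#' @export
grid_search <- function(ref_batches, val_batches, grid = NULL,
                        beta = 0.7, n_bin = 100L, k1 = 150L, k2 = 20L,
                        refinement_seeds = 10L, seed = 1L,
                        error_fraction = 0.05, progress = 0L) {
  if (is.null(grid)) grid <- enumerate_grid()
  records <- evaluate_grid(ref_batches, val_batches, grid, beta = beta,
                           n_bin = n_bin, progress = progress)
  refine_fn <- function(params, s) {
    module <- withCallingHandlers(
      suppressWarnings(
        calibrate(ref_batches, val_batches, params, beta = beta,
                  n_bin = n_bin)),
      slideqc_alert = function(w) invokeRestart("muffleWarning"))
    validation_accuracy(module)
  }
  rank_and_refine(records, k1 = k1, k2 = k2, refine_fn = refine_fn,
                  refinement_seeds = refinement_seeds, seed = seed,
                  error_fraction = error_fraction)
}
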