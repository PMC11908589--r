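# Parameter combinations searched by validation.

# The eight searched parameters: slide count, nucleus count, the nuclei
# selection composition (one composite parameter), the per-feature
# distance, the aggregator, the feature-selection method, the number of
# selected features, and the seed.
search_param_fields <- function() {
  c("n_wsi", "n_nuc", "nuc_selection", "omega", "aggregator",
    "sel_method", "n_sel", "seed")
}

# Composite label of the nuclei-selection composition, used as a single
# parameter value in frequency counts.
nuc_selection_label <- function(intern_tau, use_distrib) {
  parts <- character(0)
  if (!is.na(intern_tau)) parts <- c(parts, sprintf("intern%.1f", intern_tau))
  if (isTRUE(use_distrib)) parts <- c(parts, "distrib")
  if (length(parts) == 0L) "none" else paste(parts, collapse = "+")
}

#' A QC-module parameter combination
#'
#' Bundles the eight searched parameters of a QC module. The constraint
#' `sel_method == "none"` if and only if `n_sel` is `NA` ("all
#' features") is enforced: absence of feature selection is a single
#' configuration with the identity reduction.
#'
#' @param n_wsi Number of WSIs used per batch.
#' @param n_nuc Total number of nuclei extracted per batch.
#' @param intern_tau Elliptic interior filter fraction, or `NA` for
#'   absent.
#' @param use_distrib Whether spatially stratified sampling is used.
#' @param omega,aggregator Passed to [distance_spec()].
#' @param sel_method `"chi2"`, `"mrmr"` or `"none"`.
#' @param n_sel Number of selected features, or `NA` for all (required
#'   with `sel_method = "none"`).
#' @param seed Integer seed for nuclei sampling.
#' @param use_debris Whether the debris filter is applied (not part of
#'   the searched grid; analyzed separately).
#' @return A `param_combination` object.
#' @export
param_combination <- function(n_wsi, n_nuc, intern_tau = NA,
                              use_distrib = FALSE,
                              omega = "wasserstein", aggregator = "max",
                              sel_method = c("none", "chi2", "mrmr"),
                              n_sel = NA, seed = 1L,
                              use_debris = FALSE) {
  assert_count(n_wsi, "n_wsi")
  assert_count(n_nuc, "n_nuc")
  sel_method <- match.arg(sel_method)
  if ((sel_method == "none") != is.na(n_sel)) {
    abort("`sel_method = \"none\"` requires `n_sel = NA` (all features), and vice versa.")
  }
  spec <- distance_spec(omega, aggregator)  # validates both
  structure(
    list(n_wsi = as.integer(n_wsi), n_nuc = as.integer(n_nuc),
         intern_tau = as.numeric(intern_tau),
         use_distrib = isTRUE(use_distrib),
         use_debris = isTRUE(use_debris),
         omega = spec$omega, aggregator = spec$aggregator,
         sel_method = sel_method,
         n_sel = if (is.na(n_sel)) NA_integer_ else as.integer(n_sel),
         seed = as.integer(seed)),
    class = "param_combination"
  )
}

#' @export
print.param_combination <- function(x, ...) {
  cat(sprintf(
    "<param_combination: n_wsi=%d n_nuc=%d nuc=%s omega=%s g=%s sel=%s n_sel=%s seed=%d>\n",
    x$n_wsi, x$n_nuc, nuc_selection_label(x$intern_tau, x$use_distrib),
    x$omega, x$aggregator, x$sel_method,
    if (is.na(x$n_sel)) "all" else x$n_sel, x$seed))
  invisible(x)
}

#' Number of searched parameters of a combination
#'
#' Counts the distinct parameters enumerated by the validation grid
#' (the nuclei-selection composition counts as one).
#'
#' @param params A [param_combination()] (unused beyond its class).
#' @return The integer number of searched parameters.
#' @export
n_search_params <- function(params = NULL) {
  length(search_param_fields())
}

params_to_selection_spec <- function(params, n_nuc = NULL, seed = NULL) {
  selection_spec(n_nuc = n_nuc %||% params$n_nuc,
                 intern_tau = params$intern_tau,
                 use_distrib = params$use_distrib,
                 use_debris = params$use_debris,
                 seed = seed %||% params$seed)
}
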