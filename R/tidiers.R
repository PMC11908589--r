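# Broom-style accessors for fitted objects.

#' Tidy a calibrated QC module
#'
#' One row per reference: identifier, weight, number of selected
#' features, diagonal distance and whether the diagonal quality
#' constraint holds.
#'
#' @param x A `qc_module`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.qc_module <- function(x, ...) {
  dplyr::bind_rows(lapply(x$references, function(ref) {
    tibble(reference = ref$id, alpha = ref$alpha,
           n_sel = length(ref$P$idx),
           diagonal_distance = ref$diagonal_distance,
           diagonal_ok = ref$diagonal_ok)
  }))
}

#' One-row summary of a calibrated QC module
#'
#' @param x A `qc_module`.
#' @param ... Unused.
#' @return A tibble with module-level facts: reference count, distance
#'   configuration, validation accuracy and error, alert count.
#' @export
glance.qc_module <- function(x, ...) {
  tibble(n_ref = length(x$references), n_bin = x$n_bin,
         omega = x$distance_spec$omega,
         aggregator = x$distance_spec$aggregator,
         beta = x$beta,
         accuracy = validation_accuracy(x),
         error = suppressWarnings(validation_error(x)),
         n_merged_groups = length(x$merge_groups %||% list()),
         n_alerts = length(x$alerts))
}

#' Tidy a grid-search result
#'
#' The per-combination records with a `set` column marking how far each
#' combination survived the selection steps.
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.search_result <- function(x, ...) {
  rec <- as_tibble(x$records)
  rec$set <- dplyr::case_when(
    rec$combination %in% x$omega_star$combination ~ "omega_star",
    rec$combination %in% x$omega_minus$combination ~ "omega_minus",
    rec$combination %in% x$omega$combination ~ "omega",
    rec$A == 1 ~ "theta_star",
    TRUE ~ "invalid")
  rec
}

#' One-row summary of a grid-search result
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return A tibble with the sizes of the nested selection sets.
#' @export
glance.search_result <- function(x, ...) {
  tibble(n_grid = nrow(x$records), n_theta_star = nrow(x$theta_star),
         n_omega = nrow(x$omega), n_omega_minus = nrow(x$omega_minus),
         n_omega_star = nrow(x$omega_star), n_alerts = length(x$alerts))
}
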