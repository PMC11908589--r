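# Plotting methods.

#' Heatmap of the cross-distance matrix of a module
#'
#' Tiles of the reference-by-validation distance matrix used for the
#' weights, with the weight (row minimum off the diagonal) implicit:
#' a healthy module has a visibly smallest diagonal in every column.
#'
#' @param object A `qc_module`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_module <- function(object, ...) {
  D <- object$D
  df <- tidyr::expand_grid(reference = rownames(D),
                           validation = colnames(D))
  df$distance <- as.numeric(t(D))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$validation,
                                   y = .data$reference,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$distance)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "validation pipeline", y = "reference pipeline",
                  fill = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Quality time series of a scored stream
#'
#' One line per tested reference across the stream's batches, the plot
#' an operator watches for drift.
#'
#' @param object A `qc_stream` tibble from [qc_stream()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_stream <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$batch_index, y = .data$quality,
                               colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "batch", y = "quality", colour = "reference") +
    ggplot2::theme_minimal()
}

#' Compare a feature's histogram across references
#'
#' Bar plot of one feature's stored reference histograms, the view used
#' to inspect an argmax-feature attribution.
#'
#' @param module A `qc_module`.
#' @param feature A feature identifier present in the reference
#'   representations.
#' @return A ggplot object.
#' @export
plot_feature_histograms <- function(module, feature) {
  stopifnot(inherits(module, "qc_module"))
  rows <- lapply(module$references, function(ref) {
    if (!feature %in% colnames(ref$R)) return(NULL)
    tibble(reference = ref$id,
           bin = (seq_len(nrow(ref$R)) - 0.5) / nrow(ref$R),
           density = ref$R[, feature])
  })
  df <- dplyr::bind_rows(rows)
  if (nrow(df) == 0L) {
    abort(sprintf("Feature '%s' is not in any reference representation.",
                  feature))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$density)) +
    ggplot2::geom_col(width = 1 / max(table(df$reference))) +
    ggplot2::facet_wrap(~reference) +
    ggplot2::labs(x = "normalized feature value", y = "probability",
                  title = feature) +
    ggplot2::theme_minimal()
}
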