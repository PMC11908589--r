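# Shared fixtures, built in code at test time.

# A small, well-separated multi-pipeline cohort.
small_cohort <- function(n_pipelines = 3, n_feat = 8, separation = 2,
                         n_wsi = 6, nuclei_per_wsi = 200, seed = 11,
                         debris_rate = 0.05, cluster_fraction = 0.3) {
  generate_cohort(n_pipelines, n_feat, separation, n_wsi, nuclei_per_wsi,
                  seed, debris_rate = debris_rate,
                  cluster_fraction = cluster_fraction)
}

fast_params <- function(seed = 5, ...) {
  args <- list(n_wsi = 6, n_nuc = 600, intern_tau = NA, use_distrib = FALSE,
               omega = "wasserstein", aggregator = "max",
               sel_method = "none", n_sel = NA, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(param_combination, args)
}

quiet_calibrate <- function(...) {
  suppressWarnings(calibrate(...))
}

# Random column-stochastic histogram.
random_histogram <- function(n_bin) {
  v <- stats::rexp(n_bin)
  v / sum(v)
}

# A tiny nuclei table with explicit coordinates.
toy_table <- function(x, y, features = NULL, is_debris = NULL,
                      wsi_dims = c(width = 1, height = 1)) {
  n <- length(x)
  df <- tibble::tibble(
    wsi_id = rep("w1", n), x = x, y = y,
    is_debris = is_debris %||% rep(FALSE, n))
  if (is.null(features)) features <- matrix(0, n, 1)
  colnames(features) <- sprintf("f_%03d", seq_len(ncol(features)) - 1L)
  df <- dplyr::bind_cols(df, tibble::as_tibble(features))
  attr(df, "wsi_dims") <- wsi_dims
  attr(df, "pipeline_id") <- "toy"
  class(df) <- unique(c("wsi_batch", class(df)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent greedy transport oracle for the Wasserstein distance on
# bin centers: moves mass between the leftmost surpluses and deficits,
# paying |center_i - center_j| per unit. Deliberately distinct from the
# cumulative-sum formula used by the implementation.
wasserstein_transport_oracle <- function(f, f2) {
  n <- length(f)
  centers <- (seq_len(n) - 0.5) / n
  surplus <- f - f2
  cost <- 0
  i <- 1L; j <- 1L
  give <- pmax(surplus, 0)
  take <- pmax(-surplus, 0)
  while (i <= n && j <= n) {
    if (give[i] <= 1e-15) { i <- i + 1L; next }
    if (take[j] <= 1e-15) { j <- j + 1L; next }
    m <- min(give[i], take[j])
    cost <- cost + m * abs(centers[i] - centers[j])
    give[i] <- give[i] - m
    take[j] <- take[j] - m
  }
  cost
}
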