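# Synthetic WSI batch generation.

# Inverse-CDF sampler for a Gaussian truncated at mean +/- z*sd.
rtnorm <- function(n, mean, sd, z) {
  lo <- pnorm(-z)
  hi <- pnorm(z)
  mean + sd * qnorm(runif(n, lo, hi))
}

#' Generate a batch of synthetic WSIs from a pipeline profile
#'
#' Draws `n_wsi` whole slide images of `nuclei_per_wsi` nuclei each. Per
#' nucleus: a debris flag (probability `profile$debris_rate`), spatial
#' coordinates (a `cluster_fraction` share is placed in an elliptic
#' annulus near the slide edges, emulating centrifugation clusters; the
#' rest uniformly), and `n_feat` feature values drawn from the profile's
#' per-feature mixture laws. Debris rows draw their features from a
#' wider, non-mixture law so that filtering them out is consequential.
#' The result is bit-reproducible given `(profile, n_wsi,
#' nuclei_per_wsi, seed)`.
#'
#' @param profile A [make_pipeline_profile()] object.
#' @param n_wsi Number of WSIs in the batch (>= 1).
#' @param nuclei_per_wsi Nuclei per WSI (>= 1).
#' @param seed Integer seed.
#'
#' @return A `wsi_batch`: a tibble with one row per nucleus and columns
#'   `wsi_id`, `x`, `y`, `is_debris`, `f_000` ... ; attributes
#'   `pipeline_id` and `wsi_dims` carry the batch metadata.
#' @export
#' @examples
#' p <- make_pipeline_profile(1, n_feat = 3, separation = 1)
#' b <- generate_batch(p, n_wsi = 2, nuclei_per_wsi = 50, seed = 7)
#' dplyr::count(b, wsi_id)
generate_batch <- function(profile, n_wsi, nuclei_per_wsi, seed) {
  stopifnot(inherits(profile, "pipeline_profile"))
  assert_count(n_wsi, "n_wsi")
  assert_count(nuclei_per_wsi, "nuclei_per_wsi")

  n_total <- as.integer(n_wsi) * as.integer(nuclei_per_wsi)
  dims <- profile$wsi_dims
  w <- dims[["width"]]; h <- dims[["height"]]

  out <- withr::with_seed(as.integer(seed), {
    is_debris <- runif(n_total) < profile$debris_rate
    on_edge <- runif(n_total) < profile$cluster_fraction

    # Edge nuclei sit in an elliptic annulus hugging the slide border.
    theta <- runif(n_total, 0, 2 * pi)
    r <- runif(n_total, 0.85, 1)
    x <- ifelse(on_edge, w / 2 + r * (w / 2) * cos(theta), runif(n_total, 0, w))
    y <- ifelse(on_edge, h / 2 + r * (h / 2) * sin(theta), runif(n_total, 0, h))

    feats <- matrix(NA_real_, nrow = n_total, ncol = profile$n_feat)
    # One mixture-component draw per nucleus and feature.
    for (l in seq_len(profile$n_feat)) {
      comp <- 1L + (runif(n_total) > profile$comp_weights[1])
      mu <- profile$offsets[l] +
        ifelse(is_debris, 0, profile$comp_means[comp])
      sd <- ifelse(is_debris, profile$debris_sd, profile$comp_sds[comp])
      feats[, l] <- rtnorm(n_total, mu, sd, profile$trunc_z)
    }
    colnames(feats) <- feature_ids(profile$n_feat)

    tibble(
      wsi_id = rep(sprintf("%s_wsi_%03d", profile$pipeline_id, seq_len(n_wsi)),
                   each = nuclei_per_wsi),
      x = x, y = y, is_debris = is_debris
    ) |>
      dplyr::bind_cols(as_tibble(feats))
  })

  attr(out, "pipeline_id") <- profile$pipeline_id
  attr(out, "wsi_dims") <- dims
  class(out) <- unique(c("wsi_batch", class(out)))
  out
}

#' Generate a multi-pipeline cohort of reference and validation batches
#'
#' Convenience wrapper reproducing the study design in which each
#' pipeline contributes one reference and one validation batch of equal
#' size (a random split of its production). Profiles are built from
#' consecutive seeds at the given separation.
#'
#' @param n_pipelines Number of pipelines (>= 2).
#' @param n_feat Features per nucleus.
#' @param separation Profile separation passed to
#'   [make_pipeline_profile()].
#' @param n_wsi WSIs per batch.
#' @param nuclei_per_wsi Nuclei per WSI.
#' @param seed Integer seed; reference and validation batches of each
#'   pipeline use distinct derived seeds.
#' @param debris_rate,cluster_fraction Passed to the profiles.
#'
#' @return A list with `profiles`, `reference` and `validation` (each a
#'   named list, one entry per pipeline).
#' @export
generate_cohort <- function(n_pipelines, n_feat, separation,
                            n_wsi, nuclei_per_wsi, seed,
                            debris_rate = 0.05, cluster_fraction = 0.3) {
  assert_count(n_pipelines, "n_pipelines")
  if (n_pipelines < 2) abort("`n_pipelines` must be at least 2.")
  profiles <- lapply(seq_len(n_pipelines), function(i) {
    make_pipeline_profile(derive_seed(seed, i), n_feat, separation,
                          pipeline_id = sprintf("pipeline_%d", i),
                          debris_rate = debris_rate,
                          cluster_fraction = cluster_fraction)
  })
  names(profiles) <- vapply(profiles, `[[`, "", "pipeline_id")
  reference <- lapply(seq_len(n_pipelines), function(i) {
    generate_batch(profiles[[i]], n_wsi, nuclei_per_wsi,
                   seed = derive_seed(seed, 100 + i))
  })
  validation <- lapply(seq_len(n_pipelines), function(i) {
    generate_batch(profiles[[i]], n_wsi, nuclei_per_wsi,
                   seed = derive_seed(seed, 200 + i))
  })
  names(reference) <- names(profiles)
  names(validation) <- names(profiles)
  list(profiles = profiles, reference = reference, validation = validation)
}
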