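# Synthetic pipeline profiles.
#
# A preparation pipeline is emulated by a parametric law per nucleus
# feature: a two-component mixture of truncated Gaussians on an abstract
# feature scale, translated by a per-feature, per-pipeline location
# offset. Distinct pipelines therefore differ by location shifts of
# otherwise identical laws, which is the dominant mode of variation a
# change of preparation, coloration or scanner induces in practice
# (stain intensity shifts whole feature distributions). Spatial
# structure (edge clustering from centrifugation) and debris
# contamination are controlled separately.

# Canonical (separation = 0) mixture shared by all profiles.
.canonical_law <- list(
  means   = c(-1, 1),
  sds     = c(0.5, 0.7),
  weights = c(0.6, 0.4),
  trunc_z = 4          # truncation at mean +/- trunc_z * sd, symmetric
)

#' Create a synthetic preparation-pipeline profile
#'
#' A profile fixes, per feature, a mixture of truncated Gaussians from
#' which nucleus feature values are drawn, plus the spatial law (fraction
#' of nuclei concentrated near the WSI edges) and the debris rate. Two
#' profiles built from different seeds differ by reproducible per-feature
#' location offsets scaled by `separation`; at `separation = 0` all
#' profiles share the canonical law and only their identifiers differ.
#'
#' @param base_seed Integer seed from which the per-feature offsets are
#'   drawn; the same seed always yields the same profile.
#' @param n_feat Number of nucleus features (>= 1).
#' @param separation Non-negative scalar scaling how far this profile's
#'   per-feature means sit from the canonical center. Larger values make
#'   pipelines easier to tell apart.
#' @param pipeline_id Identifier; defaults to `"pipeline_<base_seed>"`.
#' @param debris_rate Probability in `[0, 1]` that a nucleus row is
#'   debris (default 0.05, a typical residual rate after segmentation).
#' @param cluster_fraction Fraction in `[0, 1]` of nuclei placed in the
#'   edge annulus emulating centrifugation clusters (default 0.3).
#' @param wsi_dims Width and height of the slide in abstract units.
#'
#' @return A `pipeline_profile` object.
#' @seealso [inject_shift()], [generate_batch()]
#' @export
#' @examples
#' p <- make_pipeline_profile(1, n_feat = 5, separation = 1)
#' profile_feature_means(p)
make_pipeline_profile <- function(base_seed, n_feat, separation,
                                  pipeline_id = sprintf("pipeline_%d", base_seed),
                                  debris_rate = 0.05,
                                  cluster_fraction = 0.3,
                                  wsi_dims = c(width = 1, height = 1)) {
  assert_count(n_feat, "n_feat")
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0) {
    abort("`separation` must be a single non-negative number.")
  }
  if (debris_rate < 0 || debris_rate > 1) {
    abort("`debris_rate` must be in [0, 1].")
  }
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    abort("`cluster_fraction` must be in [0, 1].")
  }
  offsets <- withr::with_seed(as.integer(base_seed),
                              separation * rnorm(n_feat))
  structure(
    list(
      pipeline_id = pipeline_id,
      n_feat = as.integer(n_feat),
      offsets = offsets,
      comp_means = .canonical_law$means,
      comp_sds = .canonical_law$sds,
      comp_weights = .canonical_law$weights,
      trunc_z = .canonical_law$trunc_z,
      debris_sd = 3,
      debris_rate = debris_rate,
      cluster_fraction = cluster_fraction,
      wsi_dims = resolve_dims(NULL, wsi_dims)
    ),
    class = "pipeline_profile"
  )
}

#' @export
print.pipeline_profile <- function(x, ...) {
  cat(sprintf(
    "<pipeline_profile %s: %d features, debris rate %.3g, edge-cluster fraction %.3g>\n",
    x$pipeline_id, x$n_feat, x$debris_rate, x$cluster_fraction))
  invisible(x)
}

#' Expected feature means of a profile's nucleus law
#'
#' Analytic mean of each feature's mixture law for non-debris nuclei.
#' Because truncation is symmetric about each component mean, the mean of
#' the mixture is exactly the weighted sum of component means plus the
#' profile's offset.
#'
#' @param profile A [make_pipeline_profile()] object.
#' @return Numeric vector of length `n_feat`.
#' @export
profile_feature_means <- function(profile) {
  stopifnot(inherits(profile, "pipeline_profile"))
  profile$offsets + sum(profile$comp_weights * profile$comp_means)
}

#' Translate selected features of a profile
#'
#' Returns a copy of `profile` in which the mixture laws of the listed
#' features are translated by `delta`, all other features untouched.
#' This emulates a drift of the preparation (for instance a coloration
#' change shifting the distribution of one color feature) and is the
#' standard way to build drifted test streams.
#'
#' @param profile A [make_pipeline_profile()] object.
#' @param feature_idx Integer indices (1-based) of the features to shift.
#' @param delta Scalar translation applied to the listed features' means.
#' @return A new `pipeline_profile`.
#' @export
inject_shift <- function(profile, feature_idx, delta) {
  stopifnot(inherits(profile, "pipeline_profile"))
  feature_idx <- as.integer(feature_idx)
  if (length(feature_idx) == 0L ||
      any(feature_idx < 1L | feature_idx > profile$n_feat)) {
    abort(sprintf("`feature_idx` must index features 1..%d.", profile$n_feat))
  }
  profile$offsets[feature_idx] <- profile$offsets[feature_idx] + delta
  profile
}
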