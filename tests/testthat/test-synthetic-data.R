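# The synthetic cohort generator: reproducibility, law structure,
# moments, and separation of distinct pipelines.

test_that("profiles are reproducible and separation scales the offsets", {
  p1 <- make_pipeline_profile(7, n_feat = 5, separation = 1)
  p2 <- make_pipeline_profile(7, n_feat = 5, separation = 1)
  expect_identical(p1, p2)

  # Zero separation: different seeds share the canonical law.
  a <- make_pipeline_profile(1, n_feat = 5, separation = 0)
  b <- make_pipeline_profile(2, n_feat = 5, separation = 0)
  expect_equal(a$offsets, b$offsets)
  expect_equal(a$offsets, rep(0, 5))

  expect_error(make_pipeline_profile(1, n_feat = 0, separation = 1))
  expect_error(make_pipeline_profile(1, n_feat = 3, separation = -1))
})

test_that("empirical feature-law gap between two profiles matches the offset", {
  # The laws of two profiles differ by a pure location shift per
  # feature, so the 1-Wasserstein distance between large samples of
  # feature 1 equals the analytic mean gap.
  p1 <- make_pipeline_profile(3, n_feat = 2, separation = 0.3,
                              debris_rate = 0)
  p2 <- make_pipeline_profile(4, n_feat = 2, separation = 0.3,
                              debris_rate = 0)
  gap <- abs(p1$offsets[1] - p2$offsets[1])
  n <- 1e6
  b1 <- generate_batch(p1, 1, n, seed = 1)
  b2 <- generate_batch(p2, 1, n, seed = 2)
  # Empirical 1-Wasserstein between samples: mean |sorted difference|.
  emp <- mean(abs(sort(b1$f_000) - sort(b2$f_000)))
  expect_lt(abs(emp - gap), 0.01)
})

test_that("inject_shift translates only the listed features", {
  p <- make_pipeline_profile(5, n_feat = 4, separation = 1)
  expect_equal(inject_shift(p, 2, 0)$offsets, p$offsets)
  q <- inject_shift(p, 4, 0.5)
  expect_equal(q$offsets[4] - p$offsets[4], 0.5)
  expect_equal(q$offsets[1:3], p$offsets[1:3])
  expect_error(inject_shift(p, 9, 1))
})

test_that("shifted feature attains the max per-feature distance", {
  p <- make_pipeline_profile(6, n_feat = 6, separation = 0, debris_rate = 0)
  q <- inject_shift(p, 3, 2)
  b_p <- generate_batch(p, 4, 500, seed = 9)
  b_q <- generate_batch(q, 4, 500, seed = 10)
  spec <- selection_spec(n_nuc = 2000, seed = 1)
  Cp <- extract_feature_matrix(b_p, spec)
  Cq <- extract_feature_matrix(b_q, spec)
  bounds <- compute_bounds(list(Cp, Cq))
  res <- distribution_distance(to_distribution(Cp, bounds, 50),
                               to_distribution(Cq, bounds, 50),
                               distance_spec("wasserstein", "max"))
  expect_identical(res$argmax_feature, "f_002")
})

test_that("batches have the requested shape, debris rate and determinism", {
  p <- make_pipeline_profile(2, n_feat = 3, separation = 1)
  b <- generate_batch(p, n_wsi = 2, nuclei_per_wsi = 5, seed = 1)
  expect_equal(nrow(b), 10L)
  expect_equal(dplyr::n_distinct(b$wsi_id), 2L)
  expect_identical(b, generate_batch(p, 2, 5, seed = 1))

  p0 <- make_pipeline_profile(2, n_feat = 3, separation = 1, debris_rate = 0)
  b0 <- generate_batch(p0, 2, 200, seed = 1)
  expect_false(any(b0$is_debris))

  # Coordinates stay inside the declared slide.
  dims <- attr(b, "wsi_dims")
  expect_true(all(b$x >= 0 & b$x <= dims[["width"]]))
  expect_true(all(b$y >= 0 & b$y <= dims[["height"]]))
})

test_that("sample feature means match analytic mixture moments", {
  p <- make_pipeline_profile(8, n_feat = 3, separation = 1, debris_rate = 0)
  b <- generate_batch(p, 1, 1e5, seed = 3)
  mu <- profile_feature_means(p)
  # Mixture sd bounded by sqrt(max component variance + mean spread).
  sd_bound <- sqrt(max(p$comp_sds)^2 + diff(p$comp_means)^2)
  for (l in 1:3) {
    se <- sd_bound / sqrt(1e5)
    expect_lt(abs(mean(b[[sprintf("f_%03d", l - 1)]]) - mu[l]), 4 * se)
  }
})

test_that("separated profiles are farther apart than same-profile replicates", {
  # Over many seeds: the distance between batches of two different
  # well-separated profiles always exceeds the distance between two
  # batches of the same profile.
  p1 <- make_pipeline_profile(21, n_feat = 4, separation = 2, debris_rate = 0)
  p2 <- make_pipeline_profile(22, n_feat = 4, separation = 2, debris_rate = 0)
  spec <- selection_spec(n_nuc = 600, seed = 1)
  dist_of <- function(ba, bb) {
    Ca <- extract_feature_matrix(ba, spec)
    Cb <- extract_feature_matrix(bb, spec)
    bounds <- compute_bounds(list(Ca, Cb))
    distribution_distance(to_distribution(Ca, bounds, 50),
                          to_distribution(Cb, bounds, 50),
                          distance_spec("wasserstein", "max"))$value
  }
  for (s in 1:20) {
    same <- dist_of(generate_batch(p1, 2, 300, seed = 100 + s),
                    generate_batch(p1, 2, 300, seed = 200 + s))
    cross <- dist_of(generate_batch(p1, 2, 300, seed = 100 + s),
                     generate_batch(p2, 2, 300, seed = 300 + s))
    expect_gt(cross, same)
  }
})
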