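# Scoring: signed distances, compatibility, quality, assignment.

test_that("signed weighted distances follow the defining rescaling", {
  # d = raw / alpha - 1 on hand cases.
  expect_equal(0.1 / 0.2 - 1, -0.5)
  co <- small_cohort(n_pipelines = 2, n_wsi = 4, nuclei_per_wsi = 150)
  m <- quiet_calibrate(co$reference, co$validation,
                       fast_params(n_wsi = 4, n_nuc = 300))
  b <- generate_batch(co$profiles[[1]], 4, 150, seed = 31)
  dv <- distance_vector(b, m)
  expect_equal(dv$d, dv$raw / dv$alpha - 1)
  expect_true(all(dv$d >= -1))
  expect_true(all(dv$d <= 1 / dv$alpha - 1 + 1e-12))
})

test_that("compatibility counts the satisfied constraints", {
  expect_equal(compatibility(c(-0.5, 0.2, -0.1), 1), 2 / 3)
  expect_equal(compatibility(c(-0.5, 0.2, 0.3), 1), 1)
  expect_equal(compatibility(c(0.5, -0.2, -0.3), 1), 0)
  expect_equal(compatibility(c(0, -0.2), 1), 0)   # boundary: d_i = 0 fails
  expect_error(compatibility(c(0.1, 0.2), 5))
})

test_that("quality matches the hand-evaluated weighted blend", {
  q <- quality(d = c(-0.4, 0.5, 1.0), i = 1,
               alphas = c(0.3, 0.2, 0.5), beta = 0.7)
  expect_equal(q$Q_similar, 0.4)
  expect_equal(q$Q_dissimilar, 0.5625)
  expect_equal(q$Q, 0.44875)

  # beta = 1 reduces to the similarity term.
  q1 <- quality(c(-0.4, 0.5, 1.0), 1, c(0.3, 0.2, 0.5), beta = 1)
  expect_equal(q1$Q, q1$Q_similar)

  # No constraint satisfied: quality is exactly zero.
  q0 <- quality(c(0.4, -0.5, -0.2), 1, c(0.3, 0.2, 0.5), beta = 0.7)
  expect_equal(q0$Q, 0)

  expect_error(quality(c(-0.1, 0.2), 1, c(0.5, 1), 0.5), "undefined")
  expect_error(quality(c(-0.1, 0.2), 1, c(0.5, 0), 0.5))
})

test_that("quality is bounded in [0,1] and zero iff nothing is satisfied", {
  withr::with_seed(77, {
    for (rep in 1:10000) {
      n <- sample(2:6, 1)
      alphas <- runif(n, 0.05, 0.95)
      raw <- runif(n)                 # raw distances in [0, 1]
      d <- raw / alphas - 1
      i <- sample(n, 1)
      beta <- runif(1)
      q <- quality(d, i, alphas, beta)
      expect_gte(q$Q, 0)
      expect_lte(q$Q, 1)
      none_satisfied <- d[i] >= 0 && all(d[-i] < 0)
      if (none_satisfied) expect_equal(q$Q, 0)
      if (q$Q == 0 && beta > 0 && beta < 1) expect_true(none_satisfied)
    }
  })
})

test_that("compatibility is invariant to uniform monotone rescaling", {
  withr::with_seed(12, {
    for (rep in 1:50) {
      n <- sample(2:5, 1)
      alphas <- runif(n, 0.1, 0.9)
      raw <- runif(n)
      i <- sample(n, 1)
      c1 <- compatibility(raw / alphas - 1, i)
      s <- runif(1, 0.1, 5)           # rescale distances and weights alike
      c2 <- compatibility((s * raw) / (s * alphas) - 1, i)
      expect_equal(c1, c2)
    }
  })
})

test_that("best_reference recovers the generating pipeline or alerts", {
  co <- small_cohort(n_pipelines = 3, separation = 2.5)
  # Full-quota extraction makes scoring deterministic: re-scoring each
  # validation batch reproduces the calibration distances exactly, so
  # the cross constraints hold with equality and the diagonal is
  # strictly inside the weight -- the true reference is recovered.
  m <- quiet_calibrate(co$reference, co$validation,
                       fast_params(n_nuc = 6 * 200))
  expect_equal(validation_accuracy(m), 1)
  for (k in 1:3) {
    res <- suppressWarnings(best_reference(co$validation[[k]], m))
    expect_equal(res$assigned, names(co$profiles)[k])
  }
  # On fresh batches the dissimilarity constraint of the weight-setting
  # pipeline sits at the decision boundary, so an alert is possible;
  # but a wrong assignment is not, at this separation.
  for (k in 1:3) {
    b <- generate_batch(co$profiles[[k]], 6, 200, seed = 400 + k)
    res <- suppressWarnings(best_reference(b, m))
    expect_true(is.na(res$assigned) ||
                  res$assigned == names(co$profiles)[k])
  }
  # A far-away pipeline is compatible with nothing: explicit alert.
  outsider <- make_pipeline_profile(999, n_feat = 8, separation = 30)
  b_out <- generate_batch(outsider, 6, 200, seed = 9)
  msgs <- testthat::capture_warnings(res <- best_reference(b_out, m))
  expect_true(any(grepl("No reference is compatible", msgs)))
  expect_true(is.na(res$assigned))
  expect_length(res$compatible, 0)
})

test_that("streams are cut into contiguous batches with remainder dropped", {
  co <- small_cohort(n_pipelines = 2, n_wsi = 4, nuclei_per_wsi = 150)
  m <- quiet_calibrate(co$reference, co$validation,
                       fast_params(n_wsi = 4, n_nuc = 300))
  stream <- generate_batch(co$profiles[[1]], n_wsi = 10, nuclei_per_wsi = 150,
                           seed = 55)
  expect_warning(
    rep <- qc_stream(stream, m, reference = m$ref_ids[1], n_wsi = 4),
    "remainder")
  expect_equal(unique(rep$batch_index), 1:2)
  expect_equal(nrow(rep), 2L)
  # Batches are disjoint and contiguous: scoring the first 4 WSIs
  # directly matches batch 1.
  ids <- unique(stream$wsi_id)[1:4]
  sub <- stream[stream$wsi_id %in% ids, ]
  attr(sub, "wsi_dims") <- attr(stream, "wsi_dims")
  direct <- qc_batch(sub, m, reference = m$ref_ids[1],
                     seed = slideqc:::derive_seed(m$params$seed, 1))
  expect_equal(rep$quality[1], direct$quality[1])
})
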