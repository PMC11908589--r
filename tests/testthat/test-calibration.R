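# Module calibration: weights, constraint guarantees, merging, and
# serialization round trips.

test_that("weights are the off-group minima of the cross distances", {
  D <- matrix(c(0.0, 0.3, 0.2,
                0.4, 0.0, 0.5,
                0.25, 0.6, 0.0), 3, 3, byrow = TRUE)
  expect_equal(compute_weights(D), c(0.2, 0.4, 0.25))
  # Two references: the single cross distance.
  D2 <- matrix(c(0, 0.7, 0.1, 0), 2, 2, byrow = TRUE)
  expect_equal(compute_weights(D2), c(0.7, 0.1))
  # Indistinguishable pipelines raise the calibration alert.
  D0 <- matrix(c(0, 0, 0.3, 0), 2, 2, byrow = TRUE)
  expect_warning(compute_weights(D0), class = "slideqc_alert")
})

test_that("calibration on a separated cohort satisfies all constraints", {
  co <- small_cohort(n_pipelines = 3, separation = 2.5)
  m <- quiet_calibrate(co$reference, co$validation, fast_params())
  expect_s3_class(m, "qc_module")
  expect_equal(validation_accuracy(m), 1)
  expect_true(all(tidy(m)$diagonal_ok))
  expect_length(m$alerts, 0)
  # The dissimilarity constraint holds for every validation batch by
  # construction of the weights.
  expect_true(all(m$D[!diag(3)] >= rep(m$alpha, 3)[!diag(3)]))
})

test_that("validation batches identical to references give zero diagonals", {
  co <- small_cohort(n_pipelines = 3, separation = 2.5)
  # A quota covering every nucleus makes extraction deterministic, so
  # identical batches yield identical representations: D_ii = 0 < alpha.
  m <- quiet_calibrate(co$reference, co$reference,
                       fast_params(n_nuc = 6 * 200))
  expect_equal(unname(diag(m$D)), rep(0, 3))
  expect_true(all(m$alpha > 0))
  expect_equal(validation_accuracy(m), 1)
})

test_that("near-identical profiles get small weights and are flagged", {
  # Clone pipeline 1 into pipeline 2 (the two differ only by sampling
  # noise): their mutual distances drive both weights down.
  p1 <- make_pipeline_profile(41, n_feat = 6, separation = 2)
  p2 <- p1; p2$pipeline_id <- "pipeline_clone"
  p3 <- make_pipeline_profile(43, n_feat = 6, separation = 2)
  refs <- list(a = generate_batch(p1, 6, 200, 1),
               b = generate_batch(p2, 6, 200, 2),
               c = generate_batch(p3, 6, 200, 3))
  vals <- list(a = generate_batch(p1, 6, 200, 4),
               b = generate_batch(p2, 6, 200, 5),
               c = generate_batch(p3, 6, 200, 6))
  m <- quiet_calibrate(refs, vals, fast_params())
  expect_lt(m$alpha[["a"]], min(m$D["a", "c"], m$D["c", "a"]))
  expect_lt(m$alpha[["b"]], m$alpha[["c"]])

  # Merging the clones raises their weights to the nearest non-member.
  merged <- merge_references(m, c("a", "b"))
  expect_equal(merged$alpha[["a"]], m$D["a", "c"])
  expect_equal(merged$alpha[["b"]], m$D["b", "c"])
  expect_equal(merged$alpha[["c"]], m$alpha[["c"]])  # min unaffected

  expect_error(merge_references(m, c("a", "b", "c")), "all references")
  expect_error(merge_references(m, "a"), "at least 2")
  expect_error(merge_references(m, c("a", "zz")), "Unknown")
})

test_that("recalibration with identical inputs is bit-reproducible", {
  co <- small_cohort(n_pipelines = 2, n_wsi = 4, nuclei_per_wsi = 120)
  p <- fast_params(n_wsi = 4, n_nuc = 240)
  m1 <- quiet_calibrate(co$reference, co$validation, p)
  m2 <- quiet_calibrate(co$reference, co$validation, p)
  expect_identical(m1$D, m2$D)
  expect_identical(m1$alpha, m2$alpha)
})

test_that("calibration works with feature selection enabled", {
  co <- small_cohort(n_pipelines = 3, n_feat = 10, separation = 2.5)
  for (method in c("chi2", "mrmr")) {
    m <- quiet_calibrate(co$reference, co$validation,
                         fast_params(sel_method = method, n_sel = 4))
    expect_equal(validation_accuracy(m), 1)
    for (ref in m$references) {
      expect_length(ref$P$idx, 4)
      expect_equal(ncol(ref$R), 4)
    }
  }
})

test_that("a calibrated module round-trips through JSON", {
  co <- small_cohort(n_pipelines = 2, n_wsi = 4, nuclei_per_wsi = 120)
  m <- quiet_calibrate(co$reference, co$validation,
                       fast_params(n_wsi = 4, n_nuc = 240,
                                   sel_method = "chi2", n_sel = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_module(m, path)
  m2 <- read_qc_module(path)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$D, m$D)
  expect_equal(unclass(m2$references[[1]]$R), unclass(m$references[[1]]$R),
               ignore_attr = TRUE)
  expect_equal(m2$references[[2]]$P$idx, m$references[[2]]$P$idx)
  expect_equal(m2$bounds$lower, m$bounds$lower)
  expect_equal(unclass(m2$params), unclass(m$params))
  # Scoring through the reloaded module matches the original.
  b <- generate_batch(co$profiles[[1]], 4, 120, seed = 99)
  r1 <- suppressWarnings(qc_batch(b, m, reference = m$ref_ids[1]))
  r2 <- suppressWarnings(qc_batch(b, m2, reference = m$ref_ids[1]))
  expect_equal(r1$quality, r2$quality)
})
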