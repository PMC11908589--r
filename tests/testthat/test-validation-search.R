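# Grid enumeration, accuracy/error metrics, ranking and refinement.

test_that("the default grid enumerates the documented combination count", {
  grid <- enumerate_grid()
  # 3 n_wsi x 3 n_nuc x (3 interior x 2 sampler) x 3 omega x 3 g x
  # (2 methods x 4 n_sel + no-selection) x 1 seed.
  expect_equal(nrow(grid), 4374L)
  expect_equal(length(unique(grid$nuc_selection)), 6L)
  expect_equal(nrow(dplyr::distinct(grid, sel_method, n_sel)), 9L)
  # All-feature rows carry no selection method and vice versa.
  expect_true(all((grid$sel_method == "none") == is.na(grid$n_sel)))
})

test_that("single-value grids and feature-config counting behave", {
  g1 <- enumerate_grid(n_wsi = 10, n_nuc = 1000, intern_tau = NA,
                       use_distrib = FALSE, omega = "wasserstein",
                       aggregator = "max", sel_methods = "chi2",
                       n_sel_values = integer(0))
  expect_equal(nrow(g1), 1L)
  fs <- feature_selection_configs()
  expect_equal(attr(fs, "n_raw_configs"), 10L)
  expect_equal(nrow(fs), 9L)
  expect_equal(n_search_params(), 8L)
})

test_that("accuracy counts satisfied diagonal constraints", {
  fake_module <- function(D, alpha) {
    structure(list(D = D, alpha = alpha), class = "qc_module")
  }
  D <- diag(c(0.1, 0.2, 0.3, 0.1, 0.1, 0.1, 0.1))
  D[D == 0] <- 0.9
  m_all <- fake_module(D, alpha = rep(0.5, 7))
  expect_equal(validation_accuracy(m_all), 1)
  m_none <- fake_module(D, alpha = rep(0.05, 7))
  expect_equal(validation_accuracy(m_none), 0)
  alpha <- rep(0.5, 7); alpha[3] <- 0.25     # one diagonal fails
  expect_equal(validation_accuracy(fake_module(D, alpha)), 6 / 7)
})

test_that("the error metric matches hand-normalized margin cases", {
  D1 <- matrix(c(0, 0.4, 0.5, 0.1), 2, 2, byrow = TRUE)
  expect_equal(slideqc:::normalized_margin_error(D1), 0)
  D2 <- matrix(c(0.2, 0.1, 0.3, 0.4), 2, 2, byrow = TRUE)
  expect_equal(slideqc:::normalized_margin_error(D2), 1)
  # A strictly column-minimal diagonal with real margins: E < 1.
  D3 <- matrix(c(0.1, 0.5, 0.6,
                 0.6, 0.2, 0.9,
                 0.7, 0.9, 0.1), 3, 3, byrow = TRUE)
  expect_lt(slideqc:::normalized_margin_error(D3), 1)
  # Degenerate column: zeroed with a warning.
  D4 <- matrix(c(0.3, 0.1, 0.3, 0.4), 2, 2, byrow = TRUE)
  expect_warning(slideqc:::normalized_margin_error(D4), "degenerate")
})

test_that("frequency objective and filtering steps follow the rules", {
  base <- enumerate_grid(n_wsi = 10, n_nuc = 1000, intern_tau = NA,
                         use_distrib = FALSE,
                         omega = c("wasserstein", "jensen_shannon"),
                         aggregator = "max", sel_methods = "chi2",
                         n_sel_values = integer(0))
  # Two combinations differing only in omega.
  records <- base
  records$A <- 1
  records$E <- c(0.4, 0.6)
  res <- rank_and_refine(records, k1 = 10, k2 = 10, refinement_seeds = 0)
  # 5% rule: ceiling(0.05 * 2) = 1 combination survives to omega.
  expect_equal(nrow(res$omega), 1L)
  expect_equal(res$omega$E, 0.4)                 # lowest error survives

  # With k1 respected and both kept, the shared parameter values have
  # frequency 1 and the differing one 0.5 each.
  records2 <- dplyr::bind_rows(records, records, records, records,
                               records, records, records, records,
                               records, records)  # 20 rows
  records2$combination <- seq_len(nrow(records2))
  res2 <- rank_and_refine(records2, k1 = 20, k2 = 20, refinement_seeds = 0)
  expect_equal(nrow(res2$omega), 1L)  # ceiling(0.05*20) = 1
  res3 <- rank_and_refine(records2, k1 = 150, k2 = 20,
                          refinement_seeds = 0)
  expect_equal(nrow(res3$omega), 1L)

  # Direct check of H on a hand-built omega of 2 rows.
  rec4 <- records; rec4$combination <- 1:2
  res4 <- rank_and_refine(rec4, k1 = 150, k2 = 20, refinement_seeds = 0)
  expect_equal(nrow(res4$omega), 1L)
  expect_equal(unname(res4$frequencies$aggregator["max"]), 1)
})

test_that("the 5%-of-valid rule reproduces the documented sizes", {
  # 2860 valid combinations with distinct errors, k1 = 150: the 5% rule
  # keeps 143.
  n_valid <- 2860L
  grid <- enumerate_grid()[seq_len(n_valid), ]
  grid$A <- 1
  grid$E <- withr::with_seed(2, runif(n_valid))
  res <- rank_and_refine(grid, k1 = 150, k2 = 20, refinement_seeds = 0)
  expect_equal(nrow(res$omega), 143L)
  expect_equal(nrow(res$omega_minus), 20L)
  expect_lte(max(res$omega$E), min(grid$E[!grid$combination %in%
                                            res$omega$combination]))
})

test_that("monotone filtering and the empty-set alerts hold", {
  grid <- enumerate_grid(n_wsi = 10, n_nuc = 500, intern_tau = c(NA, 0.2),
                         use_distrib = c(FALSE, TRUE),
                         omega = c("wasserstein", "bhattacharyya"),
                         aggregator = c("max", "mean"),
                         sel_methods = "chi2", n_sel_values = c(2L, 4L))
  withr::with_seed(9, {
    grid$A <- sample(c(1, 1, 6/7), nrow(grid), replace = TRUE)
    grid$E <- runif(nrow(grid))
  })
  res <- rank_and_refine(grid, k1 = 10, k2 = 3, refinement_seeds = 0)
  expect_true(all(res$omega_star$combination %in% res$omega_minus$combination))
  expect_true(all(res$omega_minus$combination %in% res$omega$combination))
  expect_true(all(res$omega$combination %in% res$theta_star$combination))
  expect_lte(nrow(res$omega), 10L)
  expect_lte(nrow(res$omega_minus), 3L)
  expect_true(all(res$theta_star$A == 1))
  expect_equal(res$omega_minus$T_obj, 1 - res$omega_minus$E + res$omega_minus$H)
  expect_true(all(res$omega$H >= 0 & res$omega$H <= n_search_params()))

  grid$A <- 0.5
  expect_warning(res0 <- rank_and_refine(grid, 10, 3, refinement_seeds = 0),
                 class = "slideqc_alert")
  expect_equal(nrow(res0$theta_star), 0L)
})

test_that("a reduced end-to-end search finds seed-stable combinations", {
  co <- small_cohort(n_pipelines = 3, n_feat = 6, separation = 2.5,
                     n_wsi = 6, nuclei_per_wsi = 150)
  grid <- enumerate_grid(n_wsi = 6, n_nuc = 600,
                         intern_tau = c(NA, 0.4),
                         use_distrib = FALSE,
                         omega = c("wasserstein", "jensen_shannon"),
                         aggregator = "max",
                         sel_methods = "chi2", n_sel_values = 3L,
                         seed = 2L)
  res <- suppressWarnings(
    grid_search(co$reference, co$validation, grid, k1 = 6, k2 = 4,
                refinement_seeds = 3, seed = 7))
  expect_gt(nrow(res$omega_star), 0)
  expect_true(all(res$omega_star$n_stable_seeds == 3))
  expect_true(all(res$omega_star$A == 1))
})
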