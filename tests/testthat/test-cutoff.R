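test_that("profile scans integer thresholds with nested subsets", {
  sim <- simulate_cohort(cohort_params(n_sets = 200, seed = 31))
  sets <- aggregate_replicates(sim$records)
  prof <- icc_profile(sets, n_min = 10)
  e <- prof$entries
  expect_equal(e$threshold,
               seq.int(ceiling(min(sets$iap)) + 1L,
                       floor(max(sets$iap)) + 1L))
  expect_false(is.unsorted(e$n_below))
  expect_equal(e$n_below[length(e$n_below)], nrow(sets))
  # strict inequality defines the subset
  t0 <- e$threshold[5]
  expect_equal(e$n_below[5], sum(sets$iap < t0))
  # entries under n_min are absent, and absent entries carry no ICC
  expect_true(all(is.na(e$icc[e$n_below < 10])))
  expect_true(all(!is.na(e$icc[e$n_below >= 10])))
})

test_that("degenerate covariate gives a single constant profile entry", {
  sets <- data.frame(set_id = sprintf("S%02d", 1:12),
                     subject_id = "P", cvp = rnorm(12, 10, 3),
                     fivp = rnorm(12, 10, 3), iap = 10)
  prof <- icc_profile(sets, n_min = 10)
  expect_equal(prof$entries$threshold, 11L)
  expect_equal(prof$entries$n_below, 12L)
})

test_that("profile errors when no threshold can reach n_min", {
  sets <- data.frame(set_id = 1:5, subject_id = "P",
                     cvp = rnorm(5, 10), fivp = rnorm(5, 10), iap = 8)
  expect_error(icc_profile(sets, n_min = 6),
               class = "iapagree_insufficient_data_error")
})

test_that("strict argmax picks the maximum with ties to the largest threshold", {
  prof <- fake_profile(thresholds = c(12, 14, 15),
                       icc = c(0.93, 0.94, 0.77),
                       ci_low = c(0.85, 0.88, 0.60),
                       ci_high = c(0.97, 0.97, 0.88),
                       n_below = c(20L, 30L, 40L))
  expect_equal(best_cutoff(prof, rule = "argmax")$best_threshold, 14)
  tie <- fake_profile(thresholds = c(10, 14), icc = c(0.9, 0.9),
                      ci_low = c(0.8, 0.82), ci_high = c(0.95, 0.95),
                      n_below = c(15L, 25L))
  expect_equal(best_cutoff(tie, rule = "argmax")$best_threshold, 14)
})

test_that("ci-band rule prefers the largest statistically tied threshold", {
  # small early subset has the highest point estimate, but 14 sits inside
  # its confidence interval; 15 falls below it
  prof <- fake_profile(thresholds = c(5, 10, 14, 15),
                       icc = c(0.97, 0.945, 0.94, 0.90),
                       ci_low = c(0.93, 0.92, 0.925, 0.87),
                       ci_high = c(0.99, 0.96, 0.95, 0.92),
                       n_below = c(25L, 150L, 300L, 320L))
  expect_equal(best_cutoff(prof, rule = "ci-band")$best_threshold, 14)
  expect_equal(best_cutoff(prof, rule = "argmax")$best_threshold, 5)
})

test_that("excellent-threshold rule takes the largest threshold above 0.8", {
  prof <- fake_profile(thresholds = c(12, 14, 15),
                       icc = c(0.93, 0.82, 0.77),
                       ci_low = c(0.85, 0.70, 0.60),
                       ci_high = c(0.97, 0.90, 0.88),
                       n_below = c(20L, 30L, 40L))
  expect_equal(best_cutoff(prof, rule = "excellent-threshold")$best_threshold,
               14)
  low <- fake_profile(thresholds = 12, icc = 0.5, ci_low = 0.2,
                      ci_high = 0.7, n_below = 20L)
  expect_error(best_cutoff(low, rule = "excellent-threshold"),
               class = "iapagree_insufficient_data_error")
})

test_that("best cutoff is invariant to the input order of sets", {
  sim <- simulate_cohort(cohort_params(n_sets = 150, seed = 41))
  sets <- aggregate_replicates(sim$records)
  b1 <- best_cutoff(icc_profile(sets))$best_threshold
  set.seed(1)
  b2 <- best_cutoff(icc_profile(sets[sample.int(nrow(sets)), ]))$best_threshold
  expect_equal(b1, b2)
})

test_that("bootstrap comparison of identical groups is null and reproducible", {
  set.seed(3)
  y <- draw_pairs(30)
  cmp <- bootstrap_icc_difference(y, y, n_boot = 500, seed = 77)
  expect_equal(cmp$delta_obs, 0)
  expect_gt(cmp$p_value, 0.5)
  cmp2 <- bootstrap_icc_difference(y, y, n_boot = 500, seed = 77)
  expect_identical(cmp, cmp2)
  cmp3 <- bootstrap_icc_difference(y, y, n_boot = 500, seed = 78)
  expect_false(identical(cmp$p_value, cmp3$p_value))
})

test_that("bootstrap detects a genuine ICC gap across the changepoint", {
  set.seed(9)
  below <- draw_pairs(250, sigma_T = 4, sigma_m = 1)
  above <- draw_pairs(250, sigma_T = 4, sigma_m = 1, mu_b = 4.16,
                      sigma_b = 2.01)
  cmp <- bootstrap_icc_difference(below, above, n_boot = 2000, seed = 5)
  expect_gt(cmp$delta_obs, 0.3)
  expect_lt(cmp$p_value, 0.01)
})

test_that("bootstrap rejects undersized groups and tiny resample counts", {
  y <- draw_pairs(10)
  expect_error(bootstrap_icc_difference(y[1:2, ], y, n_boot = 500),
               class = "iapagree_insufficient_data_error")
  expect_error(bootstrap_icc_difference(y, y, n_boot = 50),
               class = "iapagree_validation_error")
})

test_that("proportional regression matches hand-computed sums", {
  fit <- fit_proportional_regression(cbind(fivp = c(10, 14, 8),
                                           cvp = c(10, 14, 8)))
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$r2, 1.0)
  # by hand: slope = 490/500, SS_res = 1.8, sum(cvp^2) = 482
  fit <- fit_proportional_regression(cbind(fivp = c(10, 20),
                                           cvp = c(11, 19)))
  expect_equal(fit$slope, 0.98)
  expect_equal(fit$r2, 1 - 1.8 / 482)
  expect_equal(fit$residual_sd, sqrt(1.8))
  expect_error(fit_proportional_regression(cbind(c(0, 0, 0), 1:3)),
               class = "iapagree_degenerate_data_error")
})

test_that("regression routes agree with stats::lm on random data", {
  set.seed(13)
  y <- draw_pairs(50)
  colnames(y) <- c("cvp", "fivp")
  pairs <- y[, c("fivp", "cvp")]
  fit <- fit_proportional_regression(pairs)
  lm0 <- stats::lm(cvp ~ 0 + fivp, data = as.data.frame(y))
  expect_equal(fit$slope, unname(coef(lm0)), tolerance = 1e-12)
  expect_equal(fit$r2, summary(lm0)$r.squared, tolerance = 1e-12)
  fit1 <- fit_proportional_regression(pairs, intercept = TRUE)
  lm1 <- stats::lm(cvp ~ fivp, data = as.data.frame(y))
  expect_equal(fit1$slope, unname(coef(lm1)[2]), tolerance = 1e-12)
  expect_equal(fit1$intercept, unname(coef(lm1)[1]), tolerance = 1e-12)
})

test_that("difference summary reports median, range and strict positives", {
  d <- difference_summary(cbind(fivp = c(11, 14, 17), cvp = c(10, 10, 10)))
  expect_equal(d$median_diff, 4)
  expect_equal(c(d$min_diff, d$max_diff), c(1, 7))
  expect_equal(d$fraction_positive, 1.0)
  # zero differences do not count as positive
  z <- difference_summary(cbind(fivp = c(5, 5), cvp = c(5, 5)))
  expect_equal(z$fraction_positive, 0.0)
  expect_equal(z$median_diff, 0)
  # even n uses the midpoint convention
  e <- difference_summary(cbind(fivp = c(11, 12, 15, 18),
                                cvp = c(10, 10, 10, 10)))
  expect_equal(e$median_diff, 3.5)
  expect_true(e$min_diff <= e$median_diff && e$median_diff <= e$max_diff)
})
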