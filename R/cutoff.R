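#' Intraclass-correlation profile across intra-abdominal pressure thresholds
#'
#' The core threshold scan: for every integer threshold `t` spanning the
#' observed IAP range, the one-way ICC is computed on the subset of sets
#' with IAP strictly below `t`. Subsets smaller than `n_min` give an
#' unstable ICC and are recorded as absent (`NA`). Thresholds run from
#' `ceiling(min(iap)) + 1` to `floor(max(iap)) + 1`, so the first scanned
#' subset can be nonempty and the last contains every set.
#'
#' @param sets Measurement-set data frame from [aggregate_replicates()]
#'   (columns `cvp`, `fivp`, `iap` required).
#' @param n_min Minimum subset size for a reportable ICC (default 10).
#' @param alpha Two-sided level for the per-threshold confidence intervals.
#' @return Object of class `cutoff_profile`: list with `entries` (data
#'   frame: `threshold`, `n_below`, `icc`, `ci_low`, `ci_high`, `label`),
#'   `estimates` (list of `icc_estimate` keyed by threshold), `n_min`,
#'   `alpha`, `scan_range`.
#' @examples
#' sim <- simulate_cohort(cohort_params(n_sets = 100, seed = 3))
#' prof <- icc_profile(aggregate_replicates(sim$records))
#' prof
#' @export
icc_profile <- function(sets, n_min = 10, alpha = 0.05) {
  for (col in c("cvp", "fivp", "iap"))
    if (!col %in% names(sets))
      stop_validation("sets must have column '%s'", col)
  if (nrow(sets) < n_min)
    stop_insufficient(
      "no threshold can reach the minimum subset size %d with %d sets",
      n_min, nrow(sets))
  thresholds <- seq.int(ceiling(min(sets$iap)) + 1L,
                        floor(max(sets$iap)) + 1L)
  estimates <- stats::setNames(vector("list", length(thresholds)),
                               as.character(thresholds))
  entries <- data.frame(threshold = thresholds,
                        n_below = NA_integer_, icc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        label = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(thresholds)) {
    sub <- sets[sets$iap < thresholds[j], , drop = FALSE]
    entries$n_below[j] <- nrow(sub)
    if (nrow(sub) < n_min) next
    est <- tryCatch(icc_oneway(sub[, c("cvp", "fivp")], alpha = alpha),
                    iapagree_degenerate_data_error = function(e) NULL)
    if (is.null(est)) next
    estimates[[j]] <- est
    entries$icc[j] <- est$icc
    entries$ci_low[j] <- est$ci_low
    entries$ci_high[j] <- est$ci_high
    entries$label[j] <- est$label
  }
  stopifnot(!is.unsorted(entries$n_below))  # nesting invariant
  if (all(is.na(entries$icc)))
    stop_insufficient(
      "no threshold yields a subset of at least %d sets with non-degenerate pairs",
      n_min)
  structure(list(entries = entries, estimates = estimates, n_min = n_min,
                 alpha = alpha, scan_range = range(sets$iap)),
            class = "cutoff_profile")
}

#' Select the best intra-abdominal pressure cutoff from an ICC profile
#'
#' Three selection rules are available. `"ci-band"` (default) treats every
#' threshold whose subset ICC lies within the confidence interval of the
#' profile maximum as statistically tied with it, and returns the largest
#' such threshold: below-threshold subsets are nested estimates of the
#' same population ICC wherever agreement is unimpaired, so among
#' statistically equivalent candidates the one retaining the most data is
#' preferred. `"argmax"` is the strict rule — the threshold with the
#' single highest ICC, exact ties broken toward the largest threshold; it
#' is noise-sensitive because small early subsets have the most variable
#' estimates, and the running maximum of nested noisy estimates is biased
#' toward them. `"excellent-threshold"` returns the largest threshold
#' whose below-threshold ICC still exceeds 0.8 (the Landis-Koch
#' "excellent" boundary).
#'
#' @param profile A [icc_profile()] result.
#' @param rule `"ci-band"`, `"argmax"` or `"excellent-threshold"`.
#' @return Object of class `cutoff_result`: list with `best_threshold`,
#'   `rule`, `icc_at_best` (an `icc_estimate`).
#' @export
best_cutoff <- function(profile,
                        rule = c("ci-band", "argmax",
                                 "excellent-threshold")) {
  rule <- match.arg(rule)
  if (!inherits(profile, "cutoff_profile"))
    stop_validation("profile must be a cutoff_profile")
  e <- profile$entries
  valid <- which(!is.na(e$icc))
  if (length(valid) == 0L)
    stop_insufficient("profile has no valid entries")
  if (rule == "ci-band") {
    jmax <- valid[which.max(e$icc[valid])]
    pick <- valid[e$icc[valid] >= e$ci_low[jmax]]
    j <- pick[length(pick)]  # largest statistically tied threshold
  } else if (rule == "argmax") {
    best <- max(e$icc[valid])
    pick <- valid[e$icc[valid] >= best - 1e-12]
    j <- pick[length(pick)]  # tie -> largest threshold
  } else {
    pick <- valid[e$icc[valid] > 0.8]
    if (length(pick) == 0L)
      stop_insufficient("no threshold reaches ICC > 0.8 under rule '%s'",
                        rule)
    j <- pick[length(pick)]
  }
  structure(list(best_threshold = e$threshold[j], rule = rule,
                 icc_at_best = profile$estimates[[j]]),
            class = "cutoff_result")
}

#' Bootstrap test for a difference between two group ICCs
#'
#' Tests whether the one-way ICC differs between the below-cutoff and
#' above-cutoff measurement sets. The resampling unit is the measurement
#' set; each group is resampled with replacement independently (stratified
#' bootstrap). The two-sided p-value uses the symmetric percentile method
#' with a +1 continuity correction:
#' \deqn{p = 2 \min(\#\{\Delta^* \le 0\} + 1, \#\{\Delta^* \ge 0\} + 1)
#'       /(B + 1),} capped at 1. Degenerate resamples (all values
#' identical, ICC undefined) are redrawn; more than `100 * n_boot`
#' attempts raises an error.
#'
#' @param below,above Two-column pair containers (cvp, fivp), one row per
#'   set, for the two IAP strata.
#' @param n_boot Number of bootstrap resamples (>= 100; default 2000).
#' @param alpha Level recorded for downstream reporting.
#' @param seed RNG seed for reproducibility (`NULL` = current stream).
#' @return Object of class `bootstrap_comparison`: list with `delta_obs`
#'   (ICC below minus ICC above), `p_value`, `n_boot`, `seed`, `n_below`,
#'   `n_above`, `alpha`.
#' @examples
#' sim <- simulate_cohort(cohort_params(n_sets = 120, seed = 7))
#' sets <- aggregate_replicates(sim$records)
#' lo <- sets[sets$iap < 14, c("cvp", "fivp")]
#' hi <- sets[sets$iap >= 14, c("cvp", "fivp")]
#' bootstrap_icc_difference(lo, hi, n_boot = 200, seed = 1)
#' @export
bootstrap_icc_difference <- function(below, above, n_boot = 2000,
                                     alpha = 0.05, seed = NULL) {
  yb <- as_pair_matrix(below, c("cvp", "fivp"))
  ya <- as_pair_matrix(above, c("cvp", "fivp"))
  if (nrow(yb) < 3L || nrow(ya) < 3L)
    stop_insufficient("each group needs at least 3 pairs (got %d and %d)",
                      nrow(yb), nrow(ya))
  if (n_boot < 100)
    stop_validation("n_boot must be at least 100, got %s",
                    format(n_boot))
  delta_obs <- icc_point(yb) - icc_point(ya)
  with_seed(seed, {
    deltas <- numeric(n_boot)
    attempts <- 0L
    max_attempts <- 100 * n_boot
    b <- 1L
    while (b <= n_boot) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_degenerate(
          "bootstrap exceeded %d attempts due to degenerate resamples",
          max_attempts)
      ib <- icc_point(yb[sample.int(nrow(yb), replace = TRUE), ,
                         drop = FALSE])
      ia <- icc_point(ya[sample.int(nrow(ya), replace = TRUE), ,
                         drop = FALSE])
      if (is.na(ib) || is.na(ia)) next
      deltas[b] <- ib - ia
      b <- b + 1L
    }
    p <- 2 * min(sum(deltas <= 0) + 1L, sum(deltas >= 0) + 1L) /
      (n_boot + 1)
    structure(list(delta_obs = delta_obs, p_value = min(1, p),
                   n_boot = as.integer(n_boot), seed = seed,
                   n_below = nrow(yb), n_above = nrow(ya), alpha = alpha),
              class = "bootstrap_comparison")
  })
}

#' Proportional (through-the-origin) calibration regression
#'
#' Fits `cvp = slope * fivp` by least squares through the origin, the
#' calibration model under which one site's reading is read directly as a
#' proportional surrogate for the other:
#' \deqn{slope = \sum x_i y_i / \sum x_i^2, \qquad
#'       R^2_{uncentered} = 1 - \sum (y_i - slope\, x_i)^2 / \sum y_i^2.}
#' The uncentered R-squared is the natural fit measure for a no-intercept
#' model; for pressures far from zero it runs higher than the centered
#' version. Set `intercept = TRUE` for an ordinary two-parameter fit
#' (reported with centered R-squared).
#'
#' @param pairs Two-column container (`fivp`, `cvp`): predictor first.
#' @param intercept Fit an intercept as well (default `FALSE`).
#' @return Object of class `regression_fit`: list with `slope`,
#'   `intercept` (0 for the proportional fit), `r2` (uncentered for the
#'   proportional fit), `n`, `residual_sd` (mmHg, `n - 1` denominator for
#'   the one-parameter fit).
#' @examples
#' fit_proportional_regression(cbind(fivp = c(10, 20), cvp = c(11, 19)))
#' @export
fit_proportional_regression <- function(pairs, intercept = FALSE) {
  y <- as_pair_matrix(pairs, c("fivp", "cvp"))
  x <- y[, 1L]; cvp <- y[, 2L]
  n <- length(x)
  if (n < 2L) stop_insufficient("regression requires at least 2 pairs")
  if (intercept) {
    fit <- stats::lm(cvp ~ x)
    res <- stats::residuals(fit)
    return(structure(list(slope = unname(stats::coef(fit)[2L]),
                          intercept = unname(stats::coef(fit)[1L]),
                          r2 = summary(fit)$r.squared, n = n,
                          residual_sd = sqrt(sum(res^2) / (n - 2))),
                     class = "regression_fit"))
  }
  sxx <- sum(x^2)
  if (sxx == 0) stop_degenerate("all predictor (fivp) values are zero")
  slope <- sum(x * cvp) / sxx
  res <- cvp - slope * x
  r2 <- 1 - sum(res^2) / sum(cvp^2)
  structure(list(slope = slope, intercept = 0, r2 = r2, n = n,
                 residual_sd = sqrt(sum(res^2) / (n - 1))),
            class = "regression_fit")
}

#' Summarize FIVP minus CVP differences
#'
#' Reports the median (midpoint convention for even n), minimum and
#' maximum of `d = fivp - cvp`, and the fraction of sets with strictly
#' positive difference — the quantities used to characterize the
#' above-cutoff overestimation of CVP by FIVP.
#'
#' @param pairs Two-column container (`fivp`, `cvp`).
#' @return Object of class `difference_summary`: list with `median_diff`,
#'   `min_diff`, `max_diff` (mmHg), `fraction_positive`, `n`.
#' @examples
#' difference_summary(cbind(fivp = c(11, 14, 17), cvp = c(10, 10, 10)))
#' @export
difference_summary <- function(pairs) {
  y <- as_pair_matrix(pairs, c("fivp", "cvp"))
  if (nrow(y) < 1L) stop_insufficient("at least one pair required")
  d <- y[, 1L] - y[, 2L]
  structure(list(median_diff = stats::median(d), min_diff = min(d),
                 max_diff = max(d), fraction_positive = mean(d > 0),
                 n = length(d)),
            class = "difference_summary")
}

#' @export
print.cutoff_profile <- function(x, ...) {
  cat(sprintf(
    "ICC profile over IAP thresholds %d..%d (subset: IAP < t; n_min = %d)\n",
    min(x$entries$threshold), max(x$entries$threshold), x$n_min))
  print(x$entries, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Best IAP cutoff: %g mmHg (rule: %s)\n", x$best_threshold,
              x$rule))
  print(x$icc_at_best)
  invisible(x)
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "Bootstrap ICC difference: delta = %.3f (below n=%d vs above n=%d), p = %.4g (B = %d)\n",
    x$delta_obs, x$n_below, x$n_above, x$p_value, x$n_boot))
  invisible(x)
}

#' @export
print.regression_fit <- function(x, ...) {
  if (x$intercept == 0)
    cat(sprintf("CVP = %.3f FIVP  (uncentered R^2 = %.4f, n = %d, residual s.d. = %.2f mmHg)\n",
                x$slope, x$r2, x$n, x$residual_sd))
  else
    cat(sprintf("CVP = %.3f + %.3f FIVP  (R^2 = %.4f, n = %d)\n",
                x$intercept, x$slope, x$r2, x$n))
  invisible(x)
}

#' @export
print.difference_summary <- function(x, ...) {
  cat(sprintf(
    "FIVP - CVP: median %.2f (range %.2f to %.2f) mmHg; %.0f%% strictly positive (n = %d)\n",
    x$median_diff, x$min_diff, x$max_diff, 100 * x$fraction_positive, x$n))
  invisible(x)
}
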