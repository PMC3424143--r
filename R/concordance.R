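#' Aggregate replicate readings into measurement sets
#'
#' Each measurement session records the three pressures (CVP, FIVP, IAP)
#' several times (typically four readings at 5-minute intervals); the
#' analysis unit is the per-session mean of each site. Sets missing an
#' entire site cannot enter the paired analysis and are dropped with a
#' warning.
#'
#' @param records Data frame of raw replicate readings with columns
#'   `subject_id`, `set_id`, `site` (one of `"CVP"`, `"FIVP"`, `"IAP"`,
#'   case-insensitive), `replicate` and `value_mmHg`.
#' @return Data frame of measurement sets, one row per `set_id`, ordered by
#'   `set_id`, with columns `set_id`, `subject_id`, `cvp`, `fivp`, `iap`
#'   (mmHg, per-site replicate means) and `n_reps_cvp`, `n_reps_fivp`,
#'   `n_reps_iap` (replicates averaged per site).
#' @examples
#' rec <- data.frame(
#'   subject_id = "P1", set_id = "S1",
#'   site = rep(c("CVP", "FIVP", "IAP"), each = 4),
#'   replicate = rep(1:4, 3),
#'   value_mmHg = c(8, 9, 10, 9, 9, 10, 11, 10, 7, 7, 7, 7))
#' aggregate_replicates(rec)
#' @seealso [icc_oneway()], [read_measurements()]
#' @export
aggregate_replicates <- function(records) {
  required <- c("subject_id", "set_id", "site", "replicate", "value_mmHg")
  if (!all(required %in% names(records)))
    stop_validation("records must have columns: %s",
                    paste(required, collapse = ", "))
  if (nrow(records) == 0L)
    return(data.frame(set_id = character(), subject_id = character(),
                      cvp = double(), fivp = double(), iap = double(),
                      n_reps_cvp = integer(), n_reps_fivp = integer(),
                      n_reps_iap = integer(), stringsAsFactors = FALSE))
  if (!is.numeric(records$value_mmHg)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$value_mmHg))))
    stop_validation("non-numeric value_mmHg at row(s): %s",
                    paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(!is.finite(records$value_mmHg)))
    stop_validation("non-finite value_mmHg at row(s): %s",
                    paste(utils::head(which(!is.finite(records$value_mmHg)), 5L),
                          collapse = ", "))
  site <- toupper(as.character(records$site))
  ok <- site %in% c("CVP", "FIVP", "IAP")
  if (any(!ok))
    stop_validation("unknown site token '%s' at row %d",
                    records$site[which(!ok)[1L]], which(!ok)[1L])

  set_id <- as.character(records$set_id)
  set_f <- factor(set_id)                      # levels sorted by set_id
  site_f <- factor(site, levels = c("CVP", "FIVP", "IAP"))
  means <- tapply(records$value_mmHg, list(set_f, site_f), mean)
  counts <- tapply(records$value_mmHg, list(set_f, site_f), length)
  counts[is.na(counts)] <- 0L
  subject <- as.character(records$subject_id)[!duplicated(set_f)]
  subject <- subject[order(set_id[!duplicated(set_f)])]
  complete <- !apply(is.na(means), 1L, any)
  for (sid in rownames(means)[!complete])
    warning(sprintf("set '%s' is missing site(s) %s; dropped", sid,
                    paste(colnames(means)[is.na(means[sid, ])],
                          collapse = ", ")),
            call. = FALSE)
  out <- data.frame(set_id = rownames(means)[complete],
                    subject_id = subject[complete],
                    cvp = unname(means[complete, "CVP"]),
                    fivp = unname(means[complete, "FIVP"]),
                    iap = unname(means[complete, "IAP"]),
                    n_reps_cvp = as.integer(counts[complete, "CVP"]),
                    n_reps_fivp = as.integer(counts[complete, "FIVP"]),
                    n_reps_iap = as.integer(counts[complete, "IAP"]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(aggregate_replicates(records[0, required]))
  rownames(out) <- NULL
  out
}

# Point estimate only; shared by the bootstrap inner loop where building the
# full estimate object per resample would dominate the cost.
icc_point <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  row_means <- rowMeans(y)
  grand <- mean(y)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((y - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) return(NA_real_)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' One-way random-effects intraclass correlation for paired measurements
#'
#' Estimates the single-measurement one-way random-effects ICC, ICC(1,1) in
#' the Shrout-Fleiss taxonomy, treating the two catheter sites as
#' interchangeable measurements of one latent pressure. Under this model a
#' systematic between-site offset inflates the within-set mean square and is
#' therefore counted as disagreement, which is exactly the mechanism by which
#' raised intra-abdominal pressure degrades CVP/FIVP concordance.
#'
#' With per-set means \eqn{\bar y_i} and grand mean \eqn{\bar y}:
#' \deqn{MSB = k \sum_i (\bar y_i - \bar y)^2/(n-1), \quad
#'       MSW = \sum_{ij} (y_{ij} - \bar y_i)^2 / (n(k-1)),}
#' \deqn{ICC = (MSB - MSW)/(MSB + (k-1) MSW).}
#' Negative estimates are reported as-is, never clamped at zero. The
#' confidence interval is the exact F-based (Searle) interval from
#' [icc_ci()].
#'
#' @param pairs Two-column numeric matrix or data frame, one row per
#'   measurement set (columns `cvp`, `fivp` when named).
#' @param alpha Two-sided error level for the confidence interval
#'   (default 0.05 for a 95% CI).
#' @return An object of class `icc_estimate`: a list with elements `icc`,
#'   `ci_low`, `ci_high`, `msb`, `msw`, `n`, `k`, `alpha` and `label`
#'   (Landis-Koch category).
#' @examples
#' icc_oneway(cbind(c(10, 14, 8, 12), c(12, 13, 9, 10)))
#' @references Shrout PE, Fleiss JL (1979) Intraclass correlations: uses in
#'   assessing rater reliability. Psychol Bull 86:420-428.
#' @export
icc_oneway <- function(pairs, alpha = 0.05) {
  y <- as_pair_matrix(pairs, c("cvp", "fivp"))
  n <- nrow(y)
  if (n < 3L)
    stop_insufficient("ICC requires at least 3 pairs, got %d", n)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be a single value in (0, 1)")
  k <- ncol(y)
  row_means <- rowMeans(y)
  grand <- mean(y)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((y - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0)
    stop_degenerate("all %d values are identical; ICC undefined", n * k)
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  ci <- icc_ci(msb, msw, n, k, alpha)
  structure(list(icc = icc, ci_low = ci[[1L]], ci_high = ci[[2L]],
                 msb = msb, msw = msw, n = n, k = k, alpha = alpha,
                 label = landis_koch_label(icc)),
            class = "icc_estimate")
}

#' Exact F-based confidence interval for the one-way ICC
#'
#' Exact interval for the one-way random-effects single-measurement ICC
#' (Searle 1971), built from the observed F ratio \eqn{F = MSB/MSW} and
#' F quantiles on \eqn{(n-1, n(k-1))} degrees of freedom:
#' \deqn{L = \frac{F/F_{1-\alpha/2} - 1}{F/F_{1-\alpha/2} + k - 1}, \qquad
#'       U = \frac{F/F_{\alpha/2} - 1}{F/F_{\alpha/2} + k - 1}.}
#' Both bounds are clamped to \eqn{[-1, 1]}.
#'
#' @param msb,msw Between-set and within-set mean squares (mmHg^2).
#' @param n Number of sets (rows). @param k Measurements per set.
#' @param alpha Two-sided error level.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' icc_ci(msb = 19, msw = 1, n = 15, k = 2, alpha = 0.05)
#' @references Searle SR (1971) Linear Models. Wiley.
#' @export
icc_ci <- function(msb, msw, n, k, alpha = 0.05) {
  if (n < 3L) stop_insufficient("interval requires n >= 3, got %d", n)
  if (msw < 0 || msb < 0) stop_validation("mean squares must be nonnegative")
  if (msw == 0) {
    warning("within-set mean square is 0; degenerate interval (1, 1)",
            call. = FALSE)
    return(c(ci_low = 1, ci_high = 1))
  }
  f_obs <- msb / msw
  df1 <- n - 1
  df2 <- n * (k - 1)
  f_l <- stats::qf(1 - alpha / 2, df1, df2)
  f_u <- stats::qf(alpha / 2, df1, df2)
  low <- (f_obs / f_l - 1) / (f_obs / f_l + k - 1)
  high <- (f_obs / f_u - 1) / (f_obs / f_u + k - 1)
  c(ci_low = max(-1, min(1, low)), ci_high = max(-1, min(1, high)))
}

#' Landis-Koch qualitative label for an agreement coefficient
#'
#' Bins (lower-exclusive): poor (<= 0), slight (0, 0.2], fair (0.2, 0.4],
#' moderate (0.4, 0.6], substantial (0.6, 0.8], excellent (0.8, 1]. The top
#' bin is labelled "excellent" (the common clinical alias of Landis and
#' Koch's "almost perfect"); an estimate of exactly 0.8 is "substantial"
#' since "excellent" requires strictly more than 0.8.
#'
#' @param icc Agreement coefficient in (-1, 1].
#' @return Character label.
#' @examples
#' landis_koch_label(0.94)  # "excellent"
#' landis_koch_label(0.8)   # "substantial"
#' @references Landis JR, Koch GG (1977) The measurement of observer
#'   agreement for categorical data. Biometrics 33:159-174.
#' @export
landis_koch_label <- function(icc) {
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc) ||
      icc <= -1 || icc > 1)
    stop_validation("icc must be a single value in (-1, 1]")
  if (icc <= 0) return("poor")
  if (icc <= 0.2) return("slight")
  if (icc <= 0.4) return("fair")
  if (icc <= 0.6) return("moderate")
  if (icc <= 0.8) return("substantial")
  "excellent"
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("One-way ICC(1,1): %.3f  %d%% CI [%.3f, %.3f]  (%s)\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$label))
  cat(sprintf("  n = %d sets, k = %d; MSB = %.4g, MSW = %.4g mmHg^2\n",
              x$n, x$k, x$msb, x$msw))
  invisible(x)
}
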