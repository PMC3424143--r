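# Independent oracles and small fixture builders used across test files.

# One-way ANOVA ICC computed through stats::aov on the long layout — a code
# path fully independent of the package's pooled-sum computation.
icc_anova_oracle <- function(y) {
  d <- data.frame(v = as.vector(t(y)),
                  g = factor(rep(seq_len(nrow(y)), each = ncol(y))))
  tab <- stats::anova(stats::aov(v ~ g, data = d))
  msb <- tab$`Mean Sq`[1L]
  msw <- tab$`Mean Sq`[2L]
  (msb - msw) / (msb + (ncol(y) - 1) * msw)
}

# Paired draws from the one-way model (latent value + independent site
# noise), optionally with a site-2 offset; plain rnorm, no package code.
draw_pairs <- function(n, sigma_T = 4, sigma_m = 1, mu = 10,
                       mu_b = 0, sigma_b = 0) {
  t <- stats::rnorm(n, mu, sigma_T)
  b <- if (mu_b == 0 && sigma_b == 0) 0 else stats::rnorm(n, mu_b, sigma_b)
  cbind(cvp = t + stats::rnorm(n, 0, sigma_m),
        fivp = t + b + stats::rnorm(n, 0, sigma_m))
}

# Long-format replicate records for one measurement set.
records_for_set <- function(set_id, cvp, fivp, iap, subject_id = set_id) {
  r <- max(length(cvp), length(fivp), length(iap))
  data.frame(
    subject_id = subject_id, set_id = set_id,
    site = rep(c("CVP", "FIVP", "IAP"), times = c(length(cvp),
                                                  length(fivp),
                                                  length(iap))),
    replicate = c(seq_along(cvp), seq_along(fivp), seq_along(iap)),
    value_mmHg = c(cvp, fivp, iap),
    stringsAsFactors = FALSE)
}

# Hand-built cutoff profile for selection-rule unit tests.
fake_profile <- function(thresholds, icc, ci_low, ci_high, n_below) {
  est <- lapply(seq_along(thresholds), function(j) {
    if (is.na(icc[j])) return(NULL)
    structure(list(icc = icc[j], ci_low = ci_low[j], ci_high = ci_high[j],
                   msb = NA_real_, msw = NA_real_, n = n_below[j], k = 2L,
                   alpha = 0.05,
                   label = landis_koch_label(icc[j])),
              class = "icc_estimate")
  })
  structure(list(
    entries = data.frame(threshold = thresholds, n_below = n_below,
                         icc = icc, ci_low = ci_low, ci_high = ci_high,
                         label = NA_character_),
    estimates = est, n_min = 3L, alpha = 0.05,
    scan_range = range(thresholds)),
    class = "cutoff_profile")
}
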