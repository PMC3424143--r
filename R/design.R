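#' Expected lower confidence bound for a planned ICC study
#'
#' Sample-size reasoning for a reliability study: assuming the observed
#' ICC equals the planned value `rho`, the observed F ratio is
#' \eqn{F = 1 + k\rho/(1-\rho)}, and the exact F-based lower bound of the
#' two-sided `1 - alpha` interval follows from [icc_ci()]. For a planned
#' ICC of 0.90 with paired measurements (`k = 2`), 15 subjects already
#' push the lower 95% bound above 0.70.
#'
#' @param rho Planned ICC in (0, 1).
#' @param n Number of subjects (>= 3).
#' @param k Measurements per subject (>= 2).
#' @param alpha Two-sided level.
#' @return Expected lower confidence bound (scalar).
#' @examples
#' icc_lower_bound_at_n(0.9, n = 15, k = 2)  # about 0.736
#' @export
icc_lower_bound_at_n <- function(rho, n, k = 2, alpha = 0.05) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop_validation("rho must be in (0, 1)")
  if (k < 2) stop_validation("k must be >= 2")
  if (n < 3) stop_insufficient("n must be >= 3, got %s", format(n))
  f_obs <- 1 + k * rho / (1 - rho)
  unname(icc_ci(msb = f_obs, msw = 1, n = n, k = k, alpha = alpha)[1L])
}

#' Smallest study size meeting an ICC lower-bound requirement
#'
#' Ascending linear search for the smallest `n <= n_max` whose expected
#' lower bound ([icc_lower_bound_at_n()]) reaches `lower_target`; the
#' bound is monotone increasing in `n`, so the first hit is the minimum.
#'
#' @param rho Planned ICC in (0, 1).
#' @param lower_target Required lower confidence bound, in (0, rho).
#' @param k Measurements per subject.
#' @param alpha Two-sided level.
#' @param n_max Search limit (default 1000).
#' @return List with `n` (smallest qualifying size), `lower_bound` (the
#'   bound at that n), `rho`, `k`, `alpha`, `lower_target`.
#' @examples
#' min_n_for_lower_bound(0.9, lower_target = 0.70)
#' @export
min_n_for_lower_bound <- function(rho, lower_target, k = 2, alpha = 0.05,
                                  n_max = 1000) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop_validation("rho must be in (0, 1)")
  if (!is.numeric(lower_target) || length(lower_target) != 1L ||
      lower_target <= 0 || lower_target >= rho)
    stop_validation("lower_target must satisfy 0 < lower_target < rho")
  if (n_max < 3) stop_validation("n_max must be >= 3")
  for (n in 3:n_max) {
    b <- icc_lower_bound_at_n(rho, n, k, alpha)
    if (b >= lower_target)
      return(list(n = n, lower_bound = b, rho = rho, k = k, alpha = alpha,
                  lower_target = lower_target))
  }
  stop_infeasible(
    "no n <= %d reaches lower bound %.4g (bound at n_max is %.4g)",
    n_max, lower_target, icc_lower_bound_at_n(rho, n_max, k, alpha))
}
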