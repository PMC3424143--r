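#' Read a measurement table from CSV
#'
#' Two dialects are accepted. Long format has one row per replicate
#' reading: `subject_id`, `set_id`, `site` (CVP/FIVP/IAP,
#' case-insensitive), `replicate`, `value_mmHg`. Wide format has one row
#' per averaged measurement set: `set_id`, `subject_id`, `cvp_mmHg`,
#' `fivp_mmHg`, `iap_mmHg`, and is expanded to one replicate record per
#' site. All pressures are mmHg; files are UTF-8 CSV with a header and
#' "." decimal separator.
#'
#' @param path Path to the CSV file.
#' @param format `"long"` or `"wide"`.
#' @return Data frame of measurement records (long layout).
#' @seealso [write_measurements()], [aggregate_replicates()]
#' @export
read_measurements <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    required <- c("subject_id", "set_id", "site", "replicate", "value_mmHg")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L)
      stop_validation("long-format header lacks column(s): %s",
                      paste(missing, collapse = ", "))
    num <- suppressWarnings(as.numeric(df$value_mmHg))
    if (anyNA(num))
      stop_validation("non-numeric value_mmHg at data row %d (column value_mmHg)",
                      which(is.na(num))[1L])
    df$value_mmHg <- num
    df$site <- toupper(as.character(df$site))
    bad <- !df$site %in% c("CVP", "FIVP", "IAP")
    if (any(bad))
      stop_validation("unknown site token '%s' at data row %d (column site)",
                      df$site[which(bad)[1L]], which(bad)[1L])
    key <- paste(df$set_id, df$site, df$replicate, sep = "\r")
    if (anyDuplicated(key))
      stop_validation("duplicate (set_id, site, replicate) at data row %d",
                      which(duplicated(key))[1L])
    return(df[, required])
  }
  required <- c("set_id", "subject_id", "cvp_mmHg", "fivp_mmHg", "iap_mmHg")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_validation("wide-format header lacks column(s): %s",
                    paste(missing, collapse = ", "))
  for (col in c("cvp_mmHg", "fivp_mmHg", "iap_mmHg")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(num))
      stop_validation("non-numeric pressure at data row %d (column %s)",
                      which(is.na(num))[1L], col)
    df[[col]] <- num
  }
  if (anyDuplicated(df$set_id))
    stop_validation("duplicate set_id at data row %d",
                    which(duplicated(df$set_id))[1L])
  n <- nrow(df)
  data.frame(
    subject_id = rep(as.character(df$subject_id), 3L),
    set_id = rep(as.character(df$set_id), 3L),
    site = rep(c("CVP", "FIVP", "IAP"), each = n),
    replicate = 1L,
    value_mmHg = c(df$cvp_mmHg, df$fivp_mmHg, df$iap_mmHg),
    stringsAsFactors = FALSE)
}

#' Write measurement records or cohort truths to CSV
#'
#' `write_measurements()` writes the long-format replicate table consumed
#' by [read_measurements()]; `write_truths()` writes the per-set latent
#' state emitted by [simulate_cohort()].
#'
#' @param records,truths Data frames as produced by [simulate_cohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
write_truths <- function(truths, path) {
  utils::write.csv(truths, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Configuration of the end-to-end analysis
#'
#' Collects and validates the tunables of [run_full_analysis()]:
#' confidence level, minimum subset size in the threshold scan, bootstrap
#' resamples, the cutoff selection rule, and whether the calibration
#' regression goes through the origin.
#'
#' @param alpha Two-sided confidence/test level.
#' @param n_min Minimum subset size for a reportable profile ICC.
#' @param n_boot Bootstrap resamples (>= 100).
#' @param seed RNG seed for the bootstrap.
#' @param cutoff_rule `"ci-band"`, `"argmax"` or `"excellent-threshold"`
#'   (see [best_cutoff()]).
#' @param regression_through_origin Proportional calibration fit if `TRUE`
#'   (default), ordinary intercept fit otherwise.
#' @param input_format CSV dialect expected by the pipeline.
#' @return Validated list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, n_min = 10, n_boot = 2000,
                            seed = 1L,
                            cutoff_rule = c("ci-band", "argmax",
                                            "excellent-threshold"),
                            regression_through_origin = TRUE,
                            input_format = c("long", "wide")) {
  cutoff_rule <- match.arg(cutoff_rule)
  input_format <- match.arg(input_format)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be in (0, 1)")
  if (!is.numeric(n_min) || n_min < 3)
    stop_validation("n_min must be at least 3")
  if (!is.numeric(n_boot) || n_boot < 100)
    stop_validation("n_boot must be at least 100, got %s", format(n_boot))
  structure(list(alpha = alpha, n_min = as.integer(n_min),
                 n_boot = as.integer(n_boot), seed = seed,
                 cutoff_rule = cutoff_rule,
                 regression_through_origin = isTRUE(regression_through_origin),
                 input_format = input_format),
            class = "analysis_config")
}

input_digest <- function(records) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(records[order(records$set_id, records$site,
                                 records$replicate), ],
                   tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full agreement analysis pipeline
#'
#' Orchestrates the complete analysis of a measurement table: replicate
#' aggregation, the ICC-vs-IAP-threshold profile, best-cutoff selection,
#' per-stratum ICC at the selected cutoff (IAP strictly below vs at or
#' above), the stratified bootstrap test of the ICC difference, the
#' proportional calibration regression on the below-cutoff stratum, and
#' the FIVP-CVP difference summary on the above-cutoff stratum.
#' Deterministic given `config$seed`.
#'
#' @param records Long-format measurement records (from
#'   [read_measurements()] or [simulate_cohort()]).
#' @param config An [analysis_config()].
#' @return Object of class `analysis_report`: list with `profile`,
#'   `cutoff`, `icc_below`, `icc_above`, `comparison`,
#'   `regression_below`, `differences_above`, `sets` (the aggregated
#'   table) and `provenance` (config, input digest, package version).
#' @examples
#' sim <- simulate_cohort(cohort_params(n_sets = 120, seed = 11))
#' rep <- run_full_analysis(sim$records, analysis_config(n_boot = 200))
#' rep
#' @export
run_full_analysis <- function(records, config = analysis_config()) {
  if (!inherits(config, "analysis_config"))
    stop_validation("config must be an analysis_config")
  stage <- function(name, expr) {
    tryCatch(expr, iapagree_error = function(e) {
      stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                          class = class(e)))
    })
  }
  sets <- stage("aggregate", aggregate_replicates(records))
  profile <- stage("profile",
                   icc_profile(sets, n_min = config$n_min,
                               alpha = config$alpha))
  cutoff <- stage("cutoff", best_cutoff(profile, rule = config$cutoff_rule))
  t_best <- cutoff$best_threshold
  below <- sets[sets$iap < t_best, , drop = FALSE]
  above <- sets[sets$iap >= t_best, , drop = FALSE]
  icc_below <- stage("icc_below",
                     icc_oneway(below[, c("cvp", "fivp")], config$alpha))
  icc_above <- stage("icc_above",
                     icc_oneway(above[, c("cvp", "fivp")], config$alpha))
  comparison <- stage("bootstrap", bootstrap_icc_difference(
    below[, c("cvp", "fivp")], above[, c("cvp", "fivp")],
    n_boot = config$n_boot, alpha = config$alpha, seed = config$seed))
  regression_below <- stage("regression", fit_proportional_regression(
    below[, c("fivp", "cvp")],
    intercept = !config$regression_through_origin))
  differences_above <- stage("differences",
                             difference_summary(above[, c("fivp", "cvp")]))
  structure(list(profile = profile, cutoff = cutoff,
                 icc_below = icc_below, icc_above = icc_above,
                 comparison = comparison,
                 regression_below = regression_below,
                 differences_above = differences_above,
                 sets = sets,
                 provenance = list(
                   config = unclass(config),
                   input_digest = input_digest(records),
                   n_records = nrow(records), n_sets = nrow(sets),
                   package_version =
                     as.character(utils::packageVersion("iapagree")))),
            class = "analysis_report")
}

icc_as_list <- function(est) {
  est[c("icc", "ci_low", "ci_high", "msb", "msw", "n", "k", "alpha",
        "label")]
}

#' Serialize an analysis report to JSON
#'
#' Writes the full report (profile table, cutoff, stratum ICCs, bootstrap
#' comparison, regression, difference summary, provenance) as JSON. The
#' output carries no timestamps, so identical inputs and seed give
#' byte-identical files.
#'
#' @param report An [run_full_analysis()] result.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    profile = report$profile$entries,
    scan_range = report$profile$scan_range,
    n_min = report$profile$n_min,
    cutoff = list(best_threshold = report$cutoff$best_threshold,
                  rule = report$cutoff$rule,
                  icc_at_best = icc_as_list(report$cutoff$icc_at_best)),
    icc_below = icc_as_list(report$icc_below),
    icc_above = icc_as_list(report$icc_above),
    comparison = unclass(report$comparison),
    regression_below = unclass(report$regression_below),
    differences_above = unclass(report$differences_above),
    provenance = report$provenance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write the ICC-vs-threshold profile as TSV
#'
#' @param profile A [icc_profile()] result (or full report).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "analysis_report")) profile <- profile$profile
  if (!inherits(profile, "cutoff_profile"))
    stop_validation("profile must be a cutoff_profile or analysis_report")
  utils::write.table(profile$entries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Paired venous pressure agreement analysis (%d sets)\n",
              nrow(x$sets)))
  cat(sprintf("Best IAP cutoff: %g mmHg (rule: %s)\n",
              x$cutoff$best_threshold, x$cutoff$rule))
  cat("Below cutoff:  "); print(x$icc_below)
  cat("Above cutoff:  "); print(x$icc_above)
  print(x$comparison)
  cat("Calibration (below cutoff): "); print(x$regression_below)
  cat("Bias (above cutoff):        "); print(x$differences_above)
  invisible(x)
}
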