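#' Tabulate rule-confirmed pattern matches by toxicity and dose
#'
#' Builds the per-compound toxicity count table: for each toxicity category,
#' the number of MoA patterns that (1) are rule-confirmed at either dose and
#' (2) match the treatment at the given dose with a median correlation
#' strictly greater than `correlation_floor`. Confirmation is a
#' pattern-level (either-dose) gate, while the per-dose floor assigns
#' columns — so a pattern confirmed only at one dose can still appear in the
#' other dose's column if its correlation there clears the floor. Patterns
#' whose provenance includes the test compound itself are counted but listed
#' in the table's annotations (circularity flags), mirroring the footnote
#' convention of reference-database reports.
#'
#' @param matches_by_dose Named list: dose label -> `pattern_ranking` with
#'   `confirmed` flags set (see [confirm_matches()]).
#' @param pattern_toxicity Named character vector mapping every pattern id
#'   to its toxicity label, or a data frame with columns `pattern_id`,
#'   `toxicity_label`.
#' @param correlation_floor Strict per-dose floor on the median correlation
#'   (default 0.5).
#' @param patterns Optional list of [moa_pattern()] objects, used together
#'   with `test_compound` to flag circular references.
#' @param test_compound Optional compound id of the profiled treatment.
#' @return A tibble of class `toxicity_table` with one row per toxicity and
#'   one count column per dose; the grand totals, annotations and floor are
#'   attached as attributes.
#' @export
tabulate_toxicities <- function(matches_by_dose, pattern_toxicity,
                                correlation_floor = 0.5,
                                patterns = NULL, test_compound = NULL) {
  if (length(matches_by_dose) == 0 || is.null(names(matches_by_dose))) {
    stop_moamatch("`matches_by_dose` must be a named list of pattern rankings.",
                  "config_error")
  }
  if (is.data.frame(pattern_toxicity)) {
    pattern_toxicity <- setNames(pattern_toxicity$toxicity_label,
                                 pattern_toxicity$pattern_id)
  }
  doses <- names(matches_by_dose)
  all_matches <- purrr::imap_dfr(matches_by_dose, function(rk, d) {
    mutate(as_tibble(rk), dose = d)
  })
  unmapped <- setdiff(unique(all_matches$pattern_id), names(pattern_toxicity))
  if (length(unmapped)) {
    stop_moamatch(paste0("Pattern(s) without a toxicity mapping: ",
                         paste(unmapped, collapse = ", ")),
                  "mapping_error")
  }
  if (anyDuplicated(names(pattern_toxicity))) {
    dup <- unique(names(pattern_toxicity)[duplicated(names(pattern_toxicity))])
    stop_moamatch(paste0("Pattern(s) mapped to more than one toxicity: ",
                         paste(dup, collapse = ", ")),
                  "mapping_error")
  }

  confirmed_any <- all_matches %>%
    group_by(.data$pattern_id) %>%
    summarise(confirmed_any = any(.data$confirmed, na.rm = TRUE),
              .groups = "drop")
  counted <- all_matches %>%
    left_join(confirmed_any, by = "pattern_id") %>%
    filter(.data$confirmed_any,
           !is.na(.data$median_correlation),
           .data$median_correlation > correlation_floor) %>%
    mutate(toxicity = unname(pattern_toxicity[.data$pattern_id])) %>%
    distinct(.data$pattern_id, .data$dose, .data$toxicity)

  rows <- counted %>%
    dplyr::count(.data$toxicity, .data$dose) %>%
    tidyr::pivot_wider(names_from = "dose", values_from = "n",
                       values_fill = 0L)
  for (d in doses) if (!d %in% names(rows)) rows[[d]] <- 0L
  rows <- rows[, c("toxicity", doses)]
  rows <- arrange(rows, .data$toxicity)

  annotations <- character()
  if (!is.null(patterns) && !is.null(test_compound)) {
    prov <- purrr::map_dfr(patterns, function(p) {
      tibble(pattern_id = p$pattern_id,
             compound_id = p$provenance$compound_id %||% character())
    })
    circular <- unique(prov$pattern_id[prov$compound_id == test_compound])
    annotations <- intersect(unique(counted$pattern_id), circular)
  }
  gt <- grand_total(rows)
  structure(rows,
            grand_total = gt,
            annotations = annotations,
            correlation_floor = correlation_floor,
            compound_id = test_compound,
            class = c("toxicity_table", class(tibble())))
}

#' Grand totals of a toxicity count table
#'
#' Column-wise sums of the per-toxicity pattern-match counts — the "Grand
#' total" row of a toxicity table.
#'
#' @param rows A `toxicity_table`, or any data frame with a `toxicity`
#'   column and one non-negative integer count column per dose.
#' @return A named numeric vector of per-dose totals.
#' @examples
#' grand_total(tibble::tibble(
#'   toxicity = c("Liver toxicity", "Kidney, diuretic effect"),
#'   low = c(1, 0), high = c(2, 1)))
#' @export
grand_total <- function(rows) {
  rows <- as_tibble(rows)
  counts <- rows[setdiff(names(rows), "toxicity")]
  if (!all(vapply(counts, is.numeric, logical(1)))) {
    stop_moamatch("Count columns must be numeric.", "validation_error")
  }
  if (any(unlist(counts) < 0, na.rm = TRUE) ||
      any(unlist(counts) != round(unlist(counts)), na.rm = TRUE)) {
    stop_moamatch("Counts must be non-negative integers.", "validation_error")
  }
  vapply(counts, function(x) sum(x, na.rm = TRUE), numeric(1))
}

#' @export
print.toxicity_table <- function(x, ...) {
  cmpd <- attr(x, "compound_id")
  cat("<toxicity_table>", if (!is.null(cmpd)) paste0(" ", cmpd), "\n", sep = "")
  df <- as.data.frame(x)
  gt <- attr(x, "grand_total")
  df <- rbind(df, c(toxicity = "Grand total", as.list(gt)))
  print(df, row.names = FALSE)
  ann <- attr(x, "annotations")
  if (length(ann)) {
    cat("(*) test compound is itself a reference of: ",
        paste(ann, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Run the full matching pipeline on one study
#'
#' Composes the analysis end to end: stratified differential analysis,
#' per-stratum change counts, median-t fingerprints per non-control dose,
#' pattern ranking, rule-based match confirmation, and the dose-stratified
#' toxicity count table. Optionally calibrates the match thresholds from a
#' set of reference fingerprints first. The result is deterministic given
#' the input profile and settings; every surrogate decision rule engaged is
#' logged in the report.
#'
#' @param profile A [study_profile()] of the test compound.
#' @param patterns Non-empty list of [moa_pattern()] objects.
#' @param thresholds A [threshold_set()], or `NULL` to calibrate from
#'   `calibration_profiles`.
#' @param calibration_profiles Optional list of [median_t_profile()]s for
#'   threshold calibration when `thresholds` is `NULL`.
#' @param alpha,value_scale Passed to [stratified_diff()].
#' @param correlation_floor Passed to [tabulate_toxicities()].
#' @param min_direction_agreement Passed to [confirm_matches()].
#' @param min_signature_overlap Passed to [pattern_rank()].
#' @param calibration_percentile Passed to [calibrate_thresholds()] when
#'   calibrating.
#' @return A list of class `match_report`: `compound`, `thresholds`,
#'   `stratum_results`, `change_counts`, `profiles` (median-t fingerprints
#'   by dose), `rankings` (confirmed pattern rankings by dose),
#'   `toxicity_table`, `settings`, and `log` (the surrogate rules engaged).
#' @export
run_pipeline <- function(profile, patterns, thresholds = NULL,
                         calibration_profiles = NULL,
                         alpha = 0.05, value_scale = "log",
                         correlation_floor = 0.5,
                         min_direction_agreement = 0.6,
                         min_signature_overlap = 3,
                         calibration_percentile = 95) {
  stopifnot(inherits(profile, "study_profile"))
  if (length(patterns) == 0) {
    stop_moamatch("No patterns supplied and no derivation requested; nothing to match.",
                  "config_error")
  }
  if (inherits(patterns, "moa_pattern")) patterns <- list(patterns)
  log_lines <- character()
  if (is.null(thresholds)) {
    if (is.null(calibration_profiles)) {
      stop_moamatch("Supply `thresholds` or `calibration_profiles`.",
                    "config_error")
    }
    thresholds <- calibrate_thresholds(calibration_profiles,
                                       percentile = calibration_percentile)
    log_lines <- c(log_lines, sprintf(
      "thresholds calibrated from %d reference fingerprints at the %sth percentile (nearest rank, %s)",
      length(calibration_profiles), calibration_percentile, thresholds$method))
  }
  log_lines <- c(log_lines, sprintf(
    "confirmation surrogate: median correlation >= %.3f (min over sexes) AND best-stratum direction agreement >= %.2f",
    min(thresholds$thresholds), min_direction_agreement))
  log_lines <- c(log_lines, sprintf(
    "tabulation: pattern-level either-dose confirmation gate; per-dose floor median correlation > %.2f (strict)",
    correlation_floor))

  design <- profile_design(profile)
  results <- stratified_diff(profile, alpha = alpha, value_scale = value_scale)
  counts <- count_changes(results)
  doses <- treated_doses(design)
  profiles <- lapply(setNames(doses, doses),
                     function(d) median_t_profile(results, d))
  rankings <- lapply(profiles, function(pr) {
    confirm_matches(
      pattern_rank(pr, patterns,
                   min_signature_overlap = min_signature_overlap,
                   results = results),
      thresholds, min_direction_agreement = min_direction_agreement)
  })
  pattern_toxicity <- setNames(
    vapply(patterns, function(p) p$toxicity_label, character(1)),
    vapply(patterns, function(p) p$pattern_id, character(1)))
  tox <- tabulate_toxicities(rankings, pattern_toxicity,
                             correlation_floor = correlation_floor,
                             patterns = patterns,
                             test_compound = design$compound)
  structure(
    list(compound = design$compound,
         thresholds = thresholds,
         stratum_results = results,
         change_counts = counts,
         profiles = profiles,
         rankings = rankings,
         toxicity_table = tox,
         settings = list(alpha = alpha, value_scale = value_scale,
                         correlation_floor = correlation_floor,
                         min_direction_agreement = min_direction_agreement,
                         min_signature_overlap = min_signature_overlap),
         log = log_lines),
    class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> ", x$compound, "\n", sep = "")
  cat("  significant (stratum, analyte) calls: ",
      sum(x$stratum_results$significant), " of ",
      nrow(x$stratum_results), "\n", sep = "")
  for (d in names(x$rankings)) {
    cat("  ", d, " dose: ", sum(x$rankings[[d]]$confirmed, na.rm = TRUE),
        " rule-confirmed pattern match(es)\n", sep = "")
  }
  gt <- attr(x$toxicity_table, "grand_total")
  cat("  toxicity grand totals: ",
      paste(sprintf("%s = %d", names(gt), as.integer(gt)), collapse = ", "),
      "\n", sep = "")
  for (l in x$log) cat("  note: ", l, "\n", sep = "")
  invisible(x)
}
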