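#' Tidy a MoA pattern into its signature table
#'
#' @param x A [moa_pattern()].
#' @param ... Unused.
#' @return A tibble with one row per signature analyte: `pattern_id`,
#'   `analyte_id`, `direction`, `reference_weight`.
#' @method tidy moa_pattern
#' @export
tidy.moa_pattern <- function(x, ...) {
  mutate(x$signature, pattern_id = x$pattern_id, .before = 1)
}

#' One-row summary of a MoA pattern
#'
#' @param x A [moa_pattern()].
#' @param ... Unused.
#' @return A one-row tibble: id, name, toxicity, signature size and split,
#'   number of references, validation status.
#' @method glance moa_pattern
#' @export
glance.moa_pattern <- function(x, ...) {
  tibble(pattern_id = x$pattern_id,
         moa_name = x$moa_name,
         toxicity_label = x$toxicity_label,
         n_analytes = nrow(x$signature),
         n_up = sum(x$signature$direction > 0),
         n_down = sum(x$signature$direction < 0),
         n_references = dplyr::n_distinct(x$provenance$compound_id),
         validated = x$validated)
}

#' Tidy a threshold set
#'
#' @param x A [threshold_set()].
#' @param ... Unused.
#' @return A tibble with one row per sex: `sex`, `threshold`,
#'   `calibration_percentile`, `method`.
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  tibble(sex = names(x$thresholds),
         threshold = unname(x$thresholds),
         calibration_percentile = x$calibration_percentile,
         method = x$method)
}

#' Tidy a toxicity table into long form
#'
#' @param x A `toxicity_table` from [tabulate_toxicities()].
#' @param ... Unused.
#' @return A long tibble: `toxicity`, `dose_group`, `n_patterns`.
#' @method tidy toxicity_table
#' @export
tidy.toxicity_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = -"toxicity",
                      names_to = "dose_group", values_to = "n_patterns")
}

#' Tidy a match report into its combined pattern rankings
#'
#' @param x A `match_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-dose pattern rankings stacked into one tibble with a
#'   `dose_group` column.
#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) {
  purrr::imap_dfr(x$rankings, function(rk, d) {
    mutate(as_tibble(rk), dose_group = d, .before = 1)
  })
}

#' One-row summary of a match report
#'
#' @param x A `match_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble: compound, significant-call count, confirmed
#'   matches per dose, and the toxicity grand totals.
#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  gt <- attr(x$toxicity_table, "grand_total")
  out <- tibble(compound = x$compound,
                n_tests = nrow(x$stratum_results),
                n_significant = sum(x$stratum_results$significant))
  for (d in names(x$rankings)) {
    out[[paste0("confirmed_", d)]] <-
      sum(x$rankings[[d]]$confirmed, na.rm = TRUE)
  }
  for (d in names(gt)) {
    out[[paste0("grand_total_", d)]] <- as.integer(gt[[d]])
  }
  out
}
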