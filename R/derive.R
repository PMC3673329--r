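#' Derive a MoA metabolite pattern from reference compounds
#'
#' Builds the signed metabolite signature of a toxicological mode of action
#' from at least three reference compounds known to share it. For each
#' reference compound, the strata of its designated dose group are pooled:
#' an analyte's per-compound direction is the sign of its median Welch t
#' over the strata in which it was significant. An analyte enters the
#' signature when it is significant with one consistent direction in at
#' least `ceiling(consistency_fraction * n_compounds)` references; its
#' reference weight is the median, over those qualifying references, of the
#' per-compound median t values.
#'
#' The consistency fraction is a deterministic surrogate for the expert
#' consistency review that curated reference patterns traditionally receive;
#' see the package vignette for the rationale and for the recommended
#' stringency of the upstream significance level when deriving patterns.
#'
#' @param reference_results Named list: compound_id -> `stratum_results`
#'   (from [stratified_diff()] on that reference study). At least 3 distinct
#'   compounds.
#' @param moa_name Mode-of-action name for the pattern.
#' @param toxicity_label Toxicity category for downstream tabulation.
#' @param consistency_fraction Fraction of references in (0, 1] that must
#'   show the analyte significantly changed in the same direction
#'   (default 2/3).
#' @param dose_group Designated dose group whose strata are pooled per
#'   reference; either a single label or a named vector per compound.
#'   Default `"high"`.
#' @param pattern_id Identifier for the pattern; defaults to a slug of
#'   `moa_name`.
#' @return A [moa_pattern()] with provenance listing each reference
#'   compound and its designated dose.
#' @export
derive_pattern <- function(reference_results, moa_name, toxicity_label,
                           consistency_fraction = 2 / 3,
                           dose_group = "high", pattern_id = NULL) {
  if (is.null(names(reference_results)) ||
      any(!nzchar(names(reference_results)))) {
    stop_moamatch("`reference_results` must be a named list keyed by compound id.",
                  "validation_error")
  }
  compounds <- names(reference_results)
  if (length(unique(compounds)) < 3) {
    stop_moamatch("Pattern derivation needs at least 3 distinct reference compounds.",
                  "insufficient_references")
  }
  if (consistency_fraction <= 0 || consistency_fraction > 1) {
    stop_moamatch("`consistency_fraction` must be in (0, 1].",
                  "validation_error")
  }
  doses <- if (length(dose_group) == 1) {
    setNames(rep(dose_group, length(compounds)), compounds)
  } else {
    if (!all(compounds %in% names(dose_group))) {
      stop_moamatch("Per-compound `dose_group` must name every reference compound.",
                    "validation_error")
    }
    dose_group[compounds]
  }

  per_compound <- purrr::map_dfr(compounds, function(cmpd) {
    res <- as_tibble(reference_results[[cmpd]])
    res <- filter(res, .data$dose_group == doses[[cmpd]])
    if (nrow(res) == 0) {
      stop_moamatch(paste0("Reference '", cmpd, "' has no strata at dose '",
                           doses[[cmpd]], "'."), "validation_error")
    }
    res %>%
      filter(.data$significant) %>%
      group_by(.data$analyte_id) %>%
      summarise(median_t = median(.data$t_value), .groups = "drop") %>%
      filter(.data$median_t != 0) %>%
      mutate(compound_id = cmpd, direction = sign(.data$median_t))
  })

  k <- ceiling(consistency_fraction * length(compounds) - 1e-9)
  signature <- per_compound %>%
    group_by(.data$analyte_id, .data$direction) %>%
    summarise(n_compounds = dplyr::n(),
              reference_weight = median(.data$median_t), .groups = "drop") %>%
    filter(.data$n_compounds >= k)
  if (nrow(signature) > 0) {
    # if both directions somehow qualify (possible when the fraction <= 1/2),
    # keep the better-supported one; ties are dropped as inconsistent
    signature <- signature %>%
      group_by(.data$analyte_id) %>%
      filter(.data$n_compounds == max(.data$n_compounds)) %>%
      filter(dplyr::n() == 1) %>%
      ungroup()
  }
  signature <- signature %>%
    arrange(.data$analyte_id) %>%
    select("analyte_id", "direction", "reference_weight")

  if (nrow(signature) == 0) {
    stop_moamatch(paste0("No analyte is consistently significant in at least ",
                         k, " of ", length(compounds),
                         " reference compounds; refusing to emit an empty pattern."),
                  "no_consistent_signal")
  }
  if (is.null(pattern_id)) {
    pattern_id <- gsub("[^a-z0-9]+", "_", tolower(moa_name))
  }
  moa_pattern(pattern_id, moa_name, toxicity_label, signature,
              provenance = tibble(compound_id = compounds,
                                  dose_group = unname(doses)))
}

#' Validate a pattern against held-out positives and database negatives
#'
#' A derived pattern is accepted when it identifies at least one further
#' reference compound sharing the mode of action that was not used to
#' establish it, and identifies none of the supplied negative reference
#' compounds (which do not share the toxicity). "Identifies" means a
#' rule-confirmed match via [pattern_rank()] + [confirm_matches()] at either
#' non-control dose of the candidate study.
#'
#' @param pattern A [moa_pattern()].
#' @param heldout_positives Named list: compound_id -> `stratum_results` for
#'   compounds sharing the MoA but absent from the pattern's provenance.
#' @param negatives Named list: compound_id -> `stratum_results` for
#'   compounds not sharing the toxicity.
#' @param thresholds A [threshold_set()] used for match confirmation.
#' @param min_direction_agreement,min_signature_overlap Confirmation-rule
#'   settings passed through to [pattern_rank()]/[confirm_matches()].
#' @return A list of class `pattern_validation`: `passed`, `positive_hits`,
#'   `negative_hits`, a per-compound `details` tibble, and `pattern` — the
#'   input pattern with `validated` and `validation_report` updated.
#' @export
validate_pattern <- function(pattern, heldout_positives, negatives = list(),
                             thresholds,
                             min_direction_agreement = 0.6,
                             min_signature_overlap = 3) {
  stopifnot(inherits(pattern, "moa_pattern"))
  if (length(heldout_positives) == 0) {
    stop_moamatch("At least one held-out positive is required.",
                  "validation_error")
  }
  leak <- intersect(names(heldout_positives),
                    unique(pattern$provenance$compound_id))
  if (length(leak)) {
    stop_moamatch(paste0("Held-out positive(s) overlap the pattern's provenance: ",
                         paste(leak, collapse = ", ")),
                  "leakage_error")
  }

  check_compound <- function(results) {
    res <- as_tibble(results)
    design <- attr(results, "design")
    ctrl <- if (!is.null(design)) design$control else "control"
    doses <- setdiff(unique(res$dose_group), ctrl)
    any(vapply(doses, function(d) {
      prof <- median_t_profile(results, d)
      rk <- pattern_rank(prof, list(pattern),
                         min_signature_overlap = min_signature_overlap,
                         results = results)
      cm <- confirm_matches(rk, thresholds,
                            min_direction_agreement = min_direction_agreement)
      any(cm$confirmed, na.rm = TRUE)
    }, logical(1)))
  }

  pos_hit <- vapply(heldout_positives, check_compound, logical(1))
  neg_hit <- if (length(negatives)) {
    vapply(negatives, check_compound, logical(1))
  } else {
    logical(0)
  }
  details <- bind_rows(
    tibble(compound_id = names(heldout_positives), role = "positive",
           confirmed = unname(pos_hit)),
    tibble(compound_id = names(negatives) %||% character(), role = "negative",
           confirmed = unname(neg_hit)))
  passed <- sum(pos_hit) >= 1 && sum(neg_hit) == 0
  report <- sprintf(
    "hold-out validation: %d/%d positives identified, %d/%d negatives identified -> %s",
    sum(pos_hit), length(pos_hit), sum(neg_hit), length(neg_hit),
    if (passed) "passed" else "failed")
  pattern$validated <- passed
  pattern$validation_report <- report
  structure(list(passed = passed,
                 positive_hits = sum(pos_hit),
                 negative_hits = sum(neg_hit),
                 details = details,
                 pattern = pattern),
            class = "pattern_validation")
}

#' @export
print.pattern_validation <- function(x, ...) {
  cat("<pattern_validation> ", x$pattern$pattern_id, ": ",
      if (x$passed) "PASSED" else "FAILED", "\n  ",
      x$pattern$validation_report, "\n", sep = "")
  invisible(x)
}
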