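#' Sex-specific match thresholds
#'
#' Holds the per-sex correlation threshold above which two treatments are
#' considered a clear match, together with its calibration provenance.
#' Thresholds are usually obtained with [calibrate_thresholds()] (the
#' percentile of the null pairwise-correlation distribution of a reference
#' database); fixed values can also be supplied directly.
#'
#' @param thresholds Named numeric vector of per-sex thresholds in `[-1, 1]`,
#'   e.g. `c(M = 0.50, F = 0.60)`.
#' @param calibration_percentile Percentile used for calibration (`NA` for
#'   hand-set thresholds).
#' @param method Correlation method the thresholds refer to.
#' @param provenance Optional list describing the calibration database.
#' @return A list of class `threshold_set`.
#' @export
threshold_set <- function(thresholds, calibration_percentile = NA_real_,
                          method = "spearman", provenance = NULL) {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop_moamatch("`thresholds` must be named by sex.", "validation_error")
  }
  if (any(thresholds < -1 | thresholds > 1)) {
    stop_moamatch("Thresholds must lie in [-1, 1].", "validation_error")
  }
  structure(list(thresholds = thresholds,
                 calibration_percentile = calibration_percentile,
                 method = method,
                 provenance = provenance),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> ",
      paste(sprintf("%s = %.3f", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n", sep = "")
  if (!is.na(x$calibration_percentile)) {
    cat("  calibrated at the ", x$calibration_percentile,
        "th percentile (", x$method, ", nearest rank)\n", sep = "")
  }
  invisible(x)
}

#' Median t-value fingerprint of a treatment
#'
#' Summarises a compound's metabolite response at one dose as, per sex and
#' analyte, the median of the signed Welch t statistics over that sex's day
#' strata. This fingerprint is the common currency for pattern ranking and
#' whole-profile comparison.
#'
#' @param results A `stratum_results` tibble from [stratified_diff()].
#' @param dose_group Which non-control dose group to summarise.
#' @return A tibble of class `median_t_profile` with `sex`, `analyte_id`,
#'   `median_t`; the compound and dose are carried as attributes.
#' @export
median_t_profile <- function(results, dose_group) {
  res <- as_tibble(results)
  res <- filter(res, .data$dose_group == !!dose_group)
  if (nrow(res) == 0) {
    stop_moamatch(paste0("No strata at dose group '", dose_group, "'."),
                  "validation_error")
  }
  out <- res %>%
    filter(is.finite(.data$t_value)) %>%
    group_by(.data$sex, .data$analyte_id) %>%
    summarise(median_t = median(.data$t_value), .groups = "drop")
  structure(out,
            compound_id = attr(results, "compound"),
            dose_group = dose_group,
            class = c("median_t_profile", class(tibble())))
}

#' Construct a median-t fingerprint from a table
#'
#' Wraps an existing per-sex median-t table (e.g. imported from another
#' system) as a `median_t_profile` so it can be used with [pattern_rank()],
#' [profile_compare()] and [calibrate_thresholds()].
#'
#' @param x Data frame with columns `sex`, `analyte_id`, `median_t`.
#' @param compound_id Treatment identifier.
#' @param dose_group Dose-group label the fingerprint refers to.
#' @return A [median_t_profile()] tibble.
#' @export
as_median_t_profile <- function(x, compound_id = "profile",
                                dose_group = "high") {
  x <- as_tibble(x)
  req <- c("sex", "analyte_id", "median_t")
  if (!all(req %in% names(x))) {
    stop_moamatch("Need columns sex, analyte_id, median_t.", "format_error")
  }
  if (any(!is.finite(x$median_t))) {
    stop_moamatch("All median t values must be finite.", "validation_error")
  }
  if (anyDuplicated(x[c("sex", "analyte_id")])) {
    stop_moamatch("Each (sex, analyte) may appear at most once.",
                  "integrity_error")
  }
  structure(x[, req], compound_id = compound_id, dose_group = dose_group,
            class = c("median_t_profile", class(tibble())))
}

# Per-sex Pearson correlation between a median-t profile restricted to a
# pattern's signature and the signature's reference weights.
signature_correlations <- function(profile, pattern) {
  sexes <- sort(unique(profile$sex))
  purrr::map_dfr(sexes, function(s) {
    sub <- inner_join(pattern$signature,
                      filter(as_tibble(profile), .data$sex == s),
                      by = "analyte_id")
    r <- if (nrow(sub) < 2 ||
             sd(sub$median_t) == 0 || sd(sub$reference_weight) == 0) {
      NA_real_
    } else {
      cor(sub$median_t, sub$reference_weight)
    }
    tibble(sex = s, n_shared = nrow(sub), correlation = r)
  })
}

# Best-stratum direction agreement: the largest, over the dose's strata, of
# the fraction of signature analytes significantly changed in the pattern's
# direction. Falls back to sign agreement of the median-t profile when no
# stratum results are supplied.
direction_agreement <- function(pattern, profile, results = NULL) {
  sig <- select(pattern$signature, "analyte_id", sig_direction = "direction")
  if (!is.null(results)) {
    res <- as_tibble(results)
    res <- filter(res, .data$dose_group == attr(profile, "dose_group"))
    strata <- distinct(res, .data$sex, .data$day)
    if (nrow(strata) == 0) return(NA_real_)
    agree <- purrr::pmap_dbl(strata, function(sex, day) {
      sl <- res[res$sex == sex & res$day == day, ]
      hits <- inner_join(sig, sl, by = "analyte_id")
      n_agree <- sum(hits$significant &
                       sign(hits$t_value) == hits$sig_direction)
      n_agree / nrow(sig)
    })
    max(agree)
  } else {
    prof <- as_tibble(profile) %>%
      group_by(.data$analyte_id) %>%
      summarise(median_t = median(.data$median_t), .groups = "drop")
    hits <- inner_join(sig, prof, by = "analyte_id")
    if (nrow(hits) == 0) return(NA_real_)
    sum(sign(hits$median_t) == hits$sig_direction) / nrow(sig)
  }
}

#' Rank MoA patterns against a treatment fingerprint
#'
#' The first step of pattern matching: each pattern is scored by a split
#' correlation — the Pearson correlation between the treatment's median-t
#' values and the pattern's reference weights, restricted to the signature
#' analytes and computed separately per sex — summarised by the median of
#' the per-sex correlations (for two sexes, their mean). Patterns sharing
#' fewer than `min_signature_overlap` analytes with the fingerprint, or with
#' a zero-variance restriction, are reported unscored with a reason rather
#' than silently dropped. The result is sorted by median correlation
#' (descending, ties broken by pattern id).
#'
#' @param profile A [median_t_profile()].
#' @param patterns List of [moa_pattern()] objects.
#' @param min_signature_overlap Minimum shared analytes per sex for a
#'   pattern to be scored (default 3; a correlation on fewer points is
#'   meaningless).
#' @param results Optional `stratum_results` for the same compound; enables
#'   the best-stratum direction-agreement statistic used by
#'   [confirm_matches()]. Without it, agreement falls back to sign agreement
#'   of the median-t fingerprint.
#' @return A tibble of class `pattern_ranking`: `pattern_id`,
#'   `toxicity_label`, one `r_<sex>` column per sex, `median_correlation`,
#'   `n_overlap`, `direction_agreement`, `scored`, `reason`, and a
#'   `confirmed` placeholder (set by [confirm_matches()]).
#' @export
pattern_rank <- function(profile, patterns, min_signature_overlap = 3,
                         results = NULL) {
  stopifnot(inherits(profile, "median_t_profile"))
  if (inherits(patterns, "moa_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0) {
    stop_moamatch("No patterns supplied.", "config_error")
  }
  sexes <- sort(unique(profile$sex))
  rows <- purrr::map_dfr(patterns, function(p) {
    sc <- signature_correlations(profile, p)
    n_overlap <- min(sc$n_shared)
    if (n_overlap < min_signature_overlap) {
      scored <- FALSE
      reason <- sprintf("signature overlap %d < %d", n_overlap,
                        min_signature_overlap)
    } else if (anyNA(sc$correlation)) {
      scored <- FALSE
      reason <- "zero-variance vector on the signature restriction"
    } else {
      scored <- TRUE
      reason <- NA_character_
    }
    row <- tibble(pattern_id = p$pattern_id,
                  toxicity_label = p$toxicity_label)
    for (s in sexes) {
      row[[paste0("r_", s)]] <-
        if (scored) sc$correlation[sc$sex == s] else NA_real_
    }
    row$median_correlation <-
      if (scored) median(sc$correlation) else NA_real_
    row$n_overlap <- n_overlap
    row$direction_agreement <-
      if (scored) direction_agreement(p, profile, results) else NA_real_
    row$scored <- scored
    row$reason <- reason
    row$confirmed <- NA
    row
  })
  rows <- rows %>%
    arrange(desc(.data$scored),
            dplyr::desc(dplyr::coalesce(.data$median_correlation, -Inf)),
            .data$pattern_id)
  structure(rows,
            compound_id = attr(profile, "compound_id"),
            dose_group = attr(profile, "dose_group"),
            class = c("pattern_ranking", class(tibble())))
}

#' Whole-metabolome profile comparison between two treatments
#'
#' The complementary matching route: instead of MoA signatures, the full
#' median-t fingerprints of two treatments are correlated per sex with both
#' Spearman (average-rank ties) and Pearson coefficients over their shared
#' analytes. A sex matches when the larger of the two coefficients reaches
#' that sex's threshold.
#'
#' @param test,reference [median_t_profile()] objects.
#' @param thresholds A [threshold_set()].
#' @param min_overlap Minimum shared analytes per sex (default 5).
#' @return A tibble with one row per sex: `n_shared`, `spearman`,
#'   `pearson`, `match`.
#' @export
profile_compare <- function(test, reference, thresholds, min_overlap = 5) {
  stopifnot(inherits(test, "median_t_profile"),
            inherits(reference, "median_t_profile"))
  sexes <- sort(intersect(unique(test$sex), unique(reference$sex)))
  purrr::map_dfr(sexes, function(s) {
    sub <- inner_join(filter(as_tibble(test), .data$sex == s),
                      filter(as_tibble(reference), .data$sex == s),
                      by = "analyte_id", suffix = c("_test", "_ref"))
    if (nrow(sub) < min_overlap) {
      stop_moamatch(paste0("Only ", nrow(sub), " shared analytes for sex ", s,
                           "; at least ", min_overlap, " are required."),
                    "insufficient_overlap")
    }
    sp <- cor(sub$median_t_test, sub$median_t_ref, method = "spearman")
    pe <- cor(sub$median_t_test, sub$median_t_ref, method = "pearson")
    thr <- thresholds$thresholds[[s]]
    tibble(sex = s, n_shared = nrow(sub), spearman = sp, pearson = pe,
           match = max(sp, pe) >= thr)
  })
}

#' Calibrate sex-specific match thresholds from a reference database
#'
#' Computes, per sex, every unordered pairwise profile-comparison
#' correlation among the database treatments and sets the threshold at the
#' chosen empirical percentile of that distribution (nearest-rank
#' convention, no interpolation). With the default 95th percentile, about 5%
#' of null pairwise correlations exceed the threshold — the contract the
#' "clear match" cut-off is meant to satisfy.
#'
#' @param profiles List of [median_t_profile()] objects, one per database
#'   treatment (at least 2 per sex).
#' @param percentile Calibration percentile in (0, 100], default 95.
#' @param method `"spearman"` (default, robust to heavy-tailed t values) or
#'   `"pearson"`.
#' @param min_overlap Minimum shared analytes for a pair to contribute.
#' @return A [threshold_set()] whose provenance records the database size
#'   and the number of pairwise correlations per sex.
#' @export
calibrate_thresholds <- function(profiles, percentile = 95,
                                 method = c("spearman", "pearson"),
                                 min_overlap = 5) {
  method <- match.arg(method)
  if (length(profiles) < 2) {
    stop_moamatch("Threshold calibration needs at least 2 profiles.",
                  "insufficient_data")
  }
  sexes <- sort(unique(unlist(lapply(profiles, function(p) unique(p$sex)))))
  cors <- pairwise_profile_correlations(profiles, method, min_overlap)
  thresholds <- vapply(sexes, function(s) {
    v <- cors$correlation[cors$sex == s]
    if (length(v) < 1) {
      stop_moamatch(paste0("No pairwise correlations available for sex ", s, "."),
                    "insufficient_data")
    }
    if (max(v) - min(v) < .Machine$double.eps^0.5 && length(v) > 1) {
      stop_moamatch("All pairwise correlations are identical; the calibration set is degenerate.",
                    "calibration_degenerate")
    }
    nearest_rank_percentile(v, percentile)
  }, numeric(1))
  threshold_set(setNames(thresholds, sexes),
                calibration_percentile = percentile,
                method = method,
                provenance = list(n_profiles = length(profiles),
                                  n_pairs = table(cors$sex)))
}

#' All unordered pairwise profile correlations of a database
#'
#' The null correlation distribution that [calibrate_thresholds()] cuts:
#' one row per sex and unordered treatment pair.
#'
#' @inheritParams calibrate_thresholds
#' @return A tibble with `sex`, `treatment_a`, `treatment_b`, `correlation`.
#' @export
pairwise_profile_correlations <- function(profiles,
                                          method = c("spearman", "pearson"),
                                          min_overlap = 5) {
  method <- match.arg(method)
  n <- length(profiles)
  ids <- vapply(seq_len(n), function(i) {
    attr(profiles[[i]], "compound_id") %||% paste0("profile_", i)
  }, character(1))
  # pre-split each profile into per-sex named vectors for fast pairing
  split_one <- function(p) {
    p <- as_tibble(p)
    lapply(split(p, p$sex), function(d) setNames(d$median_t, d$analyte_id))
  }
  splits <- lapply(profiles, split_one)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      sexes <- intersect(names(splits[[i]]), names(splits[[j]]))
      rows <- purrr::map_dfr(sexes, function(s) {
        a <- splits[[i]][[s]]; b <- splits[[j]][[s]]
        shared <- intersect(names(a), names(b))
        if (length(shared) < min_overlap) return(tibble())
        tibble(sex = s, treatment_a = ids[i], treatment_b = ids[j],
               correlation = cor(a[shared], b[shared], method = method))
      })
      k <- k + 1L
      out[[k]] <- rows
    }
  }
  bind_rows(out)
}

#' Apply the confirmation rule to a pattern ranking
#'
#' Replaces the expert-panel review of candidate matches with a declared
#' two-condition rule: a pattern match is rule-confirmed when its median
#' correlation reaches the smaller of the per-sex thresholds and its
#' best-stratum direction agreement reaches `min_direction_agreement`.
#' Reports produced by this package label such matches rule-confirmed.
#'
#' @param ranked A `pattern_ranking` from [pattern_rank()].
#' @param thresholds A [threshold_set()].
#' @param min_direction_agreement Minimum fraction of signature analytes
#'   significantly changed in the pattern's direction (default 0.6).
#' @return The ranking with its `confirmed` flags set; order preserved.
#' @export
confirm_matches <- function(ranked, thresholds,
                            min_direction_agreement = 0.6) {
  stopifnot(inherits(ranked, "pattern_ranking"))
  gate <- min(thresholds$thresholds)
  ranked$confirmed <- !is.na(ranked$median_correlation) &
    ranked$median_correlation >= gate &
    !is.na(ranked$direction_agreement) &
    ranked$direction_agreement >= min_direction_agreement
  ranked
}
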