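#' Matched-control fold change
#'
#' The fold change of an analyte is the ratio of the arithmetic mean
#' intensity in the treated group to the arithmetic mean in the matched
#' control group (same sex, day and dose comparison), on the linear
#' intensity scale.
#'
#' @param treated,control Numeric vectors of positive intensities.
#' @return A positive scalar ratio.
#' @examples
#' fold_change(c(4, 4, 4), c(2, 2, 2))  # 2
#' @export
fold_change <- function(treated, control) {
  if (length(treated) == 0 || length(control) == 0) {
    stop_moamatch("Fold change needs at least one value in each group.",
                  "insufficient_data")
  }
  mean(treated) / mean(control)
}

# Vectorised Welch statistics from per-group summaries. Used for scalar
# welch_test() and for thousands of (stratum, analyte) cells at once.
welch_stats <- function(m1, v1, n1, m2, v2, n2) {
  a <- v1 / n1
  b <- v2 / n2
  se <- sqrt(a + b)
  t <- (m1 - m2) / se
  dof <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), dof)
  list(t_value = t, dof = dof, p_value = p)
}

#' Heteroscedastic (Welch) two-sample t test
#'
#' Welch's unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided p value; the statistic is signed as
#' `(mean(a) - mean(b)) / SE`, so positive values mean group `a` is higher.
#'
#' @param a,b Numeric vectors with at least 2 values each; at least one
#'   group must have nonzero variance.
#' @return A one-row tibble with `t_value`, `dof`, `p_value`.
#' @examples
#' welch_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, dof = 4
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop_moamatch("Welch test needs at least 2 values per group.",
                  "insufficient_data")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    stop_moamatch("Both groups have zero variance; the Welch p value is undefined.",
                  "degenerate_input")
  }
  s <- welch_stats(mean(a), va, length(a), mean(b), vb, length(b))
  tibble(t_value = s$t_value, dof = s$dof, p_value = s$p_value)
}

#' Sex- and day-stratified differential analysis
#'
#' For every (sex, day, non-control dose group) stratum and every analyte,
#' compares treated animals against the study's untreated controls of the
#' same sex and day: linear-scale fold change (treated mean / control mean),
#' a Welch test on the chosen scale, a significance call at `alpha`, and a
#' direction (`up`/`down` for significant analytes, `none` otherwise).
#'
#' By default the test runs on log-transformed intensities, matching a
#' lognormal error model; fold changes are always linear-scale ratios.
#' (stratum, analyte) cells with fewer than 2 treated or 2 control values
#' are dropped (absence, with a warning), never reported as significant.
#' No multiple-testing correction is applied: each analyte is tested at the
#' raw per-comparison level, as is conventional for this screening read-out;
#' `p_adjust_method` exposes correction as an opt-in.
#'
#' @param profile A [study_profile()].
#' @param alpha Per-analyte significance level (default 0.05).
#' @param value_scale `"log"` (default) or `"linear"`: scale on which the
#'   Welch test is computed.
#' @param p_adjust_method Optional [stats::p.adjust()] method applied within
#'   each stratum before the significance call; default `"none"`.
#' @return A tibble of class `stratum_results` with one row per (sex, day,
#'   dose_group, analyte): `fold_change`, `t_value`, `dof`, `p_value`,
#'   `significant`, `direction`.
#' @export
stratified_diff <- function(profile, alpha = 0.05,
                            value_scale = c("log", "linear"),
                            p_adjust_method = "none") {
  stopifnot(inherits(profile, "study_profile"))
  value_scale <- match.arg(value_scale)
  design <- profile_design(profile)
  rec <- as_tibble(profile)
  rec$test_value <- if (value_scale == "log") log(rec$value) else rec$value

  sums <- rec %>%
    group_by(.data$sex, .data$day, .data$dose_group, .data$analyte_id) %>%
    summarise(n = dplyr::n(),
              mean_lin = mean(.data$value),
              mean_test = mean(.data$test_value),
              var_test = var(.data$test_value),
              .groups = "drop")

  ctrl <- sums %>%
    filter(.data$dose_group == design$control) %>%
    select("sex", "day", "analyte_id",
           n_c = "n", mean_lin_c = "mean_lin",
           mean_test_c = "mean_test", var_test_c = "var_test")
  trt <- filter(sums, .data$dose_group != design$control)
  joined <- left_join(trt, ctrl, by = c("sex", "day", "analyte_id"))

  insufficient <- is.na(joined$n_c) | joined$n < 2 | joined$n_c < 2
  if (any(insufficient)) {
    warn(paste0(sum(insufficient),
                " (stratum, analyte) cell(s) had fewer than 2 treated or",
                " 2 control values and were dropped."))
    joined <- joined[!insufficient, ]
  }
  degenerate <- joined$var_test == 0 & joined$var_test_c == 0
  if (any(degenerate)) {
    stop_moamatch(paste0(sum(degenerate),
                         " (stratum, analyte) cell(s) have zero variance in both",
                         " groups; the Welch test is undefined. Check the input",
                         " intensities."),
                  "degenerate_input")
  }

  ws <- welch_stats(joined$mean_test, joined$var_test, joined$n,
                    joined$mean_test_c, joined$var_test_c, joined$n_c)
  out <- joined %>%
    mutate(fold_change = .data$mean_lin / .data$mean_lin_c,
           t_value = ws$t_value, dof = ws$dof, p_value = ws$p_value) %>%
    group_by(.data$sex, .data$day, .data$dose_group) %>%
    mutate(p_value = stats::p.adjust(.data$p_value, method = p_adjust_method)) %>%
    ungroup() %>%
    mutate(significant = .data$p_value < alpha,
           direction = case_when(
             .data$significant & .data$t_value > 0 ~ "up",
             .data$significant & .data$t_value < 0 ~ "down",
             TRUE ~ "none")) %>%
    select("sex", "day", "dose_group", "analyte_id", "fold_change",
           "t_value", "dof", "p_value", "significant", "direction") %>%
    arrange(.data$sex, .data$day,
            match(.data$dose_group, design$dose_levels), .data$analyte_id)

  structure(out,
            compound = design$compound, alpha = alpha,
            value_scale = value_scale, design = design,
            class = c("stratum_results", class(tibble())))
}

#' Count significant metabolite changes per stratum
#'
#' Tallies, for each (sex, day, dose group) stratum, how many analytes were
#' significantly increased and decreased — the "total metabolite changes"
#' summary customarily plotted per study.
#'
#' @param results A `stratum_results` tibble from [stratified_diff()].
#' @return A tibble with `sex`, `day`, `dose_group`, `n_increased`,
#'   `n_decreased`, `n_total`.
#' @export
count_changes <- function(results) {
  results %>%
    as_tibble() %>%
    group_by(.data$sex, .data$day, .data$dose_group) %>%
    summarise(n_increased = sum(.data$direction == "up"),
              n_decreased = sum(.data$direction == "down"),
              .groups = "drop") %>%
    mutate(n_total = .data$n_increased + .data$n_decreased)
}
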