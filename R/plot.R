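#' Plot total metabolite changes per stratum
#'
#' Bar chart of the number of significantly increased and decreased
#' analytes per study day, faceted by sex and dose group — the standard
#' per-study summary of a stratified differential analysis.
#'
#' @param counts Output of [count_changes()] (or a `stratum_results`
#'   object, which is counted first).
#' @return A ggplot object.
#' @export
plot_change_counts <- function(counts) {
  if (inherits(counts, "stratum_results")) counts <- count_changes(counts)
  long <- tidyr::pivot_longer(counts, c("n_increased", "n_decreased"),
                              names_to = "direction", values_to = "n")
  long$direction <- factor(long$direction,
                           levels = c("n_increased", "n_decreased"),
                           labels = c("increased", "decreased"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$day), y = .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(sex ~ dose_group) +
    ggplot2::labs(x = "study day", y = "significant analytes",
                  fill = NULL, title = "Total metabolite changes") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_change_counts `autoplot()` method for `stratum_results`.
#' @param object,... `stratum_results` object and ignored extra arguments.
#' @method autoplot stratum_results
#' @export
autoplot.stratum_results <- function(object, ...) {
  plot_change_counts(object)
}

#' Plot a pattern ranking
#'
#' Horizontal lollipop chart of median split correlations per pattern,
#' coloured by rule-confirmation status; unscored patterns are omitted.
#'
#' @param object A `pattern_ranking` (after [confirm_matches()] if
#'   confirmation colouring is wanted).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pattern_ranking
#' @export
autoplot.pattern_ranking <- function(object, ...) {
  df <- filter(as_tibble(object), .data$scored)
  df$pattern_id <- stats::reorder(df$pattern_id, df$median_correlation)
  df$status <- dplyr::case_when(
    is.na(df$confirmed) ~ "unconfirmed",
    df$confirmed ~ "rule-confirmed",
    TRUE ~ "not confirmed")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_correlation,
                                   y = .data$pattern_id,
                                   colour = .data$status)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$median_correlation,
                                       yend = .data$pattern_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "median split correlation", y = NULL, colour = NULL,
                  title = paste0("Pattern ranking",
                                 if (!is.null(attr(object, "dose_group")))
                                   paste0(" (", attr(object, "dose_group"),
                                          " dose)"))) +
    ggplot2::theme_minimal()
}

#' Plot a toxicity count table
#'
#' Dose-by-toxicity bar chart of rule-confirmed pattern-match counts.
#'
#' @param object A `toxicity_table` from [tabulate_toxicities()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot toxicity_table
#' @export
autoplot.toxicity_table <- function(object, ...) {
  long <- tidy.toxicity_table(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_patterns,
                                     y = .data$toxicity,
                                     fill = .data$dose_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "rule-confirmed pattern matches", y = NULL,
                  fill = "dose") +
    ggplot2::theme_minimal()
}
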