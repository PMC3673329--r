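#' Define the measured analyte panel
#'
#' An analyte panel describes the metabolite universe a profiling platform
#' reports: an ordered set of analyte identifiers, display names, and whether
#' each analyte is chemically identified or an unknown spectral feature.
#' The default dimensions (225 analytes, 167 identified) mirror a typical
#' semi-quantitative plasma profiling panel combining GC-MS and LC-MS/MS
#' read-outs.
#'
#' @param n_analytes Total number of analytes on the panel.
#' @param n_identified Number of chemically identified analytes; the
#'   remainder are unknowns. Must not exceed `n_analytes`.
#' @param analyte_id Optional character vector of identifiers (length
#'   `n_analytes`). Defaults to `met_001 ...` for identified analytes and
#'   `unk_168 ...` for unknowns.
#' @param display_name Optional display names, defaults to the identifiers.
#' @param identified Optional logical vector; overrides `n_identified`.
#'
#' @return A tibble of class `analyte_panel` with columns `analyte_id`,
#'   `display_name`, `identified`.
#' @examples
#' panel <- analyte_panel(10, 7)
#' sum(panel$identified)
#' @export
analyte_panel <- function(n_analytes = 225, n_identified = 167,
                          analyte_id = NULL, display_name = NULL,
                          identified = NULL) {
  if (is.null(identified)) {
    if (n_identified > n_analytes || n_identified < 0) {
      stop_moamatch("`n_identified` must be between 0 and `n_analytes`.",
                    "validation_error")
    }
    identified <- seq_len(n_analytes) <= n_identified
  }
  if (is.null(analyte_id)) {
    analyte_id <- ifelse(identified,
                         sprintf("met_%03d", seq_len(n_analytes)),
                         sprintf("unk_%03d", seq_len(n_analytes)))
  }
  if (is.null(display_name)) display_name <- analyte_id
  out <- tibble(analyte_id = as.character(analyte_id),
                display_name = as.character(display_name),
                identified = as.logical(identified))
  validate_analyte_panel(out)
}

validate_analyte_panel <- function(panel) {
  if (!all(c("analyte_id", "display_name", "identified") %in% names(panel))) {
    stop_moamatch("An analyte panel needs analyte_id, display_name and identified columns.",
                  "format_error")
  }
  if (anyDuplicated(panel$analyte_id) || any(!nzchar(panel$analyte_id)) ||
      anyNA(panel$analyte_id)) {
    stop_moamatch("Analyte identifiers must be unique and non-empty.",
                  "integrity_error")
  }
  if (anyNA(panel$identified)) {
    stop_moamatch("Each analyte must be flagged identified TRUE or FALSE.",
                  "validation_error")
  }
  class(panel) <- c("analyte_panel", class(tibble()))
  panel
}

#' Describe a repeat-dose study design
#'
#' Captures the design the downstream statistics assume: two or more dose
#' groups plus one untreated control group, both sexes, and a set of plasma
#' sampling days. The defaults encode a 28-day rat study with 5 treated
#' animals per sex per dose group, 10 untreated controls per sex, and
#' sampling on days 7, 14 and 28 — i.e. 40 animals and 120 plasma samples
#' per compound.
#'
#' @param compound Compound (treatment) label for the study.
#' @param dose_levels Ordered dose-group labels, containing exactly one
#'   control label.
#' @param control Which element of `dose_levels` is the untreated control.
#' @param sexes Sex labels, default `c("M", "F")`.
#' @param sampling_days Strictly increasing integer study days (>= 1).
#' @param n_per_treated_group_per_sex Animals per sex in each treated group.
#' @param n_controls_per_sex Untreated control animals per sex.
#'
#' @return A list of class `study_design`.
#' @examples
#' d <- study_design("phenytoin")
#' n_animals(d)       # 40
#' n_samples(d)       # 120
#' @export
study_design <- function(compound = "compound",
                         dose_levels = c("control", "low", "high"),
                         control = "control",
                         sexes = c("M", "F"),
                         sampling_days = c(7L, 14L, 28L),
                         n_per_treated_group_per_sex = 5L,
                         n_controls_per_sex = 10L) {
  sampling_days <- as.integer(sampling_days)
  if (length(sampling_days) == 0 || any(sampling_days < 1) ||
      any(diff(sampling_days) <= 0)) {
    stop_moamatch("`sampling_days` must be strictly increasing integers >= 1.",
                  "validation_error")
  }
  if (sum(dose_levels == control) != 1) {
    stop_moamatch("`dose_levels` must contain the control label exactly once.",
                  "validation_error")
  }
  if (anyDuplicated(dose_levels)) {
    stop_moamatch("`dose_levels` must be distinct.", "validation_error")
  }
  if (n_per_treated_group_per_sex < 1 || n_controls_per_sex < 1) {
    stop_moamatch("Group sizes must be positive.", "validation_error")
  }
  structure(
    list(compound = compound,
         dose_levels = as.character(dose_levels),
         control = control,
         sexes = as.character(sexes),
         sampling_days = sampling_days,
         n_per_treated_group_per_sex = as.integer(n_per_treated_group_per_sex),
         n_controls_per_sex = as.integer(n_controls_per_sex)),
    class = "study_design")
}

#' Treated (non-control) dose groups of a design
#' @param design A `study_design`.
#' @return Character vector of non-control dose labels.
#' @export
treated_doses <- function(design) {
  setdiff(design$dose_levels, design$control)
}

#' Animal and sample counts implied by a design
#'
#' @param design A `study_design`.
#' @return `n_animals()`: total animals; `n_samples()`: total
#'   (animal, sampling day) plasma samples.
#' @export
n_animals <- function(design) {
  n_treated <- length(treated_doses(design)) * length(design$sexes) *
    design$n_per_treated_group_per_sex
  n_ctrl <- length(design$sexes) * design$n_controls_per_sex
  n_treated + n_ctrl
}

#' @rdname n_animals
#' @export
n_samples <- function(design) {
  n_animals(design) * length(design$sampling_days)
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$compound, "\n", sep = "")
  cat("  dose groups: ", paste(x$dose_levels, collapse = ", "),
      " (control: ", x$control, ")\n", sep = "")
  cat("  sexes: ", paste(x$sexes, collapse = "/"),
      "; days: ", paste(x$sampling_days, collapse = ", "), "\n", sep = "")
  cat("  animals: ", x$n_per_treated_group_per_sex, "/sex/treated group, ",
      x$n_controls_per_sex, "/sex controls -> ", n_animals(x),
      " animals, ", n_samples(x), " samples\n", sep = "")
  invisible(x)
}
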