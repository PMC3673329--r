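#' Construct an animal-level study profile
#'
#' A study profile holds every measured intensity for one compound study in
#' tidy long form: one row per (animal, day, analyte). Missing cells are
#' represented by absent rows, never by zeros or sentinels — intensities are
#' strictly positive semi-quantitative values.
#'
#' @param records A data frame with columns `animal_id`, `sex`, `dose_group`,
#'   `day`, `analyte_id`, `value`.
#' @param design A [study_design()].
#' @param panel An [analyte_panel()]; inferred from the records if `NULL`
#'   (all analytes flagged as identified).
#'
#' @return A tibble of class `study_profile` carrying the design and panel
#'   as attributes.
#' @export
study_profile <- function(records, design, panel = NULL) {
  records <- as_tibble(records)
  req <- c("animal_id", "sex", "dose_group", "day", "analyte_id", "value")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_moamatch(paste0("Profile records are missing column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "format_error")
  }
  if (is.null(panel)) {
    ids <- sort(unique(records$analyte_id))
    panel <- analyte_panel(analyte_id = ids, identified = rep(TRUE, length(ids)))
  }
  records <- records[, req]
  records$day <- as.integer(records$day)
  validate_study_profile(records, design, panel)
}

validate_study_profile <- function(records, design, panel) {
  if (!inherits(design, "study_design")) {
    stop_moamatch("`design` must be a study_design object.", "validation_error")
  }
  panel <- validate_analyte_panel(as_tibble(panel))
  bad_value <- which(!is.finite(records$value) | records$value <= 0)
  if (length(bad_value)) {
    stop_moamatch(
      paste0("Intensities must be positive finite numbers; offending row(s): ",
             paste(utils::head(bad_value, 5), collapse = ", ")),
      "validation_error", rows = bad_value)
  }
  if (anyDuplicated(records[c("animal_id", "day", "analyte_id")])) {
    stop_moamatch("Each (animal, day, analyte) may appear at most once.",
                  "integrity_error")
  }
  ann <- distinct(records, .data$animal_id, .data$sex, .data$dose_group)
  if (anyDuplicated(ann$animal_id)) {
    bad <- ann$animal_id[duplicated(ann$animal_id)]
    stop_moamatch(paste0("Animal(s) with inconsistent sex/dose annotation: ",
                         paste(unique(bad), collapse = ", ")),
                  "integrity_error")
  }
  if (!all(records$dose_group %in% design$dose_levels)) {
    stop_moamatch("Records contain dose groups not declared in the design.",
                  "integrity_error")
  }
  if (!all(records$sex %in% design$sexes)) {
    stop_moamatch("Records contain sexes not declared in the design.",
                  "integrity_error")
  }
  if (!all(records$analyte_id %in% panel$analyte_id)) {
    stop_moamatch("Records contain analytes not on the panel.",
                  "integrity_error")
  }
  records <- arrange(records, .data$animal_id, .data$day, .data$analyte_id)
  structure(records,
            design = design, panel = panel,
            class = c("study_profile", class(tibble())))
}

#' Design, panel and compound of a study profile
#' @param profile A `study_profile`.
#' @return The attached [study_design()], [analyte_panel()], or compound label.
#' @export
profile_design <- function(profile) attr(profile, "design")

#' @rdname profile_design
#' @export
profile_panel <- function(profile) attr(profile, "panel")

#' @rdname profile_design
#' @export
profile_compound <- function(profile) attr(profile, "design")$compound

#' Read an animal-level metabolite profile table
#'
#' Reads a tidy or wide delimited text file into a [study_profile()]. The
#' delimiter is inferred from the extension (`.tsv`/`.tab` tab, otherwise
#' comma). Tidy files need columns `animal`, `sex`, `dose_group`, `day`,
#' `analyte`, `value`; wide files need `animal`, `sex`, `dose_group`, `day`
#' plus one numeric column per analyte, and are normalised to long form on
#' input. Row order in the file never affects the result.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param format `"tidy"` (long) or `"wide"`.
#' @param control Label of the untreated control dose group.
#' @param design Optional [study_design()]; inferred from the data if `NULL`.
#' @param panel Optional [analyte_panel()]; inferred if `NULL`.
#'
#' @return A [study_profile()].
#' @export
read_profiles <- function(path, format = c("tidy", "wide"),
                          control = "control", design = NULL, panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_moamatch(paste0("File not found: ", path), "format_error")
  }
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, locale = readr::locale(decimal_mark = "."))
  if (format == "tidy") {
    req <- c("animal", "sex", "dose_group", "day", "analyte", "value")
    missing_cols <- setdiff(req, names(raw))
    if (length(missing_cols)) {
      stop_moamatch(paste0("Missing required column(s): ",
                           paste(missing_cols, collapse = ", ")),
                    "format_error")
    }
    long <- rename(raw, animal_id = "animal", analyte_id = "analyte")
  } else {
    req <- c("animal", "sex", "dose_group", "day")
    missing_cols <- setdiff(req, names(raw))
    if (length(missing_cols)) {
      stop_moamatch(paste0("Missing required column(s): ",
                           paste(missing_cols, collapse = ", ")),
                    "format_error")
    }
    analyte_cols <- setdiff(names(raw), req)
    if (!length(analyte_cols)) {
      stop_moamatch("Wide profile has no analyte columns.", "format_error")
    }
    long <- tidyr::pivot_longer(raw, cols = all_of(analyte_cols),
                                names_to = "analyte_id", values_to = "value")
    long <- rename(long, animal_id = "animal")
    long <- filter(long, !is.na(.data$value))  # absent cells, not sentinels
  }
  suppressWarnings(num <- as.numeric(long$value))
  bad <- which(is.na(num) | !is.finite(num) | num <= 0)
  if (length(bad)) {
    stop_moamatch(
      paste0("Non-numeric or non-positive intensity value(s) at data row(s): ",
             paste(utils::head(bad, 5), collapse = ", ")),
      "validation_error", rows = bad)
  }
  long$value <- num
  if (is.null(design)) {
    design <- infer_design(long, control)
  }
  study_profile(long, design, panel)
}

infer_design <- function(long, control) {
  doses <- unique(long$dose_group)
  if (!control %in% doses) {
    stop_moamatch(paste0("Control dose group '", control,
                         "' not present in the data."), "integrity_error")
  }
  treated <- sort(setdiff(doses, control))
  ann <- distinct(long, .data$animal_id, .data$sex, .data$dose_group)
  counts <- dplyr::count(ann, .data$sex, .data$dose_group)
  n_treated <- counts$n[counts$dose_group != control]
  n_ctrl <- counts$n[counts$dose_group == control]
  study_design(
    compound = "study",
    dose_levels = c(control, treated),
    control = control,
    sexes = sort(unique(long$sex)),
    sampling_days = sort(unique(as.integer(long$day))),
    n_per_treated_group_per_sex = max(n_treated, 1L),
    n_controls_per_sex = max(n_ctrl, 1L))
}

#' Write a study profile as a tidy delimited file
#'
#' @param profile A [study_profile()].
#' @param path Output path; `.tsv`/`.tab` writes tab-separated, anything
#'   else comma-separated.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profile, path) {
  out <- as_tibble(profile)
  out <- rename(out, animal = "animal_id", analyte = "analyte_id")
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' @export
print.study_profile <- function(x, ...) {
  d <- profile_design(x)
  cat("<study_profile> ", d$compound, ": ",
      dplyr::n_distinct(x$animal_id), " animals, ",
      nrow(distinct(x, .data$animal_id, .data$day)), " samples, ",
      dplyr::n_distinct(x$analyte_id), " analytes, ",
      nrow(x), " records\n", sep = "")
  NextMethod()
}
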