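#' Construct a mode-of-action metabolite pattern
#'
#' A MoA pattern is the signed, weighted metabolite signature of one
#' toxicological mode of action: for each signature analyte a direction
#' (+1 increased, -1 decreased) and a reference weight (the median Welch t
#' statistic over the reference compounds that established the analyte).
#' Patterns derived from data via [derive_pattern()] carry the reference
#' compound/dose provenance and a hold-out validation status.
#'
#' @param pattern_id Unique pattern identifier.
#' @param moa_name Human-readable mode-of-action name.
#' @param toxicity_label Target-organ/effect category used for toxicity
#'   tabulation (e.g. `"Kidney, tubular toxicity"`).
#' @param signature Data frame with columns `analyte_id`, `direction`
#'   (+1/-1) and `reference_weight` (signed real, same sign as `direction`).
#' @param provenance Data frame with columns `compound_id`, `dose_group`
#'   listing the reference treatments used to establish the pattern.
#' @param validated Logical; set by [validate_pattern()].
#' @param validation_report Free-text validation summary.
#'
#' @return A list of class `moa_pattern`.
#' @export
moa_pattern <- function(pattern_id, moa_name, toxicity_label, signature,
                        provenance = tibble(compound_id = character(),
                                            dose_group = character()),
                        validated = FALSE, validation_report = "") {
  signature <- as_tibble(signature)
  req <- c("analyte_id", "direction", "reference_weight")
  if (!all(req %in% names(signature))) {
    stop_moamatch("A signature needs analyte_id, direction and reference_weight columns.",
                  "format_error")
  }
  signature <- signature[, req]
  signature$direction <- as.integer(signature$direction)
  if (nrow(signature) == 0) {
    stop_moamatch("A pattern signature must not be empty.", "validation_error")
  }
  if (anyDuplicated(signature$analyte_id)) {
    stop_moamatch("Signature analytes must be unique.", "integrity_error")
  }
  if (!all(signature$direction %in% c(-1L, 1L)) ||
      any(signature$direction != sign(signature$reference_weight))) {
    stop_moamatch("Each signature direction must be +1/-1 and match the sign of its weight.",
                  "validation_error")
  }
  structure(
    list(pattern_id = as.character(pattern_id),
         moa_name = as.character(moa_name),
         toxicity_label = as.character(toxicity_label),
         signature = signature,
         provenance = as_tibble(provenance),
         validated = isTRUE(validated),
         validation_report = as.character(validation_report)),
    class = "moa_pattern")
}

#' @export
print.moa_pattern <- function(x, ...) {
  cat("<moa_pattern> ", x$pattern_id, " (", x$moa_name, ")\n", sep = "")
  cat("  toxicity: ", x$toxicity_label, "\n", sep = "")
  cat("  signature: ", nrow(x$signature), " analytes (",
      sum(x$signature$direction > 0), " up / ",
      sum(x$signature$direction < 0), " down)\n", sep = "")
  cat("  references: ", nrow(x$provenance), "; validated: ",
      x$validated, "\n", sep = "")
  invisible(x)
}

#' Serialise and restore MoA pattern sets
#'
#' Pattern sets are stored as JSON with one object per pattern; signed
#' weights are written at full precision so `read_pattern_set(write_pattern_set(x))`
#' is the identity, including analyte order.
#'
#' @param patterns List of [moa_pattern()] objects (may be empty).
#' @param path Path to the JSON file.
#' @return `write_pattern_set()` returns `path` invisibly;
#'   `read_pattern_set()` returns a list of `moa_pattern` objects.
#' @export
write_pattern_set <- function(patterns, path) {
  ids <- vapply(patterns, function(p) p$pattern_id, character(1))
  if (anyDuplicated(ids)) {
    stop_moamatch(paste0("Duplicated pattern id(s): ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                  "integrity_error")
  }
  payload <- list(
    format = "moamatch_pattern_set",
    version = 1L,
    patterns = lapply(patterns, function(p) {
      list(pattern_id = p$pattern_id,
           moa_name = p$moa_name,
           toxicity_label = p$toxicity_label,
           signature = list(
             analyte_id = as.list(p$signature$analyte_id),
             direction = as.list(p$signature$direction),
             reference_weight = as.list(p$signature$reference_weight)),
           provenance = list(
             compound_id = as.list(as.character(p$provenance$compound_id)),
             dose_group = as.list(as.character(p$provenance$dose_group))),
           validated = p$validated,
           validation_report = p$validation_report)
    }))
  # 17 significant digits: doubles survive the write/read round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  if (!file.exists(path)) {
    stop_moamatch(paste0("File not found: ", path), "format_error")
  }
  payload <- jsonlite::read_json(path)
  if (is.null(payload$patterns)) {
    stop_moamatch("Not a pattern-set file (no 'patterns' element).",
                  "format_error")
  }
  patterns <- lapply(payload$patterns, function(p) {
    moa_pattern(
      pattern_id = p$pattern_id,
      moa_name = p$moa_name,
      toxicity_label = p$toxicity_label,
      signature = tibble(
        analyte_id = unlist(p$signature$analyte_id),
        direction = as.integer(unlist(p$signature$direction)),
        reference_weight = as.numeric(unlist(p$signature$reference_weight))),
      provenance = tibble(
        compound_id = as.character(unlist(p$provenance$compound_id)),
        dose_group = as.character(unlist(p$provenance$dose_group))),
      validated = isTRUE(p$validated),
      validation_report = p$validation_report %||% "")
  })
  ids <- vapply(patterns, function(p) p$pattern_id, character(1))
  if (anyDuplicated(ids)) {
    stop_moamatch(paste0("Duplicated pattern id(s) in file: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                  "integrity_error")
  }
  patterns
}

`%||%` <- function(a, b) if (is.null(a)) b else a
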