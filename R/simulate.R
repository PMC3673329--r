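#' Define a planted mode-of-action effect
#'
#' A MoA effect is the simulator's ground truth: a signed log-scale shift for
#' each affected analyte, applied at reference dose scaling 1.0. Downstream,
#' [derive_pattern()] should recover the support and directions of these
#' shifts from the simulated reference compounds.
#'
#' @param moa_id Unique effect identifier.
#' @param toxicity_label Toxicity category the effect represents.
#' @param effect Named numeric vector: analyte_id -> signed log-scale shift.
#'   All shifts must be finite and non-zero.
#' @return A list of class `moa_effect`.
#' @export
moa_effect <- function(moa_id, toxicity_label, effect) {
  if (length(effect) == 0 || is.null(names(effect)) ||
      any(!nzchar(names(effect)))) {
    stop_moamatch("`effect` must be a non-empty named numeric vector.",
                  "validation_error")
  }
  if (any(!is.finite(effect)) || any(effect == 0)) {
    stop_moamatch("All effect shifts must be finite and non-zero.",
                  "validation_error")
  }
  structure(list(moa_id = as.character(moa_id),
                 toxicity_label = as.character(toxicity_label),
                 effect = effect),
            class = "moa_effect")
}

#' Configure the synthetic-study generator
#'
#' The generator draws lognormal intensities with additive log-scale
#' structure: for animal `a` of sex `s` in dose group `g`, on day `d` and
#' analyte `m`,
#' `log value = baseline(m) + sex_effect(s) + day_effect(d) +
#'  dose_scaling(g) * sum(strength * shift(m)) + N(0, residual_log_sd)`.
#' Sex and day offsets are shared by treated and control animals, so
#' matched-control comparisons cancel them. Per-analyte baselines are drawn
#' once per reference database so profile comparison across compounds is
#' meaningful.
#'
#' @param panel_size,n_identified Panel dimensions (defaults 225 / 167).
#' @param design A [study_design()] template; its compound label is replaced
#'   per simulated compound.
#' @param baseline_log_mean,baseline_log_sd Mean and spread of the
#'   per-analyte log-scale baselines (drawn once per database).
#' @param sex_effect Named log-scale offsets per sex.
#' @param day_effect Named log-scale offsets per sampling day; defaults to a
#'   mild drift of 0.05 log-units per sampling occasion.
#' @param dose_scaling Named multipliers on planted MoA shifts per dose
#'   group; the control entry must be 0.
#' @param residual_log_sd Residual log-scale noise standard deviation (> 0).
#' @param seed Integer master seed; all randomness is split deterministically
#'   from it (database baselines, then per-compound residuals).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(panel_size = 225, n_identified = 167,
                       design = study_design(),
                       baseline_log_mean = 5, baseline_log_sd = 1,
                       sex_effect = c(M = 0, F = 0.2),
                       day_effect = NULL,
                       dose_scaling = c(control = 0, low = 0.5, high = 1),
                       residual_log_sd = 0.3,
                       seed = 1L) {
  panel <- analyte_panel(panel_size, n_identified)
  if (is.null(day_effect)) {
    day_effect <- setNames(0.05 * (seq_along(design$sampling_days) - 1),
                           as.character(design$sampling_days))
  }
  if (!all(design$sexes %in% names(sex_effect))) {
    stop_moamatch("`sex_effect` must name every sex in the design.",
                  "validation_error")
  }
  if (!all(as.character(design$sampling_days) %in% names(day_effect))) {
    stop_moamatch("`day_effect` must name every sampling day in the design.",
                  "validation_error")
  }
  if (!all(design$dose_levels %in% names(dose_scaling))) {
    stop_moamatch("`dose_scaling` must name every dose group in the design.",
                  "validation_error")
  }
  if (dose_scaling[[design$control]] != 0) {
    stop_moamatch("`dose_scaling` must be 0 for the control group.",
                  "validation_error")
  }
  if (!is.numeric(residual_log_sd) || residual_log_sd <= 0) {
    stop_moamatch("`residual_log_sd` must be > 0.", "validation_error")
  }
  structure(
    list(panel = panel, design = design,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         sex_effect = sex_effect, day_effect = day_effect,
         dose_scaling = dose_scaling,
         residual_log_sd = residual_log_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Per-analyte baselines, drawn once per database (seed key 1).
draw_baselines <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  setNames(rnorm(nrow(config$panel), config$baseline_log_mean,
                 config$baseline_log_sd),
           config$panel$analyte_id)
}

# Sum of planted effects for one compound: named vector over the full panel.
compound_effect <- function(config, moas, assignment) {
  eff <- setNames(numeric(nrow(config$panel)), config$panel$analyte_id)
  if (is.null(assignment) || length(assignment) == 0) return(eff)
  moa_ids <- vapply(moas, function(m) m$moa_id, character(1))
  for (i in seq_along(assignment)) {
    id <- names(assignment)[i]
    strength <- assignment[[i]]
    if (strength < 0) {
      stop_moamatch("MoA strengths must be >= 0.", "validation_error")
    }
    j <- match(id, moa_ids)
    if (is.na(j)) {
      stop_moamatch(paste0("Unknown MoA id: ", id), "validation_error")
    }
    shifts <- moas[[j]]$effect
    unknown <- setdiff(names(shifts), config$panel$analyte_id)
    if (length(unknown)) {
      stop_moamatch(paste0("MoA '", id, "' shifts analytes not on the panel: ",
                           paste(utils::head(unknown, 5), collapse = ", ")),
                    "validation_error")
    }
    eff[names(shifts)] <- eff[names(shifts)] + strength * shifts
  }
  eff
}

#' Simulate one compound study
#'
#' Generates a complete [study_profile()] under the generator model of
#' [sim_config()]: every animal of the design is sampled on every sampling
#' day across the full panel.
#'
#' @param config A [sim_config()].
#' @param moas List of [moa_effect()] objects available to the simulator.
#' @param assignment Named numeric vector `c(moa_id = strength, ...)` giving
#'   this compound's planted modes of action; `NULL` or empty for a null
#'   (untreated-like) compound. Strengths must be >= 0.
#' @param compound Compound label for the simulated study.
#' @param compound_index Integer key used to split the residual-noise seed;
#'   [make_reference_db()] assigns consecutive indices.
#' @param baselines Optional named per-analyte baseline vector; drawn from
#'   `config` if `NULL`. Pass the database's baselines to keep compounds
#'   comparable.
#' @return A [study_profile()].
#' @examples
#' cfg <- sim_config(panel_size = 20, n_identified = 15, seed = 42)
#' prof <- simulate_study(cfg, compound = "null_compound")
#' nrow(dplyr::distinct(prof, animal_id, day))  # 120 samples
#' @export
simulate_study <- function(config, moas = list(), assignment = NULL,
                           compound = "simulated", compound_index = 1L,
                           baselines = NULL) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  design$compound <- compound
  if (is.null(baselines)) baselines <- draw_baselines(config)
  eff <- compound_effect(config, moas, assignment)

  animals <- purrr::map_dfr(design$sexes, function(s) {
    purrr::map_dfr(design$dose_levels, function(g) {
      n <- if (g == design$control) design$n_controls_per_sex else
        design$n_per_treated_group_per_sex
      tibble(animal_id = sprintf("%s_%s_%s_%02d", compound, s, g, seq_len(n)),
             sex = s, dose_group = g)
    })
  })
  grid <- tidyr::expand_grid(animals,
                             day = design$sampling_days,
                             analyte_id = config$panel$analyte_id)
  mu <- baselines[grid$analyte_id] +
    config$sex_effect[grid$sex] +
    config$day_effect[as.character(grid$day)] +
    config$dose_scaling[grid$dose_group] * eff[grid$analyte_id]
  set.seed(child_seed(config$seed, 2L, compound_index))
  grid$value <- unname(exp(mu + rnorm(nrow(grid), 0, config$residual_log_sd)))
  study_profile(grid, design, config$panel)
}

#' Build a synthetic reference database with planted MoA membership
#'
#' Simulates one study per assigned compound, sharing a single set of
#' per-analyte baselines, and records the planted ground truth alongside the
#' profiles so pattern derivation and matching can be tested for parameter
#' recovery. Identical `(config, moas, assignments)` yield an identical
#' database.
#'
#' @param config A [sim_config()].
#' @param moas List of [moa_effect()] objects.
#' @param assignments Named list: compound -> named numeric vector
#'   `c(moa_id = strength, ...)` (possibly empty for null compounds).
#' @param min_compounds_per_moa Emit a warning for MoAs carried (at positive
#'   strength) by fewer than this many compounds — pattern derivation will
#'   later refuse them. Default 3.
#' @return A list of class `reference_db` with elements `profiles` (named
#'   list of [study_profile()]), `truth` (tibble compound/moa_id/strength/
#'   toxicity_label), `moas` and `config`.
#' @export
make_reference_db <- function(config, moas = list(), assignments = list(),
                              min_compounds_per_moa = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(assignments)) && length(assignments)) {
    stop_moamatch("`assignments` must be a named list (compound -> MoA strengths).",
                  "validation_error")
  }
  moa_ids <- vapply(moas, function(m) m$moa_id, character(1))
  truth <- purrr::imap_dfr(assignments, function(a, cmpd) {
    if (length(a) == 0) return(tibble(compound = character()))
    tibble(compound = cmpd, moa_id = names(a), strength = as.numeric(a))
  })
  if (nrow(truth)) {
    unknown <- setdiff(truth$moa_id, moa_ids)
    if (length(unknown)) {
      stop_moamatch(paste0("Unknown MoA id(s) in assignments: ",
                           paste(unknown, collapse = ", ")),
                    "validation_error")
    }
    tox <- tibble(moa_id = moa_ids,
                  toxicity_label = vapply(moas, function(m) m$toxicity_label,
                                          character(1)))
    truth <- left_join(truth, tox, by = "moa_id")
    carriers <- dplyr::count(filter(truth, .data$strength > 0), .data$moa_id)
    weak <- carriers$moa_id[carriers$n < min_compounds_per_moa]
    if (length(weak)) {
      warn(paste0("MoA(s) carried by fewer than ", min_compounds_per_moa,
                  " compounds (pattern derivation will refuse them): ",
                  paste(weak, collapse = ", ")))
    }
  }
  baselines <- draw_baselines(config)
  profiles <- purrr::imap(assignments, function(a, cmpd) {
    simulate_study(config, moas, a, compound = cmpd,
                   compound_index = match(cmpd, names(assignments)),
                   baselines = baselines)
  })
  structure(list(profiles = profiles, truth = truth, moas = moas,
                 config = config),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", length(x$profiles), " compounds, ",
      length(x$moas), " MoA effects, panel of ",
      nrow(x$config$panel), " analytes\n", sep = "")
  invisible(x)
}
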