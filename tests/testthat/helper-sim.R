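# Shared simulation fixtures, all built in code under fixed seeds.

# n compounds with no planted effects
null_assignments <- function(n, prefix = "neg") {
  setNames(replicate(n, setNames(numeric(0), character(0)), simplify = FALSE),
           sprintf("%s%02d", prefix, seq_len(n)))
}

# one MoA effect planted on the first `support` panel analytes
planted_moa <- function(panel, support = 10, n_up = ceiling(support / 2),
                        shift = 1, moa_id = "kidney_moa",
                        toxicity = "Kidney, tubular toxicity") {
  ids <- panel$analyte_id[seq_len(support)]
  moa_effect(moa_id, toxicity,
             setNames(c(rep(shift, n_up), rep(-shift, support - n_up)), ids))
}

# small reference database with one planted MoA: n_refs carriers for
# derivation, one held-out carrier, n_neg effect-free negatives
planted_db <- function(seed = 7, panel_size = 60, n_identified = 50,
                       support = 10, shift = 1, residual_log_sd = 0.3,
                       n_refs = 3, n_neg = 6, toxicity = "Kidney, tubular toxicity") {
  cfg <- sim_config(panel_size = panel_size, n_identified = n_identified,
                    residual_log_sd = residual_log_sd, seed = seed)
  moa <- planted_moa(cfg$panel, support = support, shift = shift,
                     toxicity = toxicity)
  refs <- setNames(
    replicate(n_refs, setNames(1, moa$moa_id), simplify = FALSE),
    sprintf("ref%02d", seq_len(n_refs)))
  asg <- c(refs, list(heldout = setNames(1, moa$moa_id)),
           null_assignments(n_neg))
  db <- make_reference_db(cfg, list(moa), asg)
  list(cfg = cfg, moa = moa, db = db,
       ref_ids = names(refs), neg_ids = names(null_assignments(n_neg)))
}

# tiny deterministic stratum_results table for unit tests of downstream ops
manual_results <- function(rows, compound = "test",
                           design = study_design(compound)) {
  out <- tibble::as_tibble(rows)
  structure(out, compound = compound, alpha = 0.05, value_scale = "log",
            design = design,
            class = c("stratum_results", class(tibble::tibble())))
}

# write a tidy profile CSV for two animals x one day x two analytes
write_tiny_tidy_csv <- function(path, shuffle = FALSE) {
  df <- data.frame(
    animal = c("a1", "a1", "a2", "a2"),
    sex = "M",
    dose_group = c("control", "control", "high", "high"),
    day = 7L,
    analyte = c("m1", "m2", "m1", "m2"),
    value = c(1.5, 2.5, 3.0, 5.0))
  if (shuffle) df <- df[c(3, 1, 4, 2), ]
  utils::write.csv(df, path, row.names = FALSE)
  path
}
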