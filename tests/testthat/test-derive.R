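# hand-built per-compound stratum results: one row per (sex, day) stratum at
# the high dose, with chosen significance/direction per analyte
ref_result <- function(compound, sig_up = character(), sig_down = character(),
                       t_up = 4, t_down = -4) {
  strata <- expand.grid(sex = c("M", "F"), day = c(7L, 14L),
                        stringsAsFactors = FALSE)
  analytes <- union(sig_up, sig_down)
  rows <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    tibble::tibble(
      sex = strata$sex[i], day = strata$day[i], dose_group = "high",
      analyte_id = analytes,
      fold_change = ifelse(analytes %in% sig_up, 2, 0.5),
      t_value = ifelse(analytes %in% sig_up, t_up, t_down),
      dof = 10, p_value = 0.001, significant = TRUE,
      direction = ifelse(analytes %in% sig_up, "up", "down"))
  })
  manual_results(rows, compound = compound)
}

test_that("unanimously significant analytes form the signature", {
  refs <- list(c1 = ref_result("c1", sig_up = "A", sig_down = "B"),
               c2 = ref_result("c2", sig_up = "A", sig_down = "B"),
               c3 = ref_result("c3", sig_up = "A", sig_down = "B"))
  pat <- derive_pattern(refs, "Liver toxicity", "Liver toxicity")
  expect_equal(pat$signature$analyte_id, c("A", "B"))
  expect_equal(pat$signature$direction, c(1L, -1L))
  expect_equal(pat$signature$reference_weight, c(4, -4))
  expect_equal(nrow(pat$provenance), 3)
  expect_false(pat$validated)
})

test_that("the consistency fraction gates admission exactly at its ceiling", {
  refs <- list(c1 = ref_result("c1", sig_up = c("A", "C")),
               c2 = ref_result("c2", sig_up = c("A", "C")),
               c3 = ref_result("c3", sig_up = "A"))
  with_c <- derive_pattern(refs, "m", "t", consistency_fraction = 2 / 3)
  expect_true("C" %in% with_c$signature$analyte_id)
  without_c <- derive_pattern(refs, "m", "t", consistency_fraction = 1.0)
  expect_false("C" %in% without_c$signature$analyte_id)
  expect_equal(without_c$signature$analyte_id, "A")
})

test_that("derivation refuses too few references or no consistent signal", {
  refs2 <- list(c1 = ref_result("c1", sig_up = "A"),
                c2 = ref_result("c2", sig_up = "A"))
  expect_error(derive_pattern(refs2, "m", "t"),
               class = "moamatch_insufficient_references")

  disjoint <- list(c1 = ref_result("c1", sig_up = "A"),
                   c2 = ref_result("c2", sig_up = "B"),
                   c3 = ref_result("c3", sig_up = "C"))
  expect_error(derive_pattern(disjoint, "m", "t"),
               class = "moamatch_no_consistent_signal")
})

test_that("derivation is invariant to reference order and shrinks monotonely", {
  refs <- list(c1 = ref_result("c1", sig_up = c("A", "C"), sig_down = "B"),
               c2 = ref_result("c2", sig_up = "A", sig_down = c("B", "D")),
               c3 = ref_result("c3", sig_up = c("A", "C"), sig_down = "B"))
  p1 <- derive_pattern(refs, "m", "t")
  p2 <- derive_pattern(rev(refs), "m", "t")
  expect_equal(p1$signature, p2$signature)

  # raising the fraction can only shrink the signature
  fractions <- c(1 / 3, 1 / 2, 2 / 3, 0.9, 1)
  sizes <- vapply(fractions, function(f) {
    nrow(derive_pattern(refs, "m", "t", consistency_fraction = f)$signature)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  sets <- lapply(fractions, function(f) {
    derive_pattern(refs, "m", "t", consistency_fraction = f)$signature$analyte_id
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("per-compound median t over significant strata sets weights", {
  # analyte A significant in 3 strata with t = 1, 2, 6 -> per-compound
  # median 2; across compounds medians 2, 3, 10 -> weight 3
  one_ref <- function(cmpd, ts) {
    rows <- tibble::tibble(
      sex = "M", day = c(7L, 14L, 28L), dose_group = "high",
      analyte_id = "A", fold_change = 2, t_value = ts, dof = 10,
      p_value = 0.01, significant = TRUE, direction = "up")
    manual_results(rows, compound = cmpd)
  }
  refs <- list(c1 = one_ref("c1", c(1, 2, 6)),
               c2 = one_ref("c2", c(3, 3, 3)),
               c3 = one_ref("c3", c(9, 10, 11)))
  pat <- derive_pattern(refs, "m", "t")
  expect_equal(pat$signature$reference_weight, 3)
})

test_that("at stringent derivation levels the signature equals the planted support", {
  # with a strict per-stratum level the expected number of null analytes
  # slipping through the consistency rule is far below one, so the derived
  # signature should coincide exactly with the planted support
  env <- planted_db(seed = 47, panel_size = 100, n_identified = 80,
                    support = 12, shift = 1, residual_log_sd = 0.3)
  refs <- lapply(env$db$profiles[env$ref_ids], stratified_diff,
                 alpha = 0.001)
  pat <- derive_pattern(refs, env$moa$moa_id, env$moa$toxicity_label)
  expect_setequal(pat$signature$analyte_id, names(env$moa$effect))
  expect_equal(
    pat$signature$direction[match(names(env$moa$effect),
                                  pat$signature$analyte_id)],
    as.integer(sign(env$moa$effect)))
})

test_that("hold-out validation passes on a clean positive and rejects leakage", {
  env <- planted_db(seed = 13)
  res_refs <- lapply(env$db$profiles[env$ref_ids], stratified_diff,
                     alpha = 0.01)
  pat <- derive_pattern(res_refs, env$moa$moa_id, env$moa$toxicity_label)

  others <- lapply(env$db$profiles[c("heldout", env$neg_ids)],
                   stratified_diff)
  thr <- calibrate_thresholds(
    lapply(others[env$neg_ids], median_t_profile, dose_group = "high"))
  val <- validate_pattern(pat, others["heldout"], others[env$neg_ids], thr)
  expect_true(val$passed)
  expect_gte(val$positive_hits, 1)
  expect_equal(val$negative_hits, 0)
  expect_true(val$pattern$validated)

  expect_error(
    validate_pattern(pat, setNames(res_refs[1], env$ref_ids[1]),
                     others[env$neg_ids], thr),
    class = "moamatch_leakage_error")
  expect_error(validate_pattern(pat, list(), others[env$neg_ids], thr),
               class = "moamatch_validation_error")
})

test_that("signature-orthogonal negatives are never identified", {
  # pattern on analytes A, B; negatives respond only on X, Y
  pat <- moa_pattern("p", "m", "t",
                     tibble::tibble(analyte_id = c("A", "B", "C"),
                                    direction = c(1L, 1L, -1L),
                                    reference_weight = c(4, 3, -4)))
  neg_rows <- tibble::tibble(
    sex = rep(c("M", "F"), each = 3),
    day = rep(c(7L, 14L, 28L), 2), dose_group = "high",
    analyte_id = rep("X", 6), fold_change = 2, t_value = 5, dof = 10,
    p_value = 0.001, significant = TRUE, direction = "up")
  # add non-significant coverage of the signature analytes so overlap exists
  sig_rows <- tidyr::expand_grid(
    sex = c("M", "F"), day = c(7L, 14L, 28L),
    analyte_id = c("A", "B", "C")) |>
    dplyr::mutate(dose_group = "high",
                  fold_change = c(1.01, 0.99, 1.02)[match(analyte_id, c("A", "B", "C"))],
                  t_value = c(0.1, -0.2, 0.05)[match(analyte_id, c("A", "B", "C"))],
                  dof = 10, p_value = 0.9, significant = FALSE,
                  direction = "none")
  neg <- manual_results(dplyr::bind_rows(neg_rows, sig_rows), compound = "neg")
  pos_rows <- dplyr::mutate(sig_rows,
                            t_value = c(4, 3, -4)[match(analyte_id, c("A", "B", "C"))],
                            p_value = 0.001, significant = TRUE,
                            direction = ifelse(t_value > 0, "up", "down"),
                            fold_change = ifelse(t_value > 0, 2, 0.5))
  pos <- manual_results(pos_rows, compound = "pos")
  thr <- threshold_set(c(M = 0.5, F = 0.6))
  val <- validate_pattern(pat, list(pos = pos), list(neg = neg), thr)
  expect_true(val$passed)
  expect_equal(val$negative_hits, 0)
})
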