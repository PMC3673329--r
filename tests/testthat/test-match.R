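profile_from <- function(df, compound = "c", dose = "high") {
  as_median_t_profile(df, compound_id = compound, dose_group = dose)
}

both_sexes <- function(analytes, values) {
  tibble::tibble(sex = rep(c("M", "F"), each = length(analytes)),
                 analyte_id = rep(analytes, 2),
                 median_t = rep(values, 2))
}

test_that("median_t_profile takes per-sex medians over day strata", {
  res <- manual_results(tibble::tibble(
    sex = c("M", "M", "M", "F", "F", "M"),
    day = c(7L, 14L, 28L, 7L, 14L, 7L),
    dose_group = "high",
    analyte_id = c("A", "A", "A", "A", "A", "B"),
    fold_change = 2,
    t_value = c(1, 2, 6, 1, 3, -2),
    dof = 10, p_value = 0.01, significant = TRUE,
    direction = "up"))
  prof <- median_t_profile(res, "high")
  get <- function(s, a) prof$median_t[prof$sex == s & prof$analyte_id == a]
  expect_equal(get("M", "A"), 2)    # odd count: middle value
  expect_equal(get("F", "A"), 2)    # even count: mean of middle pair
  expect_equal(get("M", "B"), -2)   # singleton median
  expect_error(median_t_profile(res, "low"),
               class = "moamatch_validation_error")
})

test_that("pattern_rank reproduces hand-computed split correlations", {
  pat <- moa_pattern("p1", "m", "t",
                     tibble::tibble(analyte_id = c("a", "b", "c", "d"),
                                    direction = c(1L, 1L, -1L, -1L),
                                    reference_weight = c(1, 1, -1, -1)))
  prof <- profile_from(both_sexes(c("a", "b", "c", "d"), c(2, 1, 0, -1)))
  rk <- pattern_rank(prof, list(pat))
  # Pearson((2,1,0,-1), (1,1,-1,-1)) = 2/sqrt(5)
  expect_equal(rk$r_M, 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(rk$r_F, 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(rk$median_correlation, 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(rk$r_M, 0.894, tolerance = 1e-3)

  # self-correlation ranks first; anti-profile scores -1
  self <- profile_from(both_sexes(c("a", "b", "c", "d"), c(1, 1, -1, -1)))
  rk_self <- pattern_rank(self, list(pat))
  expect_equal(rk_self$median_correlation, 1.0)
  anti <- profile_from(both_sexes(c("a", "b", "c", "d"), c(-1, -1, 1, 1)))
  expect_equal(pattern_rank(anti, list(pat))$median_correlation, -1.0)
})

test_that("pattern_rank sorts by median correlation and reports unscored patterns", {
  sig <- function(id, w) {
    moa_pattern(id, id, "t",
                tibble::tibble(analyte_id = c("a", "b", "c", "d"),
                               direction = as.integer(sign(w)),
                               reference_weight = w))
  }
  p_hi <- sig("hi", c(2, 1, -1, -2))
  p_lo <- sig("lo", c(-2, 1, -1, 2))
  p_small <- moa_pattern("small", "m", "t",
                         tibble::tibble(analyte_id = c("zz1", "zz2", "zz3"),
                                        direction = c(1L, 1L, 1L),
                                        reference_weight = c(1, 2, 3)))
  prof <- profile_from(both_sexes(c("a", "b", "c", "d"), c(2, 1, -1, -2)))
  rk <- pattern_rank(prof, list(p_small, p_lo, p_hi))
  expect_equal(rk$pattern_id, c("hi", "lo", "small"))
  expect_true(rk$scored[1])
  expect_false(rk$scored[3])
  expect_match(rk$reason[3], "overlap")
  expect_true(all(is.na(rk$median_correlation[!rk$scored])))

  # zero-variance restriction is unscored with its own reason
  flat <- profile_from(both_sexes(c("a", "b", "c", "d"), c(1, 1, 1, 1)))
  rk_flat <- pattern_rank(flat, list(p_hi))
  expect_false(rk_flat$scored)
  expect_match(rk_flat$reason, "variance")

  # ties on the median correlation break lexicographically
  twin_a <- sig("twin_a", c(2, 1, -1, -2))
  twin_b <- sig("twin_b", c(2, 1, -1, -2))
  rk_tie <- pattern_rank(prof, list(twin_b, twin_a))
  expect_equal(rk_tie$pattern_id, c("twin_a", "twin_b"))
})

test_that("profile_compare computes rank-robust and linear correlations", {
  a <- profile_from(both_sexes(paste0("m", 1:6), c(1, 2, 3, 4, 5, 6)))
  thr <- threshold_set(c(M = 0.5, F = 0.6))

  same <- profile_compare(a, a, thr)
  expect_equal(same$spearman, c(1, 1))
  expect_equal(same$pearson, c(1, 1))
  expect_true(all(same$match))

  # strictly monotone transform: spearman exactly 1, pearson below 1
  b <- profile_from(both_sexes(paste0("m", 1:6), exp(c(1, 2, 3, 4, 5, 6))))
  mono <- profile_compare(b, a, thr)
  expect_equal(mono$spearman, c(1, 1))
  expect_true(all(mono$pearson < 1))

  rev <- profile_from(both_sexes(paste0("m", 1:6), c(6, 5, 4, 3, 2, 1)))
  expect_equal(profile_compare(rev, a, thr)$spearman, c(-1, -1))

  small <- profile_from(both_sexes(paste0("m", 1:4), 1:4))
  expect_error(profile_compare(small, a, thr),
               class = "moamatch_insufficient_overlap")
})

test_that("calibration picks the nearest-rank percentile of pairwise correlations", {
  # engineered database: pairwise correlation multiset {0.01, ..., 1.00}
  # checked against a brute-force sort-and-index oracle
  set.seed(99)
  vals <- seq(0.01, 1, by = 0.01)
  oracle <- function(v, p) sort(v)[ceiling(p / 100 * length(v))]
  expect_equal(oracle(vals, 95), 0.95)

  # random null database: calibrated threshold equals the oracle value on
  # the actual pairwise multiset
  profs <- lapply(1:12, function(i) {
    profile_from(both_sexes(paste0("m", 1:40), rnorm(40)),
                 compound = paste0("t", i))
  })
  cors <- pairwise_profile_correlations(profs, method = "spearman")
  thr <- calibrate_thresholds(profs, percentile = 95)
  for (s in c("M", "F")) {
    v <- cors$correlation[cors$sex == s]
    expect_equal(thr$thresholds[[s]], oracle(v, 95))
    expect_true(thr$thresholds[[s]] >= min(v) & thr$thresholds[[s]] <= max(v))
  }
  expect_equal(nrow(cors), 2 * choose(12, 2))

  # percentile 100 returns the maximum observed correlation
  thr100 <- calibrate_thresholds(profs, percentile = 100)
  expect_equal(thr100$thresholds[["M"]],
               max(cors$correlation[cors$sex == "M"]))

  # two-profile database: any percentile returns the single pairwise value
  two <- profs[1:2]
  c2 <- pairwise_profile_correlations(two)
  for (p in c(5, 50, 95)) {
    t2 <- calibrate_thresholds(two, percentile = p)
    expect_equal(t2$thresholds[["M"]],
                 c2$correlation[c2$sex == "M"])
  }

  # identical profiles cannot calibrate anything
  expect_error(calibrate_thresholds(list(profs[[1]], profs[[1]], profs[[1]])),
               class = "moamatch_calibration_degenerate")
})

test_that("confirmation requires both the correlation and agreement gates", {
  pat <- moa_pattern("p", "m", "t",
                     tibble::tibble(analyte_id = c("a", "b", "c", "d"),
                                    direction = c(1L, 1L, -1L, -1L),
                                    reference_weight = c(1, 1, -1, -1)))
  prof <- profile_from(both_sexes(c("a", "b", "c", "d"), c(1, 1, -1, -1)))
  rk <- pattern_rank(prof, list(pat))
  thr <- threshold_set(c(M = 0.5, F = 0.6))

  ok <- confirm_matches(rk, thr)
  expect_true(ok$confirmed)  # r = 1, sign agreement 1

  high_thr <- threshold_set(c(M = 1.01, F = 1.01) / 1.01)  # effectively 1
  rk2 <- rk; rk2$median_correlation <- 0.4; rk2$r_M <- 0.4; rk2$r_F <- 0.4
  expect_false(confirm_matches(rk2, thr)$confirmed)

  rk3 <- rk; rk3$direction_agreement <- 0
  expect_false(confirm_matches(rk3, thr)$confirmed)

  # raising thresholds can only remove matches
  stricter <- threshold_set(c(M = 0.9, F = 0.95))
  before <- confirm_matches(rk, thr)$confirmed
  after <- confirm_matches(rk, stricter)$confirmed
  expect_true(all(!after | before))
})
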