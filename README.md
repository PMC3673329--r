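# moamatch

Mode-of-action (MoA) metabolite pattern matching for preclinical safety
assessment.

`moamatch` turns animal-level plasma metabolite profiles from repeat-dose
rodent studies into toxicological safety signals. It is written for
toxicologists and biostatisticians who screen candidate compounds against
a reference library of MoA metabolite signatures — the approach behind
curated toxicometabolomics databases — and for method developers who need
an open, fully tested implementation of that pipeline to study its
operating characteristics.

## The method

A study measures a panel of `m` semi-quantitative plasma analytes in
treated and untreated rats of both sexes on several study days. The
pipeline is:

1. **Stratified differential analysis.** For each stratum (sex `s`, day
   `d`, dose group `g`) and analyte, the fold change is the ratio of
   arithmetic means against the matched controls (same sex and day),
   and significance comes from Welch's heteroscedastic *t* test,

   FC = x̄_treated / x̄_control,  t = (x̄₁ − x̄₂) / √(s₁²/n₁ + s₂²/n₂),

   with Welch–Satterthwaite degrees of freedom and two-sided p < 0.05.

2. **Signature derivation.** A MoA pattern is built from ≥ 3 reference
   compounds sharing the mode of action: an analyte enters the signature
   when it is significant with a consistent direction in ≥ ⌈2/3 · n⌉ of
   the references; its weight is the median of the per-compound median
   *t* values. Patterns must then identify a held-out carrier of the MoA
   and no negative reference compound before they count as validated.

3. **Matching.** A test compound's fingerprint — per sex and analyte, the
   median signed *t* across day strata at one dose — is correlated with
   each signature (Pearson, per sex, summarised by the median: a "split
   correlation") and with whole reference fingerprints (Spearman and
   Pearson). Sex-specific match thresholds are calibrated as the
   95th nearest-rank percentile of all pairwise profile correlations in
   the reference database, so ~5% of null comparisons exceed them.

4. **Toxicity tabulation.** Rule-confirmed pattern matches are counted
   per toxicity category and dose: a pattern counts in a dose column when
   it is confirmed at either dose and its median correlation at that dose
   exceeds 0.5, with grand totals per column.

Because curated reference databases are proprietary, the package includes
a lognormal synthetic-study generator that emulates the assumed design
(2 dose groups × 5 rats/sex + 10 controls/sex, days 7/14/28, 225-analyte
panel) and plants known MoA effects, so the whole pipeline is testable
for parameter recovery. See `vignette("moamatch-methods")` for the model,
its assumptions and the design decisions.

## Worked example

Build a small synthetic reference database with one planted kidney MoA,
derive and validate the pattern, then screen a held-out carrier:

```r
library(moamatch)
library(purrr)

cfg <- sim_config(panel_size = 60, n_identified = 50, seed = 7)
moa <- moa_effect("kidney_tubular", "Kidney, tubular toxicity",
                  setNames(c(rep(1, 6), rep(-1, 4)), cfg$panel$analyte_id[1:10]))
assignments <- c(
  list(ref1 = c(kidney_tubular = 1), ref2 = c(kidney_tubular = 1),
       ref3 = c(kidney_tubular = 1), candidate = c(kidney_tubular = 1)),
  setNames(replicate(6, setNames(numeric(0), character(0)), simplify = FALSE),
           paste0("neg", 1:6)))
db <- make_reference_db(cfg, list(moa), assignments)

# derive the signature from three reference compounds (stricter alpha)
ref_results <- map(db$profiles[c("ref1", "ref2", "ref3")],
                   stratified_diff, alpha = 0.01)
pattern <- derive_pattern(ref_results, "Kidney tubular injury",
                          "Kidney, tubular toxicity")
pattern
#> <moa_pattern> kidney_tubular_injury (Kidney tubular injury)
#>   toxicity: Kidney, tubular toxicity
#>   signature: 10 analytes (6 up / 4 down)
#>   references: 3; validated: FALSE

# calibrate thresholds from the unrelated (negative) treatments
other <- map(db$profiles[c("candidate", paste0("neg", 1:6))], stratified_diff)
thresholds <- calibrate_thresholds(
  map(other[paste0("neg", 1:6)], median_t_profile, dose_group = "high"))
thresholds
#> <threshold_set> F = 0.266, M = 0.269
#>   calibrated at the 95th percentile (spearman, nearest rank)

# hold-out validation: one further carrier, six negatives
val <- validate_pattern(pattern, other["candidate"],
                        other[paste0("neg", 1:6)], thresholds)
val
#> <pattern_validation> kidney_tubular_injury: PASSED
#>   hold-out validation: 1/1 positives identified, 0/6 negatives identified -> passed

# screen the candidate end to end
report <- run_pipeline(db$profiles$candidate, list(val$pattern), thresholds)
report
#> <match_report> candidate
#>   significant (stratum, analyte) calls: 134 of 720
#>   low dose: 1 rule-confirmed pattern match(es)
#>   high dose: 1 rule-confirmed pattern match(es)
#>   toxicity grand totals: low = 1, high = 1
#>   note: confirmation surrogate: median correlation >= 0.266 (min over sexes) AND best-stratum direction agreement >= 0.60
#>   note: tabulation: pattern-level either-dose confirmation gate; per-dose floor median correlation > 0.50 (strict)
```

The derived signature recovers exactly the ten planted analytes with
their directions; the validated pattern then flags the planted kidney
toxicity for the candidate at both doses (its correlation clears the 0.5
tabulation floor at each). `tidy()`, `glance()` and `autoplot()` methods
on the result objects give the tables and figures; `read_profiles()` /
`write_pattern_set()` handle the CSV/TSV and JSON interchange formats.

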