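---
title: "Methods: mode-of-action metabolite pattern matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mode-of-action metabolite pattern matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moamatch)
library(dplyr)
```

## The problem

Repeat-dose rodent studies remain the workhorse of preclinical safety
assessment, but their standard read-outs (clinical pathology,
histopathology) can miss toxicities — drug-induced kidney injury in
particular — that only become apparent clinically. Plasma metabolite
profiling offers a systemic read-out from the same animals: a panel of a
few hundred semi-quantitative analytes measured at several time points. If
a reference database links characteristic metabolite-change signatures to
toxicological modes of action (MoA) — liver enzyme induction, kidney
tubular toxicity, bone-marrow suppression, and so on — then a new
compound's metabolite response can be screened against those signatures to
flag likely toxicities before they are morphologically visible.

`moamatch` implements that screening pipeline as reusable, tested R code:

1. **Stratified differential analysis** of the animal-level intensities
   against matched controls (`stratified_diff()`).
2. **Signature derivation** of MoA patterns from reference compounds that
   share a mode of action, with hold-out validation
   (`derive_pattern()`, `validate_pattern()`).
3. **Pattern ranking and profile comparison** of a test compound against
   the signature library and against whole reference profiles, with
   sex-specific match thresholds calibrated as a percentile of the null
   pairwise-correlation distribution (`pattern_rank()`,
   `profile_compare()`, `calibrate_thresholds()`).
4. **Toxicity tabulation**: dose-stratified counts of rule-confirmed
   pattern matches per toxicity category with grand totals
   (`tabulate_toxicities()`), composed end to end by `run_pipeline()`.

Because curated reference databases of this kind are proprietary, the
package ships a **synthetic-study generator** (`sim_config()`,
`simulate_study()`, `make_reference_db()`) that emulates the assumed study
design and plants known MoA effects, so every stage can be tested for
parameter recovery without external data.

## Study design and data model

The design the statistics assume is a 28-day rat study: per compound, two
dose groups (low, high) of 5 males and 5 females each, plus 10 untreated
males and 10 untreated females as controls, with plasma sampled on study
days 7, 14 and 28 — 40 animals and 120 plasma samples per compound. The
assay panel holds 225 semi-quantitative plasma analytes, 167 chemically
identified and 58 unknown. Both are defaults, not constraints:
`study_design()` and `analyte_panel()` accept any dose groups, days and
panel sizes.

Data are tidy and long: one row per (animal, day, analyte) with a strictly
positive intensity. Missing cells are *absent rows*, never zeros or
sentinels — semi-quantitative intensities have no meaningful zero, and
absence composes correctly with the per-cell sample-size preconditions
downstream. Analyte identifiers are opaque strings; with 58 unknowns on
the reference panel, no chemical ontology can be assumed.

## Differential analysis

For every stratum — a (sex, study day, non-control dose group)
combination — and every analyte, the treated group is compared with the
study's untreated controls of the same sex and day:

* **Fold change** is the ratio of arithmetic means on the linear intensity
  scale, `mean(treated) / mean(control)`.
* **Significance** comes from Welch's heteroscedastic two-sample *t* test
  with Welch–Satterthwaite degrees of freedom, two-sided, at
  `alpha = 0.05` per analyte. The statistic is signed
  `(mean(treated) - mean(control)) / SE`.

Two choices deserve comment:

* **Test scale.** By default the test runs on log-transformed intensities
  (`value_scale = "log"`), matching the lognormal error model under which
  effects are multiplicative; `value_scale = "linear"` preserves the
  literal raw-scale reading. Fold changes are linear-scale ratios in
  either case. On simulated data the choice moves individual p values but
  not the calibration of the procedure.
* **No multiple-testing correction** by default. The screening convention
  this pipeline reproduces applies raw per-analyte p < 0.05; the
  per-stratum expected false-positive count (about 11 of 225 analytes) is
  part of how the downstream consistency and confirmation rules are
  tuned. `p_adjust_method` exposes correction for users who want it.

Cells with fewer than 2 treated or 2 control values are dropped with a
warning (absence, never a significance call). A cell with zero variance in
*both* groups raises an error rather than returning p = 0: on continuous
intensity data that situation indicates a broken input (constant columns,
unit mix-ups), not evidence.

`count_changes()` tallies significant increases and decreases per stratum
— the conventional "total metabolite changes" study summary
(`plot_change_counts()` draws it).

## Signature derivation and validation

A MoA pattern is derived from at least three reference compounds sharing
the mode of action (`derive_pattern()`):

1. Per reference compound, the strata of its designated dose group
   (default `"high"`) are pooled: for each analyte the *per-compound
   direction* is the sign of its median *t* over the strata in which it
   was significant.
2. An analyte enters the signature when it is significant with one
   consistent direction in at least
   `ceiling(consistency_fraction * n_compounds)` references
   (default fraction 2/3).
3. Its *reference weight* is the median, over the qualifying references,
   of the per-compound median *t* values — so signatures and test
   fingerprints share one currency (signed *t*), and correlation-based
   ranking needs no unit conversion.

In the curated-database original, step 2 is an expert consistency review
by toxicologists. The fraction rule is this package's declared
deterministic surrogate, and it is deliberately paired with a **stricter
derivation significance level**: reference stratum results should be
computed at `alpha = 0.01` (the package's derivation workflows do this)
rather than the matching-stage 0.05. The arithmetic: at alpha 0.05 a null
analyte has a ~26% chance of at least one significant stratum among the 6
pooled (2 sexes x 3 days), so the 2-of-3-references rule would admit
roughly 0.1 junk analyte per null analyte — about 20 spurious entries on a
225-analyte panel, which would dilute the direction-agreement gate at
confirmation time. At alpha 0.01 the expected number of spurious signature
entries drops to about one per pattern, and at 0.001 far below one, which
is the regime in which the package's recovery tests require the derived
signature to equal the planted support exactly.

`validate_pattern()` enforces the hold-out contract: the pattern must
identify at least one further carrier of the MoA that was *not* used to
establish it, and must identify none of the supplied negative reference
compounds. "Identify" means a rule-confirmed match (below) at either
non-control dose. Positives overlapping the pattern's provenance raise a
leakage error rather than silently inflating validation.

## Matching and thresholds

A treatment's **median-*t* fingerprint** (`median_t_profile()`) is, per
sex and analyte, the median signed *t* over that sex's day strata at one
dose.

**Pattern ranking** correlates the fingerprint with each signature's
reference weights, restricted to the signature analytes — a *split
correlation*: computed separately per sex, summarised by the median of the
per-sex values (for two sexes, their mean). The split is by sex because
match thresholds are sex-specific; this interpretation is worth flagging,
since "split" could in principle also mean by day or by analyte subset.
Patterns sharing fewer than `min_signature_overlap = 3` analytes with the
fingerprint are reported unscored (a correlation on fewer points is
meaningless), as are zero-variance restrictions.

**Profile comparison** (`profile_compare()`) correlates two treatments'
full fingerprints with both Spearman (average-rank ties) and Pearson
coefficients per sex; a sex matches when the larger of the two reaches
that sex's threshold. The package reuses the median-*t* fingerprint for
both matching routes so the two stay comparable.

**Threshold calibration** (`calibrate_thresholds()`) computes all
unordered pairwise profile correlations among the database treatments, per
sex, and takes the empirical percentile (default 95) under the
*nearest-rank* convention — no interpolation, so a calibrated threshold is
always an observed correlation value and the procedure is bit-stable
across implementations. By construction, about 5% of null pairwise
correlations exceed the threshold; on a synthetic null database of 40
treatments the attained percentile rank is exactly 95.0 (rank 741 of 780
pairs). Spearman is the calibration default because median-*t* values are
heavy-tailed. The widely quoted 0.50 (male) / 0.60 (female) thresholds of
curated databases are properties of *those* databases obtained by this
contract, not constants of the method; `threshold_set()` accepts them
directly when appropriate.

**Confirmation** (`confirm_matches()`) replaces the expert panel's
"confirmed match" judgement with a declared two-condition rule: median
split correlation at or above the smaller of the per-sex thresholds, *and*
best-stratum direction agreement — the largest, over the dose's strata, of
the fraction of signature analytes significantly changed in the pattern's
direction — at or above `min_direction_agreement = 0.6`. Both constants
are configuration; reports log the rule and label matches rule-confirmed,
never expert-confirmed.

## Toxicity tabulation

`tabulate_toxicities()` builds the per-compound summary table: patterns
map to toxicity categories, and a pattern contributes to dose column *d*
when it is rule-confirmed **at either dose** and its median correlation at
dose *d* strictly exceeds the fixed floor of 0.5. The either-dose gate
with per-dose floor reproduces the dose-asymmetric rows such tables show
(a pattern confirmed only at the high dose can still appear in the low
column when its low-dose correlation clears the floor — a documented
reading of an ambiguous convention). Patterns whose provenance includes
the test compound itself are counted but listed in the table's
annotations, mirroring the footnote convention for circular references.
`grand_total()` is the column sum and is checked against the table on
every construction.

## The synthetic-study generator

The generator is first-class, tested code, not a fixture. Intensities are
lognormal with additive log-scale structure: for animal of sex $s$ in dose
group $g$, day $d$, analyte $m$,

$$\log Y = \beta_m + u_s + v_d + \lambda_g \sum_k w_k \, \delta_{k,m} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with per-analyte baselines $\beta_m$ drawn once per reference database
(profiles across compounds stay comparable), sex and day offsets $u_s,
v_d$ shared by treated and control animals (matched-control ratios cancel
them exactly), dose scaling $\lambda_g$ multiplying the planted MoA shift
vectors $\delta_k$ weighted by compound-specific strengths $w_k$ (one
compound can carry several toxicities), and i.i.d. residual noise. The
model guarantees positivity and makes fold changes the natural effect
parameterisation; the original study reports only ratios and significance,
so the noise model is the package's own choice.

Defaults, chosen once as plausible for semi-quantitative plasma panels and
not revisited: baseline log-mean 5, between-analyte baseline log-sd 1,
female offset +0.2, day drift +0.05 per sampling occasion, dose scaling
0 / 0.5 / 1 for control / low / high, residual log-sd 0.3, planted shifts
of 1.0 log-unit on 10–20 analytes. With shift 1.0, n = 5 vs 10 and sd
0.3, the per-stratum noncentrality is about 6 — strongly detectable, as a
pattern-bearing reference compound should be.

All randomness splits deterministically from one integer seed via a
Lehmer-style recurrence keyed by stage and compound index
(database baselines -> per-compound residual streams), so identical
configurations are bit-identical and sub-experiments are reproducible in
isolation.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: correlated analytes (real metabolite panels are
strongly co-regulated; effective dimensionality is lower than 225, so real
null pairwise-correlation distributions are wider than the simulated
ones), pharmacokinetics (no absorption/clearance, no time-by-dose
interaction beyond the fixed day offsets), missingness mechanisms
(detection limits), heteroscedasticity across analytes, and any
body-weight or clinical-pathology endpoints.

## Numerical choices and degenerate inputs

* Welch statistics are computed vectorised from per-group summaries and
  are cross-checked against `stats::t.test` in the test suite.
* Even-count medians are the mean of the two middle values
  (`stats::median`).
* Ranking ties break lexicographically by pattern id; tabulation and
  derivation are invariant to input order.
* The consistency count uses `ceiling(fraction * n - 1e-9)` so that exact
  products (2/3 of 3 references = 2) are not tipped by floating-point
  representation.
* Signature weights serialise to JSON with 17 significant digits, making
  write-then-read the identity for IEEE doubles.
* Degenerate inputs fail loudly with typed conditions
  (`moamatch_degenerate_input`, `moamatch_calibration_degenerate`,
  `moamatch_leakage_error`, ...) rather than returning boundary values.

## Problem sizes used in the tests

The packaged checks run at deliberately modest sizes: the null calibration
of the Welch test uses 4 replicate null studies (10,800
stratum-by-analyte tests); threshold calibration uses a 40-treatment null
database (780 pairwise correlations per sex); pattern recovery uses a
full-size 225-analyte panel with a 20-analyte planted support, 3
derivation references, 1 held-out carrier and 10 negatives. Unit tests use
smaller panels (4–100 analytes) built by the same generator.

## Known limitations

* The expert-judgement surrogates (consistency fraction, confirmation
  rule) are declared approximations; their defaults are tuned to the
  synthetic conditions and should be re-examined against any real
  reference database.
* Each study day is an independent stratum; there is no longitudinal
  modelling across days.
* Threshold calibration assumes the database treatments are exchangeable
  nulls; shared modes of action among them shift the percentile upward.
* The pipeline starts at the quantified analyte table; raw
  mass-spectrometry processing is out of scope.
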