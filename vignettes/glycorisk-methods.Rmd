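---
title: "glycorisk: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycorisk: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycorisk)
```

# The analytical problem

`glycorisk` treats the serum N-glycome as *compositional* data: 46
chromatographic peak areas closed to 100%, so only relative information
is meaningful. Everything downstream respects that constraint — group
comparisons are rank-based on the closed parts (as in the source
analyses), and multivariate prediction is done through log-contrast
balances, which are invariant to the closure constant by construction.

The binary outcome throughout is *risk drinking*, defined per sex as
consumption above 40/20 g/day (men/women) **or** an AUDIT score above
7/5. Both inequalities are strict; `classify_risk()` is the single
implementation used everywhere, including inside the cohort generator.

# Chromatogram reduction

A dextran ladder (2-AB-labelled glucose oligomers) maps retention time
(minutes) to glucose units via a least-squares fifth-order polynomial.
Numerical choices:

* **Monotonicity is enforced, not assumed.** A degree-5 fit to plausible
  ladders can oscillate; the fit is rejected with a diagnostic if its
  derivative is non-positive anywhere on the ladder's retention range
  (checked on a 2048-point grid). A non-monotone calibration cannot
  assign peak identities, so failing fast is the only safe behaviour.
* **Half-open windows.** Peak GU values are binned into 46 contiguous
  windows `[lo, hi)`; a GU exactly on a boundary belongs to the *upper*
  window. This is an arbitrary but deterministic tie rule.
* **Unassigned area is reported, never silently dropped.** Peaks outside
  the calibration range or all windows accumulate in an `unassigned`
  attribute with a warning.
* **The default window table is a placeholder.** The published 46-peak
  scheme does not print its GU boundaries (they live in the cited
  integration protocol), so `default_gu_windows()` ships 46 equal-width
  windows spanning GU 4.4–12.0 and the table is fully configurable. All
  package tests use synthetic windows; no claim is made that the default
  matches any laboratory's integration. Real analyses must supply their
  own table.

Peak *detection* is out of the critical path: the canonical input is an
integrated peak list. `integrate_trace()` (local maxima,
valley-to-valley trapezoid areas) exists only to build fixtures.

# Derived traits

The 17 traits (S0–S4, G0–G4, A1–A4, OM, CF, OF) are fixed linear
aggregates of the peaks, stored as a coefficient table
(`trait_matrix()`), not as code: `derive_traits()` does nothing but
multiply by it. The test suite re-parses the printed formula strings
term by term as an independent oracle, so the table and the oracle share
no logic. Mixed peaks contribute fractionally: GP6, GP12, GP21, GP44
split 1/2; GP41, GP46 split 1/3. Three identities hold to 1e-9 on the
percent scale for any valid input (pure arithmetic, hence the tight
tolerance): the S-classes, the G-classes plus OM, and the A-classes plus
OM each sum to 100. CF and OF overlap structurally and partition
nothing; the package deliberately asserts nothing about their sum. A4
and G4 aggregate the same peak set and are therefore numerically
identical by construction.

# Univariate toolkit

* `rank_sum()`: exact two-sided p by enumeration of all group
  assignments when combined n ≤ 20 (valid under ties; C(20,10) ≈ 1.8e5
  assignments is cheap), otherwise normal approximation with tie
  correction and 0.5 continuity correction. The switch at 20 keeps the
  exact branch enumerable while matching common practice.
* `proportion_test()`: Pearson chi-squared, 1 df, no continuity
  correction by default (the source analyses do not state one); Yates
  behind a flag.
* `jonckheere_terpstra()`: J = Σ concordant cross-pairs + ½ ties, normal
  approximation with the standard no-tie variance. When tied cross-pairs
  exceed 10% of all cross-pairs the no-tie variance is anticonservative,
  so a seeded Monte-Carlo permutation null (default 10⁴ draws) is used
  instead; the permutation p includes the +1 correction and so never
  returns 0. The tie-corrected closed-form variance is deliberately not
  implemented — the permutation route is simpler and its calibration is
  directly testable by simulation.
* `holm_adjust()`: step-down sequential Bonferroni. One subtlety found
  during development: the full step-down map is *not* idempotent on
  typical adjusted vectors (holm(0.01, 0.04, 0.03) = (0.03, 0.06, 0.06),
  and adjusting again gives (0.09, 0.12, 0.12)); only degenerate 0/1
  vectors are fixed points. What is idempotent is the running-maximum
  monotonicity step. The tests assert the properties that are actually
  true: dominance over the raw p-values, the Bonferroni upper bound,
  step-down monotonicity, and agreement with `p.adjust(·, "holm")`.

"Sequential Bonferroni" is read as Holm throughout; Hochberg/Hommel
variants are not offered.

# Balance selection

For disjoint part sets N (p parts) and D (q parts), the balance score is
`sqrt(pq/(p+q)) * (mean(ln x_N) - mean(ln x_D))`. The forward search:

1. exhaustive search over all ordered pairs (the best 2-part balance);
2. each later step tries every unused part on each side, keeping the
   best;
3. model size 2..`max_size` chosen by repeated stratified k-fold
   cross-validation, re-running the forward path within every training
   fold; highest mean test criterion wins, ties to the smaller size;
4. final balance = full-data forward path truncated at the chosen size.

Design choices made where the design was genuinely open:

* **Criterion = AUC** of the logistic model
  `outcome ~ balance + covariates` (the reference algorithm's default
  for dichotomous outcomes; the source analyses name no criterion).
  Covariates (age in years, smoker 0/1) enter additively, untransformed.
* **Defaults** `cv_folds = 5`, `cv_repeats = 10`, `max_size = 12`: small
  enough that the exhaustive first step over 46·45 ordered pairs stays
  desk-scale; whether the original study used the cross-validated
  variant, and with what folds, is unstated, so these are package
  defaults flagged in the configuration, not reproductions.
* **Determinism**: every tie (candidate criteria within 1e-12) breaks to
  the lexicographically smallest part label, numerator side first; folds
  are drawn under the caller's seed and re-drawn stratified by outcome,
  so single-class training folds cannot occur.
* **The one-standard-error size rule** exists behind `one_se_rule` but
  is off by default.
* **Training-trace monotonicity is not guaranteed and not claimed.**
  Balances of different sizes are *not* nested GLMs (the log-contrast
  coefficients are constrained to the balance form), so the in-sample
  AUC can decrease when a part is added; this is observable on planted
  two-part signals, where every extension beyond the true pair dilutes
  it. The guarantee that does hold, and is tested, is that step 1
  attains the exhaustive-pair maximum.
* **Zeros**: log-contrasts need positive parts. `zero_replace()` offers
  a pseudocount rule (add half the smallest positive value to zero
  cells, re-close) and a multiplicative rule (exactly preserves ratios
  among positive cells); pseudocount is the default. The generator
  itself never emits zeros (log-normal draws), so this only matters for
  ingested data.
* **Perfect separation** is tolerated everywhere (AUC is computed from
  the fitted ordering, which separation does not break) and flagged
  rather than raised.

# Diagnostic evaluation

Threshold rules use the clinical reference limits with strict
inequalities: GGT > 73 IU/L (men) / > 38 IU/L (women), MCV > 100 fL,
CDT > 1.6%. From a 2×2 table, LR+ = sens/(1−spec) with the log-method
95% CI, `SE = sqrt(1/TP − 1/(TP+FN) + 1/FP − 1/(FP+TN))`, z = 1.96.
This formula reproduces all four published GGT/CDT confidence intervals
to printed precision, which is why it was adopted as the contract.
Degenerate tables (FP = 0 or TP = 0) return flagged infinite/zero LRs
instead of erroring.

"ROC adjusted for age and smoking" is implemented as the standard
logistic-score reading: fit `outcome ~ predictor + age + smoker`, take
the fitted probabilities as the score, compute the empirical ROC/AUC on
those. AUC uses the rank statistic (ties ½) — provably equal to
U/(n₁n₀) from the package's own rank-sum test, which the suite exploits
as a cross-module oracle. The AUC CI is DeLong's variance estimator
(deterministic; whether the original figures used DeLong or bootstrap is
unstated, and DeLong avoids a second seed).

Two published inconsistencies are documented rather than reproduced: the
men-GGT specificity prints as 81.8% where its own counts give 91.0%
(and 91.0% is the value consistent with the printed LR+ of 2.03), and
the women-CDT LR+ prints as 16.0 where the counts give 15.76 (its
printed CI endpoints match the counts). The package always computes from
counts. MCV metrics depend on an unpublished split of 11+5 missing
subjects across strata; the fixture uses the only split consistent with
the printed 7.1% male sensitivity (2 of 11 missing men in the risk
stratum, 0 of 5 women) and records it as an attribute.

# The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* the analysis
assumes, parameterized entirely by the published stratum summaries:

* per sex × risk stratum, each subject's 46-part vector is
  `exp(ln(median) + ε)` closed to 100, with per-peak log-scale standard
  deviation `(ln q3 − ln q1)/1.349` from the published IQRs — a
  logistic-normal-style model chosen because the analysis treats peaks
  as compositional;
* ε is either independent or one-factor correlated (default loading
  0.3), so balances face realistic positive correlation; the independent
  model is retained for oracle tests. The true joint distribution of
  peaks is unknown — the one-factor choice is an artifact decision, not
  a claim about the cohort;
* ages are IQR-matched normal draws truncated to 18–91; smoking is
  Bernoulli at the published prevalence; alcohol (g/week) and a
  discretized shifted-Poisson AUDIT score are resampled until consistent
  with the stratum's risk label under `classify_risk()`;
* markers are log-normal with the published median and IQR-implied
  dispersion, so marker positivity arises from distribution tails
  against the clinical cut-offs rather than being planted; the published
  positivity rates are served exactly by `table2_fixtures()` instead.

Closure slightly perturbs the marginal medians (the reference rows
already sum to ≈100, so the perturbation is small); the generator tests
therefore use ±1.5 absolute % for large peaks and sign-recovery rather
than exact medians for small ones.

**What a green test establishes, and what it does not.** The generator
reproduces stratum medians, IQR-scale dispersion, covariate prevalences
and compositional closure. It does not emulate chromatographic noise,
batch effects, the real peak-peak correlation structure, zero inflation,
or any nonlinear covariate-glycome relationship. Green pipeline tests
show the *machinery* recovers what was planted under the stated model —
they are not evidence about the real cohort, whose individual-level data
are unavailable. For the same reason the real-data results (the
published balance peak sets and adjusted AUCs of 0.65–0.77) are treated
as qualitative context, not acceptance targets.

# Reference-table repairs

Two typographical defects in the published peak table required a
decision: the men non-risk GP20 upper quartile prints below its median
(0.61 < 0.65) and was set to 0.71, consistent with the 0.70–0.72 printed
for every other stratum of that peak; and the men risk GP37 IQR prints
with a stray parenthesis, read as 1.41–2.08. Both are flagged in
`R/reference-tables.R`.

# Known limitations

* The GU window defaults are placeholders (boundaries unpublished).
* No peak alignment, baseline correction or MS-level structure
  assignment: the pipeline starts from integrated peak lists.
* No paired DeLong test for AUC differences; comparisons report
  intervals, not a difference statistic.
* The exact JT null distribution is not implemented (permutation
  fallback instead).
* Continuous outcomes are not supported in balance selection.
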