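---
title: "The FASD Eye Code: scoring model, diagnostic evaluation and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FASD Eye Code: scoring model, diagnostic evaluation and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyecode)
```

## The scoring model

Children with fetal alcohol spectrum disorders (FASD) show a characteristic
cluster of ophthalmological abnormalities — subnormal visual acuity,
refractive errors, strabismus and defective binocularity, and structural
anomalies of the lids, optic disc and retinal vessels.  The FASD Eye Code
condenses a standard paediatric eye examination into four ordinal
categories, each ranked independently on a 4-point scale where 1 is a
normal finding and 4 a strong expression of an abnormality common in FASD:

* **A — best corrected visual acuity** (decimal notation, linear chart at
  3 m), aggregated over eyes (worse eye by default, amblyopia-sensitive);
* **B — refraction** under cycloplegia, summarised per eye by the
  spherical equivalent SE = sphere + cylinder/2 (minus-cylinder form;
  plus-cylinder input is transposed automatically, which leaves SE
  unchanged).  Four sub-features feed the category — myopia, hypermetropia,
  astigmatism (|cylinder|) and anisometropia (|SE difference between
  eyes|) — and the category score is the worst triggered band;
* **C — strabismus and binocular function**: the cover-test class
  (none / heterophoria / intermittent tropia / manifest tropia) and
  random-dot stereoacuity (TNO, or Lang I when TNO is not feasible), again
  combined by maximum;
* **D — ocular structural abnormalities**: clinician-coded flags (ptosis,
  epicanthal folds, optic disc, retinal vessel and other fundus
  abnormalities), graded by count.

The total score is the sum, 4 ("1111", normal) to 16 ("4444", the most
severe expression), and a total at or above a cut-off (10 by default, 9 as
a sensitivity-oriented alternative) is flagged positive.  The flag is a
complement to — never a substitute for — a clinical FASD work-up, and
palpebral fissure length is deliberately excluded because every FASD
diagnostic scheme already uses it.

### Band conventions and boundary handling

Bands are encoded as ordered break vectors in a JSON rubric, so every
threshold is data, not code.  Boundaries are inclusive in the direction the
clinical cut-off names: a visual acuity exactly at a band floor takes the
better score ("acuity ≥ 0.8 is normal"), while a worsening feature exactly
at its cut-off counts as abnormal ("myopia ≥ 1 D SE").  This makes every
band total, mutually exclusive and deterministic, and makes the category
scores monotone: worsening any derived feature can never lower a score —
a property the test suite checks on 10^4 random feature records.  Note the
monotonicity statement is about *derived* features; worsening one raw eye
can reduce anisometropia and hence, legitimately, category B.

The exact published band protocol lives in a supplementary examination
protocol that is not reproduced here; the shipped rubric
(`rubric_child_4_15_synthetic.json`) is a synthetic reconstruction from
paediatric population norms — hence the `_synthetic` label — with the two
anchors that are documented: the childhood myopia cut-off of 1.0 D SE and
the young-adult alternative of 2.0 D SE
(`default_rubric("young_adult")`), reflecting the age dependence of
refraction; the presets target ages 4–15 and young adults respectively.
Users validating the code against their own protocol should supply their
own rubric JSON; `run_cli(c("rubric-validate", ...))` checks it.

Missing measurements propagate: a category with a missing required feature
is unscorable, and an exam with any unscorable category gets no total
(policy `"refuse"`; `"drop"` gives complete-case cohort analyses).  The one
exception is category C when the present sub-feature already attains 4,
since no value of the missing one could change the maximum.

## Diagnostic evaluation

`confusion_at_cutoff()` cross-tabulates case and non-case totals at a
cut-off and derives sensitivity, specificity, accuracy and likelihood
ratios from the exact fractions.  Reported percentages are rounded half
away from zero to whole percent and likelihood ratios to one decimal,
mirroring clinical reporting; the exact values are always retained, and an
LR+ with specificity 1 is "undefined", never infinity.  Pooled comparison
groups are concatenated score lists with no reweighting, which is exactly
the arithmetic used when several comparison groups are merged.

The empirical ROC (`roc_curve()`) sweeps `total >= t` over t = 4..17 for
integer totals (at most 14 distinct points), and its trapezoidal area is
algebraically identical to the Mann–Whitney statistic with ties given half
credit (`auc_mann_whitney()`); the suite verifies the identity to 1e-12 on
a thousand random instances.  Confidence intervals (`auc_ci()`) use
DeLong's nonparametric variance by default — the convention of the pROC
toolchain — with a stratified percentile bootstrap (2,000 replicates,
seedable) as an option and as the automatic fallback when the DeLong
variance degenerates under complete separation.  Published AUC values
cannot be recomputed from printed group summaries (they need the full
individual score distributions), so the package validates this machinery
by property instead: oracle equivalence of the two AUC routes, agreement
of DeLong and bootstrap endpoints within 0.03 on simulated data, and
empirical 95% coverage between 0.92 and 0.98 over 1,000 simulated
replicates at true AUC 0.8 (n = 40/60, binormal scores).

## Control matching

`match_controls()` implements population matching by minimising the
maximal t-value: controls are selected from a reference pool one at a
time, each step adding the candidate whose inclusion minimises the largest
absolute two-sample t-statistic across the matching variables (age and
sex; sex enters as a 0/1 coding, i.e. a proportion comparison).  The
t-statistic uses pooled variance by default (Welch by flag) with a
variance floor of 1e-12 so degenerate variables reduce to a standardized
mean difference.  Ties break by input order and selection is without
replacement, one candidate per iteration, making the procedure fully
deterministic; the tests verify each greedy step against exhaustive
evaluation of all candidates on pools of up to 30.

## Longitudinal comparison

`wilcoxon_signed_rank()` compares paired childhood and young-adult totals.
Zero differences are dropped, tied absolute differences get midranks, and
for up to 12 effective pairs the two-sided p-value is exact, from the full
2^n sign-enumeration distribution of the observed ranks (valid under
ties); larger samples use the normal approximation with tie and continuity
corrections, which matches the exact value within 0.02 on tie-free
instances at the crossover size.  `stability_report()` gives the
per-individual deltas and the share of individuals changing by at most one
point.  When scoring the adult wave, the young-adult rubric preset can be
used; in the original cohort the two myopia cut-offs did not change the
median total, because affected individuals tend to score through
astigmatism or anisometropia anyway.

## Synthetic cohorts and calibration

No individual-level data are published, so `cohort_spec()` defines a
generative stand-in: one probability table over scores 1–4 per category
plus a one-factor latent-threshold coupling (z_k = √ρ·W + √(1−ρ)·e_k
thresholded at the table quantiles), which preserves the marginals exactly
and reduces to independence at ρ = 0.  `simulate_exams()` inverts the
rubric — drawing raw measurements uniformly inside a band combination that
reproduces each drawn score vector exactly — so the whole pipeline from
CSV to indices can be exercised end to end; the suite demands 100%
round-trip agreement on 1,000 random targets.

`calibrate_to_summaries()` searches for tables matching published
group-level summaries: category medians, total median/quartiles, the
printed total range, and exceedance proportions at cut-offs.  Choices worth
recording:

* **What "range" pins down.**  The support of the implied totals is capped
  structurally so its maximum equals the printed range maximum (e.g. the
  control support is contained in 4–9, which is why no simulated control
  cohort can ever produce a total ≥ 10, at any seed).  A finite sample may
  occasionally fail to reach the support maximum; only support inclusion
  carries inferential weight here.
* **Quantile conventions.**  Sample medians/quartiles of integer scores
  are taken as Tukey's hinges (`fivenum()`); because the software
  convention behind the published tables is unknowable, calibration
  targets the population CDF with a ±0.03 margin around the required
  probability so that large simulated cohorts reproduce integer quantile
  targets exactly.  Half-integer medians pin the CDF to 0.5 ± 0.01 at the
  floor value instead, so a sample median lands on either side of the
  half-integer — they are reproduced approximately, not exactly.
* **Dependence is estimated, not assumed.**  The printed summaries of some
  validation groups are mutually inconsistent with independent categories:
  with all four category medians at 1, the ADHD group's 6/33 exceedance at
  ≥ 10 is unreachable at ρ = 0 (the optimum over marginals stays near
  0.11), so the hill-climb searches ρ ∈ [0, 0.95) alongside the tables.
  That correlated categories are *required* to reconcile the summaries is
  itself a finding: the four categories co-vary in affected children.  The
  control spec pins ρ = 0, where the support cap alone satisfies every
  constraint, and a degenerate-table spec at ρ = 0 factorises joint cell
  frequencies to within binomial tolerance (tested).
* **Search.**  A seeded stochastic hill-climb (multiplicative jitter and
  mass-transfer proposals on the in-support cells, floor 0.002, up to
  20,000 iterations × 4 restarts) minimises the summed constraint
  violations computed from the *exact* total distribution — a 4-fold
  convolution at ρ = 0, or an 81-node Gaussian-grid integration over the
  latent factor otherwise — and declares infeasibility naming the worst
  violated constraint if it cannot reach zero.  Every group converges in
  well under a second.
* **Non-uniqueness.**  Summary statistics never determine a distribution;
  the shipped specs under `inst/extdata/cohorts/` are one documented,
  versioned solution (calibration seed 20260101), not a reconstruction of
  the study data.

What the simulator deliberately does not emulate: real per-category IQRs
other than where constrained, demographic structure beyond the age/sex
fields that matching needs, and any within-category correlation structure
richer than the single latent factor.  Passing tests therefore certify the
*machinery* — scoring, indices, ROC algebra, matching, the paired test —
on cohorts whose totals behave like the published ones, not the clinical
performance of the Eye Code on new patients.

## Problem sizes and numerics

The test suite simulates 10^5-score cohorts for calibration recovery and
law-of-large-number checks (binomial tolerance ±0.01), 10^4 feature
records for monotonicity, 10^3 ROC instances and 10^3 coverage
replicates at n = 40/60 — sizes chosen so the whole suite runs in well
under a minute on one core while keeping Monte Carlo noise an order of
magnitude below every asserted tolerance.  All randomness flows through
explicit seeds (`withr::with_seed`, so library calls never disturb the
caller's RNG), bootstrap intervals are percentile-based with 2,000
replicates by default, and band sampling keeps a 0.1% guard margin away
from boundaries so floating-point rounding can never flip a simulated
measurement across a band edge.

## Known limitations

The shipped rubric is a reconstruction, not the published protocol; scores
produced with it are internally consistent but not certified against the
original instrument.  The exceedance-calibrated specs reproduce printed
counts and medians, not the unpublished full distributions, so AUCs
computed on simulated cohorts approximate but do not reproduce the
published AUCs.  The matcher implements the minimal-maximal-t heuristic
only — no propensity or optimal-pair matching — and whether the original
method also balances dispersion is not stated in the source this package
models, so only means (and the sex proportion) are matched.
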