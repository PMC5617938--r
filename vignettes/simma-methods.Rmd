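---
title: "Salivary biomarker screening and caries risk assessment with simma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salivary biomarker screening and caries risk assessment with simma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simma)
```

## The problem

Dental caries is driven by the interplay of immune competence, the adhesion
of cariogenic micro-organisms to the tooth surface, and the acid
production/buffering balance of saliva. A practical risk test therefore
measures a small panel of salivary compounds drawn from all three
categories, at a standardized time of day, and reports both *which*
category is out of balance (pointing to a preventive treatment) and an
*overall* risk of being caries-active.

`simma` implements that full analysis chain for longitudinal salivary
marker panels — cohorts of caries-active (CA) and caries-free (CF)
subjects sampled at several times after toothbrushing:

1. **Univariate screening** (`screen_markers()`): an exact
   Wilcoxon–Mann–Whitney rank-sum test per marker, plus per-group quantile
   intervals and a non-overlap criterion.
2. **Per-category selection** (`select_biomarkers()`): the best two
   markers from each of the immune, adhesion and pH categories.
3. **Classification power** (`classification_power()`): sensitivity +
   specificity of a single-hidden-layer neural network, estimated by
   repeated stratified train/test splits.
4. **Random-subset null** (`random_combination_null()`): the distribution
   of that power over random marker subsets, the backdrop against which a
   selected panel is judged.
5. **Patient risk report** (`simma_report()`): per-marker flags against
   caries-free reference intervals (local risk), per-category imbalance
   counts, and a multivariate caries-active probability (global risk).

A synthetic-data generator (`simulate_panel()`) reproduces the temporal
and group structure such studies exhibit, so the entire chain is testable
without access to any cohort.

## The univariate screen

For each marker at a chosen timepoint, `rank_sum_p()` computes the
two-sided Wilcoxon–Mann–Whitney p-value comparing CA against CF
concentrations. The test is distribution-free, which matters because
immunoassay concentrations are right-skewed and on incomparable scales
across markers. The exact null distribution is used whenever the smaller
group has at most 25 observations and the pooled values are tie-free;
otherwise mid-ranks with the tie-corrected normal approximation and a
continuity correction. At the canonical cohort size of 10 + 10 this means
all screening p-values are exact: complete separation gives
$p = 2/\binom{20}{10} = 2/184756 \approx 1.08\times10^{-5}$, and the
smallest non-trivial tail values (such as $14/184756 \approx
7.58\times10^{-5}$) are reproduced exactly rather than approximated.

Alongside the p-value, each group gets a quantile interval
(`quantile_interval()`, linear interpolation of order statistics — R's
default quantile rule). The screening default is the interquartile box
(0.25/0.75); a marker only qualifies for unforced selection when the CA
and CF boxes do not overlap. Overlap is a *closed*-interval test: boxes
that merely touch are conservatively counted as overlapping.

Selection (`select_biomarkers()`) ranks each category's markers by
ascending p-value, breaking ties by the larger signed gap between the two
group boxes, and takes the top `per_category` (default 2) among markers
with $p \le \alpha$ (default 0.05) and non-overlapping boxes. When a
category has too few qualifying markers — acid/buffering markers in
morning samples are the typical case, because fermentation metabolites
accumulate only after meals — the remaining slots are filled by ascending
p-value anyway and flagged `forced`, so the panel always covers all three
biological categories. No multiple-testing correction is applied across
the 25 markers; the screen is a ranking device feeding a multivariate
validation stage, not a family of confirmatory tests. This is a
documented limitation: individual screening p-values near $\alpha$ should
not be read as confirmatory evidence.

`time_contrast()` applies the same test within one group between two
timepoints. It is how a marker is called circadian (morning vs afternoon
differ, but the two morning samples taken 24 h apart do not) or
plaque-maturity-driven (monotone in hours since brushing). The default is
the unpaired rank-sum test; since subjects are repeatedly measured, a
paired signed-rank mode (`paired = TRUE`) is also provided.

## The classification-power statistic

The multivariate stage asks: do the six selected markers, taken together,
actually separate the groups? The statistic is

$$\text{power} = \text{sensitivity} + \text{specificity} \in [0, 2],$$

with sensitivity the proportion of caries-active test subjects classified
correctly and specificity the same for caries-free. A chance-level
classifier has expected power 1; a perfect one reaches 2.

Both proportions are estimated by Monte-Carlo cross-validation: a
"50-fold" resampling of a 20-subject cohort cannot be a 50-way partition,
so `cv_config()` defaults to 50 independent *stratified random
train/test splits* holding out one third of each class, and the per-split
rates are averaged. Within each split, features are z-scored using
training-split statistics only and missing values are mean-imputed from
the training split — test subjects never influence the scaling, which
would otherwise leak information at these sample sizes.

The classifier is a single-hidden-layer neural network (`nnet`, logistic
activations) with 2 hidden units, weight decay 0.01 and at most 500
iterations — deliberately small, since training sets hold about 14
subjects; the decay term is what keeps the fit stable on nearly separable
data. Weight initialization is seeded, so every estimate is reproducible.
The classifier sits behind a fit/predict contract
(`fit_classifier()`/`predict()`): `type = "ridge"` swaps in a closed-form
ridge least-squares discriminant that is exactly deterministic and
exactly antisymmetric under label swap, which the test suite uses for the
sharper invariance checks. Predicted probabilities are thresholded at
0.5; an exact tie is called caries-free, the risk-averse convention.

`random_combination_null()` places a marker set in context: it draws
`n_combinations` (default 1000) uniform random 6-subsets of the roster —
unconstrained by category, and possibly repeating across draws — and
records each subset's power. The selected panel's power is then reported
with its percentile in that empirical distribution. On an effect-free
cohort the null's median converges to 1, which the acceptance suite
verifies at 200 combinations.

## The patient risk report

The clinical output has two complementary arms:

- **Local risk** (`local_risk()`): each selected marker is compared to a
  reference interval built *only from caries-free subjects*
  (`build_reference_intervals()`). A value strictly outside the closed
  interval is `out_of_range`; boundary values are in-range, matching the
  screening convention. Flags aggregate into per-category imbalance
  counts — an immune-only imbalance suggests a different preventive
  strategy than a buffering deficit — and their total is the urgency
  count.
- **Global risk** (`global_risk()`): the trained multivariate model's
  probability that the sample is caries-active, using the cohort's
  scaling statistics and training-mean imputation for missing markers.

Reference intervals default to the 0.05/0.95 quantile pair, deliberately
wider than the screening boxes: an interquartile flag would mark half of
all healthy subjects out-of-range on every marker. With 0.05/0.95, a
healthy subject is flagged on a given marker about 10% of the time
asymptotically. On small reference cohorts the empirical quantile
interval is systematically slightly narrow — with 50 reference subjects
the realized flag rate is nearer 13% — an $O(1/n)$ property of quantile
estimation worth remembering when references are built from 10-subject
pilot cohorts.

`simma_report()` combines the arms into one record and calls the subject
`elevated` when the global risk exceeds 0.5 *or* at least two markers are
out of range. That decision rule is a reporting convention of this
package (threshold configurable via `urgency_threshold`), not an
estimated quantity: the underlying scientific claim is only that the
out-of-range count is a usable urgency measure.

## The synthetic-data generator

`simulate_panel()` draws log-normal concentrations: for subject $i$ in
group $g$, marker $m$, $t$ hours after toothbrushing,

$$\log C = \mu_m + \beta_m\,[g=\mathrm{CA}] + u_i +
a_{m,g}\cos\!\Big(2\pi\,\frac{\mathrm{clock}(t) - \mathrm{peak}}{24}\Big)
+ s_m t + \varepsilon,$$

with $\varepsilon \sim N(0, \sigma_m^2)$ and a per-subject intercept
$u_i \sim N(0, \sigma_{\mathrm{subject}}^2)$.

- The **circadian term** runs on clock time
  $\mathrm{clock}(t) = (9 + t) \bmod 24$ for a 9 a.m. brushing, not on
  hours since brushing, so samples at 0.5 h and 24 h (same clock hour,
  next day) agree — the structural signature that distinguishes a
  clock-driven marker from a plaque-maturity trend. Group-specific
  amplitudes let a marker be U-shaped in caries-free subjects but flat in
  caries-active ones, the pattern that makes a circadian marker
  discriminative only in afternoon samples.
- The **trend term** $s_m t$ models biofilm regrowth: markers that
  accumulate with plaque maturity have $s_m > 0$, markers washed out
  after brushing $s_m < 0$.
- The **group shift** $\beta_m$ plants discriminative markers.

`default_study_config()` encodes the canonical study conditions: 10 CA +
10 CF subjects, the 25-marker roster (12 immune, 7 adhesion, 6 pH),
timepoints 0.5/6/12/24 h. Defaults chosen once and fixed: $\sigma_m =
0.5$ log-units, so the default planted shift of 2 log-units (4 residual
SDs) produces the near-complete group separation that the best real
markers show at $n = 10 + 10$; $\sigma_{\mathrm{subject}} = 0.3$ to
induce realistic within-subject correlation across timepoints; circadian
amplitude 0.4 for IgA and the two discriminative defensin-family markers
(caries-free group only for IgA and beta-defensin 2, both groups for
beta-defensin 3); trend slopes $\pm 0.03$/h for IgG (declining) and
calprotectin (rising). The planted set defaults to the canonical
afternoon panel: beta-defensin 2, LL-37, collagen I, fibronectin,
formate, phosphate — two per category.

What the generator does **not** emulate: salivary-flow effects (daily
concentration changes in real saliva are partly flow-driven, and no flow
normalization is modeled), assay floor/ceiling censoring, a
sugar-rinse-specific shift (the `condition` label is carried through the
data model and screening, but only baseline data are simulated), and any
dependence structure between markers beyond the shared subject intercept.
Passing tests on synthetic panels therefore demonstrate the statistical
machinery — calibration, recovery, coverage, determinism — not the
biological validity of any particular marker on real cohorts.

## Numerical choices and degenerate inputs

- Exact rank-sum distribution up to min(n, m) = 25 without ties; beyond
  that, or with ties, the tie-corrected continuity-corrected normal
  approximation. Identical samples give $p = 1$.
- Quantiles: type 7 (linear interpolation), so `quantile_interval(1:4,
  0.25, 0.75)` is [1.75, 3.25]; constant vectors give zero-width
  intervals.
- Ties in selection: broken by the larger inter-box gap; re-running
  selection on the same screen results is deterministic.
- Markers with no usable data in one group are reported with
  `insufficient = TRUE`, never silently dropped; references without
  caries-free data are marked unavailable, never fabricated.
- Z-scoring uses training-split statistics; a zero-variance training
  column gets unit scale rather than dividing by zero.
- All randomness (simulation, splits, weight initialization, subset
  draws) is seed-controlled, and every seeded routine restores the
  caller's RNG state.

## Problem sizes in the test suite

The packaged checks run the whole pipeline at the canonical cohort size
(10 + 10 subjects, 25 markers): an exhaustive enumeration oracle for the
exact test over all group assignments up to $n + m = 12$; 100 simulated
studies for planted-marker recovery; a 200-combination random-subset null
on an effect-free panel; and a reference-interval coverage simulation
with 200 caries-free reference subjects (sized so the quantile
estimator's $O(1/n)$ bias is negligible against the binomial sampling
band). `scripts/acceptance.R` re-runs the same quantities end to end from
a single command-line seed.

## Known limitations

- No multiple-testing correction in the screen (by design, documented
  above).
- The selection fallback guarantees category coverage but can return
  markers with no univariate evidence; they are flagged `forced` so
  downstream users can see exactly which slots were filled that way.
- Power estimates on 20-subject cohorts have large Monte-Carlo and
  sampling variance; the random-subset null is the honest yardstick, not
  the absolute power value.
- Reference intervals from small healthy cohorts under-cover; age
  stratification and larger reference populations are out of scope.
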