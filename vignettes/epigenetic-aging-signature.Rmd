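---
title: "Methods: building and applying an epigenetic aging signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and applying an epigenetic aging signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclock)
```

## The model

A beta value is the fraction of methylated alleles at a CpG site across the
cells of a sample, bounded in [0, 1]. At a minority of CpGs this fraction
drifts with donor age in a strikingly linear way, in either direction:
hypermethylating sites rise, hypomethylating sites fall. `methclock` treats
age prediction as plain multivariate linear regression on those sites,

$$\widehat{\mathrm{age}}_j \;=\; b_0 + \sum_i w_i\,\beta_{ij},$$

fitted by ordinary least squares. That is a deliberate modelling choice:
no regularisation by default (a ridge penalty is available via
`fit_age_model(ridge_lambda = )` for designs where the marker count
approaches the sample count), no basis expansion, no clipping of
predictions. Negative predicted ages are retained because they are
informative — pluripotent cells score below zero, reflecting epigenetic
reversal past the newborn state.

The assumptions, explicitly:

* beta–age relationships are approximately linear over the cohort's age
  range at the selected sites;
* samples are exchangeable (one tissue, here blood; no batch or
  cell-composition adjustment is applied — see *Limitations*);
* measurement noise on betas is roughly additive and homoscedastic.

## The discovery pipeline

`end_to_end_signature()` chains four stages, each available on its own.

**1. AR-CpG screen.** Pearson correlation of each CpG's betas with age,
pairwise-complete over non-missing samples (`correlate_with_age()`), then
a hard cutoff `|r| > threshold` with `threshold = 0.85` by default
(`select_ar_cpgs()`). The inequality is strict, and the cutoff is on r,
not on a p-value: at the sample sizes where this method is used, an
absolute-correlation cutoff is the more interpretable stringency knob, and
no multiple-testing machinery is attached to it. CpGs with zero beta
variance or fewer than 3 usable samples have no defined correlation and
are excluded rather than silently scored 0.

**2. Variability pre-filter.** `filter_by_variability()` keeps the CpGs
whose interquartile range of betas lies strictly above the median IQR of
the screened set — for an even-sized set, exactly half. Sites that pass the
correlation screen but barely move in absolute terms contribute little
dynamic range to a downstream assay; the IQR filter removes them before
the (combinatorially expensive) subset search. Tie-break: if strict
filtering would keep fewer than 2 CpGs (all IQRs equal, a degenerate but
reachable case), the rule falls back to `>=` the median.

**3. Iterative split / RFE search.** `run_search()` repeatedly splits the
cohort into a training fraction (the *split ratio*) and a test remainder;
on each training side, recursive feature elimination (`rfe_select()`)
shrinks the candidate set to `k` CpGs (default 5), and both the k-CpG
subset model and the full-candidate baseline model are fitted on the
training side and scored by mean absolute deviation (MAD, years) on the
test side. Defaults: split ratios {0.2, 0.4, 0.6, 0.8} × 25 iterations
each. These are configurable; the spread of ratios probes how robustly a
subset generalises from both scarce and generous training data, and 100
total cells keeps desk-scale runs in seconds while giving the frequency
ranking a denominator large enough to be stable.

RFE details: at each elimination step the model is refitted and each CpG
is scored by |coefficient| × training standard deviation of its betas (a
standardized coefficient — raw coefficients would confound the beta scale),
and the lowest-scoring CpG is dropped. One CpG is dropped per step once 20
or fewer remain; above that the lowest 10% per step, a standard
exact-at-the-end schedule. Collinear (aliased) CpGs receive importance 0
and so are eliminated first, with a message.

**4. Baseline filter and frequency ranking.** `filter_and_rank()` retains
only subsets whose test MAD beats the baseline, then ranks CpGs by their
frequency of occurrence among the retained subsets; CpGs occurring in
strictly more than 50% of them form the signature. "Beats the baseline" is
ambiguous in prose, so both readings are implemented: the default
(`baseline = "global_mean"`) compares each subset against the mean
full-candidate-set test MAD over *all* cells; `"per_split"` requires each
subset to beat its own split's baseline. The default is the global mean
because it makes the filter a fixed bar rather than a paired comparison,
which keeps retained counts comparable across ratios.

One guard is forced by RFE's own precondition: RFE needs at least `k`
candidates, so `end_to_end_signature()` applies the variability filter
only while the filtered pool still holds ≥ `k` CpGs. A cohort whose screen
already yields exactly `k` AR-CpGs proceeds unfiltered (logged as such). A
cohort with no age signal returns an empty signature with an explanatory
log rather than an error.

## The three-CpG clock

The published pyrosequencing clock over the *ASPA* (α = cg02228185),
*ITGA2B* (β = cg25809905) and *PDE4C* (γ, one CpG upstream of cg17861230)
markers is stored exactly as printed:

$$\widehat{\mathrm{age}} = 38.0 - 26.4\,\alpha - 23.7\,\beta + 164.7\,\gamma
\quad\text{(years, fractions in } [0,1]).$$

No extra digits are re-derived: the printed equation is the public
contract of the assay, and `three_cpg_model()` reproduces it verbatim.
Fractions are validated to [0, 1]; pyrosequencing software reports
percent, so `read_pyro_table(unit = "percent")` divides by 100 at the
boundary. `fit_three_cpg_model()` refits the same family by OLS from a new
training table. Patient-group comparisons of age deviation
(`compare_deviation_groups()`) are reported as deviation distributions
with a two-sided Wilcoxon rank-sum test — a deliberately assumption-light
descriptive comparison.

## Error metrics

`compute_metrics()` reports MAD (mean |error|, years), RMSE, and R².
**R² is the squared Pearson correlation between predicted and
chronological age, not 1 − SSE/SST.** The two differ whenever predictions
carry a systematic offset, which is exactly what happens when a clock
trained on one array platform is applied to another; squared correlation
still credits the preserved ordering, the coefficient of determination
does not. The cross-platform workflow itself is handled by
`refit_on_marker_subset()`: rather than normalising probe chemistries, the
model is refitted from scratch on the markers the target platform actually
measures, with dropped markers recorded in the provenance.

`loocv()` computes leave-one-out predictions through the exact hat-matrix
identity $e_{(i)} = e_i/(1-h_{ii})$ — one QR decomposition instead of n
refits, algebraically identical to refitting (the package's tests verify
the identity against a brute-force refit oracle to 1e-9). Samples with
leverage 1 (not predictable from the rest) abort with a clear message.

## Comparators

* **Telomeres.** Granulocyte telomere length declines close to linearly
  with age (≈ 39 bp/yr), so a linear fit on healthy donors yields a
  comparison age predictor. The default regresses `length ~ age` (the
  biology-forward direction) and inverts the line for prediction; because
  the two least-squares directions differ on noisy data and the choice is
  genuinely open, `direction = "age_on_length"` fits the other way.
  Telomere-based prediction is included as a *reference point* — it is far
  less precise than the methylation clock, which is part of the scientific
  story.
* **Covariates.** `associate_deviation()` fits univariate OLS of deviation
  on one covariate at a time, with classical t-based p-values, optionally
  per sex. Ordered categories are coded to consecutive integers (0, 1, 2,
  ≥3 children → 0..3). No multiple-testing correction is applied across
  covariates: the analysis is exploratory and the raw per-covariate
  p-values are the honest output.
* **Entropy.** `methylation_entropy()` is the binary Shannon entropy in
  bits with the 0·log 0 := 0 convention — the quantitative form of the
  observation that age-related drift pushes CpGs toward 50% methylation,
  the entropy maximum.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the method assumes,
nothing more:

* ages uniform over the requested range (default ranges in examples use
  0–78 years, a realistic blood-cohort span), or stratified into 6-year
  bins with equal counts, mirroring how population cohorts are sampled by
  age category;
* planted AR-CpGs follow `clip(intercept + slope·age + noise, 0, 1)`; the
  spec of each trajectory must stay inside [0, 1] over the age range
  *before* noise, enforced at construction;
* background CpGs are a constant per-CpG level plus noise;
* noise is additive Gaussian, then clipped. Clipping makes boundary-near
  CpGs slightly biased and heteroscedastic — noted, accepted, and one
  reason planted intercepts in `default_planted_cpgs()` keep a margin from
  the boundaries;
* one global seed expands into an independent derived stream per
  operation (ages, background levels, noise, pyro, telomeres), so each
  stage is reproducible on its own and in any order.

`simulate_pyro()` inverts the published equation: α and β are drawn from
declining baseline curves (α: 0.90 − 0.002·age; β: 0.80 − 0.0015·age) with
independent per-sample biological scatter (sd 0.05), and γ is *solved*
from the equation so the noise-free triplet reproduces the sample's age
exactly. The scatter is what makes the three regressors linearly
independent, so coefficient recovery from noise-free simulations is exact;
the baseline curves are chosen so the solved γ stays in [0, 1] across
ordinary human ages (the β draw is clamped into the feasibility window,
and an error is raised only when the window is empty — ages beyond
38.0 + 164.7 = 202.7 years are unrepresentable by construction).
`simulate_telomeres()` plants `baseline − 0.039·age` kb with Gaussian
noise, floored at a small positive constant.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: array probe-type chemistry (type I/II bead
bias), batch effects between pooled studies, cell-composition shifts with
age, non-linear beta–age trajectories, and spatial correlation between
neighbouring CpGs. Tests on synthetic cohorts demonstrate algorithmic
correctness (the right quantity is computed, deterministically, at the
stated tolerances), not field performance on arbitrary cohorts.

## Numerical and format choices

* Betas are stored as fractions; percent is an input convenience
  (`percent = TRUE` divides by 100 before validation). The clock
  coefficients are only dimensionally sensible on the fraction scale.
* Missing betas are an explicit mask (`NA`), accepted on read as empty
  cells or `"NA"`. Nothing imputes silently; `impute = TRUE` requests
  per-CpG mean imputation and announces how many values it filled.
* Models serialize to versioned JSON with coefficients as 17-significant-
  digit decimal strings, which round-trips IEEE-754 doubles bit-exactly
  across platforms. Unknown versions and truncated files are rejected.
* Combined layouts that mix ages into a beta table are rejected by
  validation rather than guessed at; ages live in the sample table, and
  `align_samples()` (idempotent, order-preserving on the beta table's
  sample order) joins the two.
* Rank-deficient designs (duplicated or collinear CpG rows) abort the OLS
  fit with a named error rather than returning one of infinitely many
  solutions; inside RFE, aliased CpGs are instead eliminated first, since
  elimination is exactly the remedy there.
* Quantiles/IQRs use R's default type-7 definition throughout.
* Split-search cells derive their seeds as a pure function of (master
  seed, ratio index, iteration), so a parallel execution would reproduce
  the serial results cell-for-cell.

## Problem sizes

The package's own test and example workloads are desk-scale by design:
cohorts of 40–300 samples, 12–100 CpGs, 100 search cells. These sizes make
every property checkable in seconds while leaving the algorithms'
complexity (OLS via one QR per fit, hat-matrix LOOCV, exhaustive oracles
only at n ≤ 12 CpGs) comfortable for the thousands-of-CpGs, hundreds-of-
samples inputs the functions are written for.

## Limitations

* The correlation screen runs on pooled betas without study or batch
  adjustment; with strongly confounded multi-study input, screen results
  will reflect that confounding.
* OLS clocks extrapolate linearly outside the training age range; nothing
  warns about extrapolation.
* The published clock's applicability is specific to blood and to the
  exact assayed CpGs; the package evaluates the equation, it cannot
  validate an assay.
* The covariate analysis is univariate and exploratory; it does not model
  covariate interdependence.
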