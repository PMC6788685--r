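---
title: "A discovery-replication workflow for plasma proteomic biomarkers of Parkinson disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discovery-replication workflow for plasma proteomic biomarkers of Parkinson disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodiscover)
```

## The problem

Aptamer-based platforms quantify ~1,000 plasma proteins at once as
relative fluorescence units (RFUs). A biomarker study built on such a
panel must (i) clean the raw measurements, (ii) find proteins whose
levels differ between people with Parkinson disease (PD) and
neurologically normal controls (NC) while adjusting for demographics
and medication, (iii) rank the candidates in a way that is robust to
the strong collinearity between plasma proteins, (iv) show that the top
candidates re-appear, with the same direction, in an independent
multisite cohort, (v) rule out mundane explanations (dopaminergic
medication state, sample handling, generic neurodegeneration), and
(vi) ask whether baseline marker levels predict the subsequent rate of
cognitive decline. `proteodiscover` implements that chain as
composable, individually testable stages, and ships a synthetic-cohort
generator with known ground truth so every stage can be validated
without access to measured patient data.

## The measurement model and the synthetic cohorts

All analysis happens on the log10-RFU scale. The generator builds raw
values as

$$\log_{10} x_{ij} = b_j + \delta_j\,\mathrm{PD}_i + a\,(\mathrm{age}_i - \overline{\mathrm{age}})
 + s\,\mathrm{female}_i + u_{\mathrm{site}(i)} + v_{\mathrm{batch}(i)}
 + \sigma\left(\sqrt{\rho}\,F_{i,b(j)} + \sqrt{1-\rho}\,Z_{ij}\right)$$

with baseline abundances $b_j$ uniform on [2.5, 4.5] (raw RFU roughly
300–30,000, the usual plasma dynamic range), planted group effects
$\delta_j$ nonzero only for a designated subset (signs alternating so
both directions of change occur), multiplicative site/plate shifts that
are constants on the log scale, and a shared latent factor $F$ per
block of `block_size` proteins giving exact within-block correlation
$\rho$ — the collinearity that motivates Stability Selection.
A configurable fraction of proteins is anchored just below the lower
detection limit so the detection-limit filter has true positives;
defaults scale the reference panel's loads (125 of 1,129 near-limit
proteins, 36 of 1,129 noisy-triplicate proteins). Ages are
normal(70, 8) truncated to 45–95 and sexes Bernoulli(1/2) in both
groups, so the groups are demographically matched in expectation;
levodopa-equivalent daily dose (LEDD) is positive only for PD.

Auxiliary designs mirror the study structure: three QC reference pools
run in triplicate (replicate noise lognormal with
$\sigma_{\log} = \sqrt{\log(1 + \mathrm{CV}^2)}$, which makes the
target raw-scale CV exact); paired ON/OFF-medication samples sharing
subject-level baselines; longitudinal cognitive scores
$y_{it} = \alpha_i + (\beta_0 + \gamma x_i)\,t + e_{it}$ whose slopes
depend on the baseline level $x_i$ of a designated protein; and
exponential conversion times whose log hazard is shifted for the lowest
biomarker tertile.

What the generator does **not** emulate: aptamer binding chemistry,
plate-geometry artifacts beyond multiplicative shifts, non-Gaussian
heavy tails, missingness, or real biological covariance beyond the
block-factor structure. Passing tests therefore demonstrate that the
*estimators* behave as designed under the model the analysis assumes —
not that any particular protein is a real biomarker.

One global seed fans out to fixed per-stage child seeds (cohort, QC,
longitudinal, on/off, survival, jackknife masks, ...), so a stage
re-run in isolation reproduces its stream from the full pipeline and
identical configurations give bit-identical outputs.

## QC and normalization

`run_qc()` applies, in order: hybridization normalization (per-sample
factor = median over spiked-in controls of reference/observed; when no
external reference is supplied, the across-sample median of each
control is the reference), median normalization (per-sample factor =
median over proteins of the across-sample median divided by the
sample's value), a scale-factor gate (acceptance range 0.4–2.5,
boundaries **pass**; the range is stated without boundary semantics, so
the inclusive choice is pinned here), the triplicate-CV filter (CV =
n−1 standard deviation / mean on raw RFU; exclusion when **any** pool's
CV exceeds 0.2, strictly), the detection-limit filter (exclusion when
the out-of-limits fraction strictly exceeds 0.25; proteins without
annotated limits are retained with a warning, matching panels that ship
no limits), and the log10 transform. The CV and LOD filters act on
disjoint evidence, so the exclusion set is their union and
order-independent.

```{r}
cfg <- sim_config(n_pd = 24, n_nc = 24, n_proteins = 120, n_planted = 4,
                  delta = 0.3, seed = 11)
cohort <- generate_cohort(cfg)
qc <- run_qc(cohort$matrix, qc_runs = generate_qc_triplicates(cfg))
qc$report
```

## Discovery: covariate-adjusted per-protein models

Each retained protein's log10 level is regressed on the group indicator
(PD = 1), age (years), sex (female = 1), and LEDD (mg/day; 0 for
untreated controls — the model mixes treated PD and untreated NC, and
the zero convention makes the covariate well-defined for everyone).
Covariates are left unscaled so coefficients keep their units.
Candidates are proteins with a group-effect p-value strictly below
0.005, sorted by p with ties broken by protein id;
Benjamini–Hochberg q-values are computed across the full tested family.
Inference uses the t reference distribution — at n ≈ 141 this barely
differs from the normal, but it makes the estimator exactly equal to
the closed-form oracles used in the tests. One practical note: because
LEDD is near-collinear with the PD indicator (controls are untreated),
adjusting for it roughly doubles the group-effect standard error; this
is faithful to the design, and planted effects in the examples are
sized accordingly.

```{r}
assoc <- run_discovery(qc$matrix, cohort$meta)
assoc
nominate_candidates(assoc, p_threshold = 0.05)
```

Candidate structure is visualized by agglomerative clustering of the
per-protein centered and scaled values, euclidean distance, average
linkage, on both proteins and samples (`cluster_candidates()`), with
newick export for the dendrograms.

## Stability Selection

Candidates are ranked by how often LASSO selects them across jackknife
iterations that simultaneously drop 10% of samples and 30% of features
(`round(frac * n)` of each). Within each in-bag block the features are
standardized, the centered 0/1 group label is the response (a linear,
not logistic, selector — standard for selection on a class label), and
a 20-point log-spaced penalty grid runs from the per-subsample
$\lambda_{\max} = \max_j |x_j^\top y|$ down to
`lambda_min_ratio * lambda_max`. A feature is selected when its
coefficient is nonzero anywhere on the grid; its frequency is selected
iterations / in-bag iterations (features out of the bag cannot be
selected, so counting them would deflate frequencies without changing
expected ranks).

The grid floor matters. At the reference geometry (127 in-bag samples,
98 in-bag features) a floor of 0.1·λ~max~ lets ~70 of 98 features into
the model and frequencies saturate near 1, reducing the ranking to a
coefficient sort; the default floor of 0.5·λ~max~ keeps ~10 features
per iteration — the sparse regime in which selection frequencies are
discriminative. Even so, the single best-correlated feature of a fixed
pure-noise dataset is genuinely stable under a 10% sample jackknife and
can reach frequency ≈ 1; what distinguishes noise is the *bulk* of the
frequency distribution (median ≈ 0.02 under the null), not its maximum.
Rank ties are broken by mean absolute coefficient across selected
iterations, then protein id, making the top-10 deterministic. The inner
solver is compiled cyclic coordinate descent with warm starts
(cross-checked in the tests against closed-form soft-thresholding and
against an independent path solver), which keeps 10,000-iteration runs
in a few seconds; 10,000 iterations already give Monte-Carlo-stable
frequencies, and the iteration count is a config field for larger runs.

```{r}
rk <- stability_rank(qc$matrix, cohort$meta$group,
                     nominate_candidates(assoc, 0.05),
                     stability_config(iterations = 1000, seed = 11))
rk
top_k(rk, 5)
```

## Replication, specificity, robustness

`run_replication()` re-fits the discovery estimator for the top-ranked
proteins in the independent cohort with site and plate as additional
reference-coded covariates (LEDD deliberately omitted — the replication
design predates complete LEDD availability, and the analysis plan is
mirrored, not improved). BH correction is over the advanced family
only. A protein **replicates** when q < 0.05 in both cohorts with the
same coefficient sign. Disease specificity refits with a three-level
group factor (NC reference; PD and ALS contrasts extracted, one BH
family across both). The treated versus never-treated comparison is a
Wilcoxon rank-sum test, exact for combined n ≤ 20 without ties.

Medication-state robustness uses the paired designs: the classic paired
t test, and an exact sign-flip permutation test whose statistic is the
absolute mean ON−OFF difference (the natural paired statistic; the
choice is pinned here since several are defensible). All $2^n$ sign
assignments are enumerated for n ≤ 12 — 1,024 flips at the design's
n = 10 — making p-values exact multiples of $2^{-n}$; larger n uses
Monte-Carlo flips with the add-one convention so p-values stay valid.
Sample-handling sensitivity is the relative change of each protein
between a baseline and a perturbed reference-pool aliquot, computed on
**raw** RFU, flagged beyond ±30%.

## Progression models

Baseline association uses Spearman rank correlation with BH adjustment.
The longitudinal model is a linear mixed-effects fit (REML; the
likelihood flavor is unstated upstream, and REML is the conventional
default for variance components) of the cognitive score on age, sex,
disease duration, baseline score, time, and time×protein, with a
participant random intercept. Two pinned choices: the time main effect
accompanies the interaction (an interaction without its marginal term
is uninterpretable), and the baseline visit serves as the
baseline-score covariate and is **excluded from the response rows** —
keeping the same measurement on both sides of the model forces zero
residuals at t = 0 and corrupts the residual variance. The random
intercept is the only random effect (random slopes are a
straightforward extension but are not fitted by default); a singular
mixed fit falls back to the fixed-effects model with a warning. Under
the generator's reference conditions (90 participants, 4 annual visits,
residual SD 2 score units, between-person marker spread ≈ 0.15 log10
units) the interaction CI is wide; the simulation studies therefore
assess *calibration* (≈95% CI coverage) rather than precision.

Cognitive states for survival analysis come from MoCA norms (26–30
normal, 21–25 MCI, ≤20 dementia; DRS states are consensus diagnoses
supplied as data). Event derivation excludes participants with
dementia at baseline or a normal state following a baseline MCI, takes
the first normal→MCI, normal→dementia or MCI→dementia transition as the
event, and censors at the last visit otherwise. Tertiles are cut at
the 1/3 and 2/3 type-7 sample quantiles with boundary ties to the lower
tertile (the convention is pinned because alternatives move boundary
participants). The Cox model (Efron ties) enters the tertile as a
categorical term with the **highest** tertile as reference, so the
reported hazard ratio reads lowest-versus-highest; whether the upstream
contrast was lowest-versus-highest or lowest-versus-rest is not
recoverable, so both are implemented (`contrast =`). Education enters
as an optional covariate, with a partial-likelihood-ratio comparison of
the two nested models.

```{r}
surv <- generate_conversion_times(cohort, follow_up_yr = 8)
fit_cox(surv)
```

## Numerical choices and degenerate inputs

* Coordinate descent converges at coefficient-change tolerance 1e-7
  (retry once from a cold start, then skip the iteration with a logged
  count); nonzero means |coefficient| > 1e-9.
* Zero-variance in-bag features are frozen at zero (eligible, never
  selected); zero-variance proteins abort clustering before scaling.
* All-zero paired differences give paired-t p = 1 with a degeneracy
  flag; permutation p is 1 by construction.
* Constant tertile-defining levels abort tertile assignment; complete
  separation in the Cox fit aborts with a diagnostic.
* Scale gates use inclusive bounds; the CV, LOD and nomination
  thresholds are strict, as documented per filter.

## Problem sizes used by the test suite

The packaged studies run at the reference cohort geometries (96 + 45
discovery, 215 + 102 replication) with panel sizes chosen per question:
the full 1,129-protein panel for QC accounting, 968 proteins for null
calibration (5 pooled seeds), 140 candidates with 5 planted effects for
the stability study (20 runs × 10,000 iterations), 200 simulations for
mixed-model coverage, 600 participants for Cox consistency, and
1,000–1,305-protein panels for the robustness stages.

## Known limitations

* The LASSO selector is linear-only; a logistic variant would need a
  second solver and is out of scope.
* The generator's effect sizes are chosen for testability; the
  upstream study does not report marker effect sizes on the RFU scale,
  so no fidelity claim is made for $\delta$.
* Frequencies from Stability Selection are interpretable as ranks, not
  as selection probabilities with error control; no per-family error
  bound is computed.
* Vendor plate calibration against proprietary calibrator sets is
  replaced by the documented median-reference default.
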