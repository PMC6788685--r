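# proteodiscover

An R implementation of a multicohort plasma-proteomics biomarker
workflow for Parkinson disease (PD), for biostatisticians and
translational researchers working with aptamer-based (SOMAScan-style)
panels. The package covers the full chain of such a study:

1. **QC / normalization** of raw relative-fluorescence units (RFUs):
   hybridization and median normalization, a 0.4–2.5 scale-factor
   gate, a triplicate CV > 0.2 filter, a >25%-outside-detection-limits
   filter, and the log10 transform.
2. **Discovery**: per-protein linear models
   `log10(RFU) ~ group + age + sex + LEDD` (PD = 1 vs NC = 0),
   nomination at group-effect p < 0.005, Benjamini–Hochberg FDR over
   the tested family, and hierarchical clustering (euclidean distance,
   average linkage) of the candidates.
3. **Stability Selection**: candidates ranked by the proportion of
   jackknife iterations (10% of samples and 30% of features left out
   of the bag per iteration) in which LASSO reports a nonzero
   coefficient anywhere on a per-subsample penalty grid
   `λ_max … 0.5·λ_max`; the inner coordinate-descent path solver is
   compiled, so 10,000-iteration runs take seconds.
4. **Replication**: the same estimator in an independent multisite
   cohort with site and plate covariates; a marker replicates when
   FDR q < 0.05 in both cohorts with the same direction of effect.
   Disease specificity against ALS via a three-group model, and a
   treated vs never-treated Wilcoxon comparison.
5. **Robustness**: paired t and exact sign-flip permutation tests for
   ON/OFF dopaminergic medication samples; ±30% flags for
   sample-handling percent change on raw RFU.
6. **Progression**: Spearman baseline correlation; linear mixed-effects
   models of cognitive score with a time-by-protein interaction and a
   participant random intercept; MoCA-based cognitive states
   (26–30 normal, 21–25 MCI, ≤20 dementia), conversion-event
   derivation with the baseline exclusion rules; tertile-stratified
   Cox proportional hazards (Efron ties, lowest-vs-highest contrast by
   default) with an optional education adjustment and a
   likelihood-ratio comparison of the nested models.

A synthetic-cohort generator (`generate_cohort()` and friends) emulates
the statistical structure the analysis assumes — log-normal RFUs,
planted log10-scale group effects, matched demographics,
site/batch shifts, correlated protein blocks, detection-limit
censoring, QC triplicates, paired ON/OFF samples, and cognitive
trajectories with biomarker-dependent slopes — so every stage is
testable against known ground truth. See the methods vignette
(`vignettes/biomarker-workflow.Rmd`) for the model, parameter and
design documentation.

## A worked example

```r
library(proteodiscover)

cfg <- sim_config(n_pd = 24, n_nc = 24, n_proteins = 120, n_planted = 4,
                  delta = 0.3, seed = 11)
cohort <- generate_cohort(cfg)

qc <- run_qc(cohort$matrix, qc_runs = generate_qc_triplicates(cfg))
qc$report
#> <qc_report>
#>   proteins assayed:  120
#>   excluded, CV > 0.2:        4
#>   excluded, >25% outside LOD: 13
#>   proteins retained: 103
#>   samples dropped (scale factor outside 0.4-2.5): 0
```

Thirteen proteins sat too close to the detection limits and four had
noisy QC triplicates; 103 enter the discovery scan.

```r
assoc <- run_discovery(qc$matrix, cohort$meta)
assoc
#> <association_table> 103 tests, 3 with q < 0.05
#>     protein_id  term   beta     se     t        p direction n_used      q
#> 8        P0008 group  0.258 0.0678  3.80 0.000447         1     48 0.0244
#> 84       P0097 group  0.313 0.0851  3.68 0.000646         1     48 0.0244
#> 72       P0084 group -0.290 0.0796 -3.65 0.000710        -1     48 0.0244
#> ...
```

`beta` is the adjusted PD−NC difference in log10 RFU; positive means
higher in PD. Stability Selection then ranks the nominated candidates:

```r
cand <- nominate_candidates(assoc, p_threshold = 0.05)
rk <- stability_rank(qc$matrix, cohort$meta$group, cand,
                     stability_config(iterations = 1000, seed = 11))
top_k(rk, 5)
#> [1] "P0008" "P0084" "P0097" "P0118" "P0017"
cohort$truth$planted_ids
#> [1] "P0008" "P0084" "P0097" "P0118"
```

All four planted markers lead the ranking. Downstream, tertile
survival models ask whether low baseline levels predict conversion to
MCI/dementia (the generator plants a hazard ratio of 2.27 for the
lowest tertile):

```r
surv <- generate_conversion_times(cohort, follow_up_yr = 8)
fit_cox(surv)
#> <cox_fit> 19 events / 24 participants (lowest_vs_highest)
#>               term    hr    lo   hi     p
#> 1       tertilelow 2.504 0.696 9.01 0.160
#> 2    tertilemedium 0.970 0.290 3.25 0.961
#> ...
```

At 24 participants the point estimate (2.50) is near the planted
hazard ratio but, as expected, not significant; the acceptance study
runs the same check at n = 600.

`run_pipeline(run_config(...))` chains every stage (simulation → QC →
discovery → ranking → replication → robustness → progression) and
writes tidy TSV reports plus a JSON manifest stamped with a
configuration hash.

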