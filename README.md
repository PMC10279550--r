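# protraj

Patient subphenotyping from repeatedly measured proteomic profiles.

Large aptamer-based proteomic panels (SOMAscan-style, thousands of proteins
measured as relative fluorescence units) are increasingly collected *serially*
in cardiovascular cohorts — typically a baseline sample plus the last two
samples drawn before an adverse event or censoring. `protraj` is for
biostatisticians and computational biologists who want to turn such data into
patient subphenotypes and ask whether those subphenotypes carry prognostic
information. It implements the full analysis chain as a tested R package:

1. **Preprocess** — filter aptamers to human, validated, highest-affinity
   (smallest Kd) reagents; keep each patient's baseline + last two samples;
   log-transform and Z-score per protein.
2. **Trajectory features** — per protein, fit the linear mixed model
   `y_ij = (β₀+b₀ᵢ) + (β₁+b₁ᵢ)·t_ij + ε_ij` with `(b₀,b₁) ~ N(0, Ψ)` by REML
   and take each patient's predicted intercept and slope (BLUPs) as features.
3. **Cluster patients** — embed the feature matrix (PCA by default, UMAP via
   `umap-learn` optionally), choose k by a bootstrap consensus of seven
   cluster-validity indices (silhouette, Calinski–Harabasz, Davies–Bouldin,
   Dunn, C-index, gap statistic, Hartigan), assign by k-means++, and score
   per-cluster stability as the mean best Jaccard similarity under Gaussian
   feature noise.
4. **Protein subsets** — cluster proteins (not patients) separately on the
   intercept and slope axes; quantify per-protein association with the
   subphenotypes by Kruskal–Wallis with Benjamini–Hochberg correction; score
   patients per subset via a random-intercepts model.
5. **Outcomes** — compare clinical characteristics (Kruskal–Wallis /
   chi-square / Fisher), fit four pre-specified Cox proportional-hazards
   adjustment levels with Efron ties, and report hazard ratios, AIC/BIC, and
   Harrell's C with bootstrap optimism correction; Kaplan–Meier + log-rank.

Because cohorts of this design are not publicly deposited, the package ships
a synthetic-cohort generator (`cohort_config()` / `generate_cohort()`) with
known latent subphenotypes, protein-subset effects, trimonthly jittered
visits, and proportional-hazards event times — every stage of the pipeline is
tested end to end against it.

## A worked example

```r
library(protraj)

cfg <- cohort_config(n_patients = 120, n_proteins = 60,
                     baseline_hazard = 1e-4, log_hr = rep(0, 4), seed = 7)
coh <- generate_cohort(cfg)
fit <- protraj(coh$long, coh$outcomes, annotation = coh$annotation,
               B_boot = 25, R_stab = 50, seed = 1)
fit
#> Proteomic subphenotypes (repeated mode): 120 patients, 60 proteins, k = 4
#>   cluster sizes: 36, 31, 27, 26
#>   modal k over 25 bootstrap resamples: 4
#>   stability (tau = 0.1): mean Jaccard 1.00, 1.00, 1.00, 1.00

adjusted_rand_index(cluster_labels(fit),
                    coh$truth$patient[names(cluster_labels(fit))])
#> [1] 1
```

The printout says the bootstrap consensus over 25 resamples voted for four
clusters (the number planted by the generator), that the four clusters hold
36/31/27/26 of the 120 patients, and that every cluster's allocation is
perfectly stable under feature noise of SD 0.1 (mean Jaccard 1.00, far above
the 0.75 "stable" flag). The adjusted Rand index of 1 means the recovered
subphenotypes match the generator's latent groups exactly.

Continuing with the same fit:

```r
part <- cluster_proteins(fit$features, "intercept", seed = 2)
drv <- driver_summary(part, fit$features, cluster_labels(fit))
drv
#> Driver statistics (intercept axis):
#>  subset n_proteins n_significant fraction_significant
#>       A         15            15                    1
#>       B         15            15                    1
#>       C         15            15                    1
#>       D         15            15                    1
```

The intercept-axis protein clustering recovers the four planted 15-protein
subsets, and in every subset 100% of proteins are significantly associated
with the subphenotypes after Benjamini–Hochberg correction (q ≤ 0.05).

`run_pipeline(run_config(...))` chains all stages — simulation or TSV/ADAT
inputs, preprocessing, features, consensus clustering, stability, protein
subsets, survival — with per-stage seeds derived from one master seed,
cached resumable intermediates, and a TSV/JSON report
(`write_report()` / `manifest.json`).

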