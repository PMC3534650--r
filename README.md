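# ccam — canonical correspondence analysis for paired transcriptome datasets

`ccam` relates a gene × sample expression matrix that needs explaining
(e.g. disease transcriptomes: leukaemia, myelodysplastic syndromes) to the
averaged expression profiles of well-characterised groups from an
independent dataset (e.g. sorted normal haematopoietic cell populations).
It is built for the *maturation arrest* question: where along normal
differentiation does each patient's transcriptome sit, which genes drive
that placement, and does the placement predict outcome?

The engine is canonical correspondence analysis (CCA) in the χ²-metric of
correspondence analysis. For a nonnegative matrix **S** (genes × samples):

- **P** = S / grand total, row masses **r**, column masses **c**;
- standardized residuals **Q̄** = D_r^(−1/2) (P − r cᵀ) D_c^(−1/2); the
  total *inertia* is ‖Q̄‖² (the table's Pearson χ² / total);
- the environment matrix **Z** (genes × populations, per-population means
  of the z-scored reference) is standardized with **r** as weights and the
  residuals are projected onto it: Z_w = D_r^(1/2) Z_std,
  **Q_c** = Z_w (Z_wᵀ Z_w)^(−1) Z_wᵀ Q̄;
- the SVD Q_c = U Λ Vᵀ gives the axes. ‖Q_c‖² = Σ λ_k² is the
  *constrained inertia*; %Explained = 100 · constrained / total; sample
  scores are D_c^(−1/2) V, constrained (lc) gene scores D_r^(−1/2) U, and
  weighted-average (wa) gene scores (D_r^(−1) P · samplescore_k)/λ_k;
- environment arrows are the r-weighted correlations between Z_std columns
  and the wa gene scores of each axis.

On top of the engine: one-vs-rest moderated-t population signatures
(empirical-Bayes variance shrinkage with digamma/trigamma hyperparameter
inversion), Pearson signature scoring, an axis-derived prognostic score
(top/bottom wa-ranked gene lists, mean-z difference, percentile strata),
Kaplan-Meier / log-rank / Cox survival analysis, confidence-ellipse triplot
coordinates, a ground-truth synthetic data generator, and a CLI.

## Worked example

Synthetic demonstration: 5 mixture populations (HSC, MEP, CMP, GMP, ProB)
plus 2 reference-only populations, 200 disease samples whose transcriptomes
are Dirichlet mixtures of the population programs, and survival driven by
the HSC mixture weight (log hazard ratio 1.5 per unit weight).

```r
library(ccam)
cfg  <- synthetic_config(seed = 1)
ref  <- make_reference(cfg)
dis  <- make_disease(cfg)
sv   <- make_survival(cfg, dis$truth)
pipe <- ccam_pipeline(dis$expr, ref$expr, ref$annotation$group,
                      populations = cfg$population_names)
pipe$fit
#> Canonical correspondence analysis (chi-square metric)
#>   500 genes x 200 samples, 5 environment variables
#>   Total inertia:       0.0850875
#>   Constrained inertia: 0.0502628 (%Explained = 59.07)
#>   Eigenvalues (share of constrained inertia):
#>     Axis1  0.0174051 (34.6%)
#>     Axis2  0.0116954 (23.3%)
#>     Axis3  0.0109452 (21.8%)
#>     Axis4  0.010143 (20.2%)
#>     Axis5  7.40389e-05 (0.1%)
```

59% of the cohort's χ² variation is interpretable through the five normal
programs, and axis 1 carries 34.6% of that constrained part. The arrow
coordinates show axis 1 is the stemness axis (HSC 0.98; all other
populations negative), so the default axis-1 score is an HSC-ward severity
score. The median-split strata separate survival:

```r
st <- merge(pipe$strata, sv, by = "sample_id")
logrank_test(st$time, st$event, st$stratum)
#> chi-square = 22.47 on 1 df, p = 2.13e-06
cox_ph(st, "score")
#>   covariate  coef hazard_ratio ci_lower ci_upper  p_value
#>   score     0.452         1.57     1.30     1.90  2.74e-06
```

A hazard ratio of 1.57 per score standard deviation: samples scored as more
stem-like progress faster, which is the planted ground truth.

## Command line

```sh
Rscript inst/cli/ccam.R demo --seed 1 --out-dir demo_out
Rscript inst/cli/ccam.R fit --expr disease.tsv --ref reference.tsv \
    --annotation ann.tsv --populations HSC,MEP,CMP,GMP,ProB --out-dir fit_out
```

Stages: `prepare`, `signatures`, `fit`, `score`, `survival`, `plot`,
`demo`; every stage accepts `--config config.yaml` and writes
deterministic, byte-stable TSV/YAML artifacts.

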