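---
title: "Constrained ordination of paired transcriptome datasets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained ordination of paired transcriptome datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccam)
options(ccam.verbose = FALSE)
```

## The problem and the model

Disease transcriptomes are routinely interpreted against normal cellular
counterparts: a leukaemia sample resembles the differentiation stage at
which its cells are arrested, and a myelodysplastic marrow may lean toward
stem/progenitor programs. Comparing the two kinds of datasets directly
(clustering, MDS) fails because between-experiment variation dwarfs the
biological contrasts of interest; comparing one signature at a time hides
the relationships *between* signatures. Canonical correspondence analysis
solves both problems: the disease matrix is the response, the per-population
average profiles of an independent reference are the explanatory
("environmental") variables, and only the part of the disease variation
that is interpretable through the reference is decomposed into axes.

Genes play the role of observations (rows); expression values are treated
as frequencies, which is why the χ²-metric applies and why the matrix must
be nonnegative. For the main matrix \(S\):

\[ P = S/n_{++},\quad r = P\mathbf{1},\quad c = P^T\mathbf{1},\quad
   \bar{Q} = D_r^{-1/2}(P - rc^T)D_c^{-1/2} . \]

\(\|\bar Q\|_F^2\) is the total inertia. The reference matrix is z-scored
per gene, averaged per population into \(Z\), standardized column-wise with
the row masses \(r\) as weights, and the residuals are projected onto the
weighted environment space:

\[ Z_w = D_r^{1/2} Z_{std},\qquad
   Q_c = Z_w (Z_w^T Z_w)^{-1} Z_w^T \, \bar{Q} . \]

The SVD \(Q_c = U\Lambda V^T\) (singular values descending, values below
\(10^{-12}\lambda_1\) treated as zero) yields eigenvalues \(\lambda_k^2\)
whose sum is the constrained inertia. Three score systems share the axes:
sample scores \(D_c^{-1/2}V\), constrained (lc) gene scores
\(D_r^{-1/2}U\), and weighted-average (wa) gene scores
\((D_r^{-1}P\,\text{samplescore}_k)/\lambda_k\). lc scores are exactly the
\(r\)-weighted projection of wa scores onto the environment space — a
property the test suite asserts axis by axis. Environment arrows are
\(r\)-weighted Pearson correlations between \(Z_{std}\) columns and the wa
scores, i.e. standardized single-regressor coefficients; they are bounded
by 1 in absolute value.

Diagnostics: %Explained = 100 · constrained/total inertia compares how much
of a cohort different explanatory sets can interpret (only meaningful for
the same genes and main matrix, so the report carries a fingerprint of
both); %Visualised is the share of constrained inertia in the displayed
axes.

## Numerical and convention choices

- **Sign convention.** SVD signs are arbitrary; each axis is oriented so
  the environment arrow with the largest absolute loading is positive.
  This makes every output deterministic and byte-stable.
- **Scaling.** The display scaling (0 = standard coordinates, 1 = gene
  scores × Λ, 2 = sample scores × Λ, default 2) multiplies scores after
  sign fixing; fitted quantities (eigenvalues, inertia) are unaffected.
- **Nonnegativity.** The χ²-form requires nonnegative entries, but z-scored
  expression is not nonnegative and there is no canonical way to reconcile
  the two. Both documented modes are provided: `global_min` (subtract the
  matrix minimum; default, rank-preserving) and `clip_zero`. The pipeline
  applies `global_min` and logs the shift.
- **Cross-level distances.** Sample and gene spaces have different sizes,
  so inter-level relations use angular distance (arc cosine of the cosine
  similarity), never Euclidean distance; `nearest_arrow()` implements the
  assignment of samples to their most correlated population.
- **Exact collinearity of population averages.** If the reference is
  z-scored per gene and *all* of its populations are used as explanatory
  variables, the population means are exactly linearly dependent (their
  size-weighted sum is zero for every gene) and the projection is singular.
  `cca_fit()` refuses such environments, naming the aliased columns;
  `check_env_collinearity()` reports pairwise correlations and VIFs. In
  practice — as in the haematopoietic analyses that motivated the method —
  one selects a biologically meaningful subset of populations.

## Gene signatures and the moderated t

Population signatures come from a one-vs-rest equal-variance contrast per
gene, with empirical-Bayes variance moderation: sample variances are
modelled as scaled inverse-χ² around a prior \(s_0^2\) with \(d_0\) degrees
of freedom, estimated by moment-matching the distribution of \(\log s_g^2\)
(digamma/trigamma inversion); the moderated statistic uses the posterior
variance \(\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)\) with
\(d_0+d_g\) degrees of freedom, and Benjamini-Hochberg adjustment across
genes. The two limits anchor the implementation: \(d_0 = 0\) reproduces the
ordinary t exactly and \(d_0 \to \infty\) collapses all posterior variances
to \(s_0^2\); the tests also verify equality with the reference
implementation in limma and null calibration at 2000 genes. The one-vs-rest
design was chosen because each population is characterised "against all
other populations"; no general design-matrix machinery is offered.

Signature thresholds default to adjusted p ≤ 1e−5 and top 200 genes per
population; there is no field-wide canonical cutoff, so these are
explicit, configurable choices. The pipeline filters genes
using only the signatures of the populations chosen as explanatory
variables: signatures of unused reference populations would admit genes
carrying no information about the cohort and dilute downstream scores.

## The axis-derived prognostic score

Genes are ranked by wa score on one axis; the top and bottom 100 define the
score model. The per-patient combination rule is not printed in the source
method and is a documented decision here: mean per-gene z-score over the
top list minus the mean over the bottom list, then z-scaled across samples.
The rule is monotone in the wa ranking, robust to unequal list sizes, and
flipping the axis sign swaps the lists and negates the scores exactly.
Percentile stratification assigns ties to the lower stratum (type-7
quantiles); the canonical cuts are the 50th and the 50th+95th percentiles.
`select_axis()` implements the first step of map analysis — identifying an
axis through its arrow loadings (e.g. the stemness axis) — before a score
is built on it.

## Survival statistics

Kaplan-Meier curves and the k-sample log-rank test (hypergeometric-variance
formulation, χ² with k−1 df) are implemented directly and checked against
direct O−E enumeration and `survival::survdiff`. Cox regression is a thin
contract over `survival::coxph` with Efron tie handling, with explicit
errors for constant covariates and non-convergence/separation. Group
comparisons use Kruskal-Wallis (>2 groups) or Mann-Whitney (2 groups) with
tie correction; the Bonferroni option multiplies by the number of pairwise
comparisons — the conservative family-wise choice usual in clinical
stratification analyses.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` states one world per analysis type:

- **Reference** (sorted-population style): per population, a marker block
  of 100 genes shifted by 3 sd over a shared baseline, 6 replicates,
  Gaussian noise sd 0.5. Two reference-only populations (NM, MatB) emulate
  the fact that real references carry many more populations than the few
  used as explanatory variables — and, technically, break the exact
  collinearity described above.
- **Disease cohort** (default, MDS-like): each sample is a Dirichlet
  mixture of the five population programs plus noise. The default
  concentration c(1, 0.3, 0.3, 0.3, 0.3) encodes a severity continuum:
  the cohort varies chiefly in its degree of maturation arrest toward the
  target (stem-like) population, which makes the first axis the severity
  axis, as in the motivating myelodysplastic cohort. A symmetric sparse
  concentration (e.g. 0.1) instead gives a leukaemia-like cohort of
  near-pure samples, the appropriate world for asking whether each
  sample's nearest arrow recovers its dominant program.
- **Survival**: exponential event times with hazard
  0.1 · exp(1.5 · w_target); independent exponential censoring whose rate
  is solved (root finding on the expected censored fraction) to give 30%
  censoring.

Not emulated: probe-level noise physics, batch nonlinearity beyond additive
per-gene shifts, correlated marker blocks, and any cohort structure beyond
mixtures of fixed programs. A green recovery test therefore establishes
that the ordination geometry works on mixture data of stated noise — not
that real marrow deconvolves this cleanly.

## Known limitations

- No permutation tests for axis significance, no partial or detrended
  variants.
- Cross-platform gene matching is identifier intersection; probe-level
  best-match mapping is out of scope.
- The batch adjustment is the parametric location/scale empirical-Bayes
  model only (no nonparametric variant, no covariate preservation).
- The 95% ellipses use the bivariate-normal χ²(2) quantile on the group
  covariance — the standard construction; covariance-scaling alternatives
  can be substituted by adjusting the quantile.
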