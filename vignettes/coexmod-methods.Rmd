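---
title: "Methods: discovering bimodal co-expression modules across datasets"
author: "coexmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering bimodal co-expression modules across datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large compendia of tumor expression datasets contain recurring patterns in
which groups of genes switch together between an "off" and an "on" state —
estrogen-receptor programs, proliferation, immune infiltration, extracellular
matrix. `coexmod` finds such groups without using any clinical labels, by
asking two questions of every candidate pattern: *is each gene's expression
bimodal within a dataset?* and *does the same co-expression pattern recur
independently in several datasets?* Patterns that pass both filters are
aggregated into consensus **modules**, each summarized by a gene list and a
weight vector that can score any new sample by a simple inner product.

## The pipeline, stage by stage

### Normalization and array-quality adjustment

Within each dataset every gene is z-scored (sample standard deviation,
`n - 1` denominator); zero-variance genes are dropped with a warning because
they carry no co-expression signal and break the mixture fits. The
**avg.z** quality score of an array is the mean of its gene z-scores:
technically poor arrays shift all genes together, so avg.z captures a
pervasive technical factor. Each gene row is then replaced by its OLS
residual on (intercept, avg.z) and re-z-scored, so that downstream
projections operate on unit-variance rows. Because a shared additive
per-array offset loads identically on every gene, this residualization
removes it exactly (the generator constructs its quality confounder the same
way, which is what makes the adjustment provably complete on synthetic
data). The adjustment is idempotent; if avg.z is constant it is skipped with
a warning since the regression is undefined.

### Bimodality: mixture model, index, and empirical null

Each gene is fit with a two-component, **equal-variance** univariate
Gaussian mixture `pi N(mu1, sigma^2) + (1 - pi) N(mu2, sigma^2)` by EM.
The equal-variance form is the model under which the Bimodality Index

BI = sqrt(pi (1 - pi)) * |mu2 - mu1| / sigma

is defined; BI is location/scale free and symmetric in the two components.
Fitting uses the best of 10 initializations — quartile means with pi = 0.5
first, then random quantile pairs — with each gene's restart stream seeded
from a hash of (dataset id, gene id), so results do not depend on the order
genes are processed. Restarts are screened at a loose tolerance (1e-4,
at most 300 iterations) and the winner is polished to the convergence
criterion (log-likelihood change below 1e-8 within 1,000 iterations); the
two-stage schedule is purely a speed optimization and changes the null
quantiles by less than 0.001. Solutions in which a component collapses onto
almost a single observation are not meaningful maximum-likelihood estimates
(the mixture likelihood is unbounded there) and are rejected.

Significance is assessed against a **simulated null**: 10,000 standard
normal samples of the same size as the dataset, each fit with the identical
procedure. Standard normals suffice because BI is location- and scale-free.
The empirical p-value uses the add-one convention
`p = (1 + #{null BI >= observed BI}) / (n_draws + 1)`, avoiding p = 0.
P-values are Benjamini–Hochberg adjusted *within* each dataset (bimodality
is a per-dataset property) and genes with q < 0.05 are called bimodal.

A practical note on power: the null 95th/99.5th percentiles of BI at
n = 100 are roughly 1.17/1.37. A planted effect of 3 within-component
standard deviations with a 30/70 split has BI ≈ 1.37 — right at the null
99.5th percentile — so after FDR adjustment only the stronger half of such
genes is detected. Balanced (50/50) on/off patterns of the same separation
(BI = 1.5) are detected much more reliably. This is a property of the
statistic, not of the implementation, and it shapes what the end-to-end
recovery results below can and cannot show.

### Within-dataset gene clustering

Significantly bimodal genes are clustered on their standardized
across-sample profiles with Gaussian mixtures under spherical
(`sigma_k^2 I`) and diagonal per-component covariances, k from 1 to
min(20, genes/3). These restricted families are used because the feature
dimension (samples) routinely exceeds the number of observations (genes),
where full covariances are singular. Model selection maximizes
`BIC = loglik - (n_params / 2) ln(n_genes)`, ties toward smaller k. Each
(k, family) fit takes the best of 5 k-means++-style seedings drawn from a
dataset-seeded stream. Degenerate solutions (a component owning fewer than
two observations, or a variance at the numerical floor of 1e-4 times the
mean feature variance) are rejected; if every seeding degenerates the
(k, family) cell is treated as unavailable, mirroring how the standard
model-based-clustering tools handle singular fits. Hard assignments come
from maximum posterior; clusters below 3 genes are discarded (PC1 of fewer
than 3 genes is not a meaningful pattern summary).

### Metagenes and projection scoring

Each cluster is summarized by the unit-norm first principal axis of its
genes × samples submatrix in its origin dataset (genes as variables; the
rows are z-scored, so this is a correlation-style PCA). The sign is chosen
so that member genes correlate positively with the projected score on
average; an exact tie falls back to making the first gene's weight positive,
with a warning. Every sample in the compendium is scored by the inner
product of its z-scored expression with the metagene; datasets are always
normalized independently before projection. When a target dataset lacks
some metagene genes, the projection simply omits them **without
renormalizing** — renormalization would silently change the score scale
between platforms — and the retained fraction of the weight norm is
reported (warning below 0.5).

### Consensus modules

Pairwise Pearson correlations between cluster score rows define a
cluster–cluster similarity. A cluster is **recurrent** if it correlates
(strictly r > 0.7) with at least `min_neighbors` other clusters. The
reference value of `min_neighbors` is 6, appropriate for compendia of many
dozens of datasets; since a pattern that appears once per dataset can have
at most D − 1 correlated partners in a D-dataset compendium,
`discover_modules()` scales the default to `min(6, D - 1)` (explicit
override available). Retained clusters are hierarchically clustered using
the *rows of the correlation matrix* as feature vectors (Euclidean
distance, complete linkage). The tree is cut into k modules; with
`n_modules = "auto"` k maximizes the mean silhouette width over
k = 2..min(15, n − 1), falling back to k = 2 with a warning when the
silhouette is degenerate (e.g. all pairwise correlations equal). A module's
distilled gene set keeps the genes present in **strictly more than 1/3** of
its member clusters; at the boundary (exactly 1 of 3) the gene is excluded.
Module weights are the unit-norm PC1 of the gene set over the pooled,
per-dataset z-scored samples of the datasets that contributed a member
cluster, with the metagene sign convention. Scoring new data reuses the
metagene projection rules; cross-platform data should first be
median-collapsed to gene symbols (`collapse_by_symbol()`) and z-scored.

### SigClust validation

Whether two modules are genuinely distinct is tested with SigClust: the
**cluster index** CI = (within-group SS) / (total SS) of the two-module
split of the member clusters (in the same correlation-row feature space
used to define the modules) is compared with CIs of `n_sims` datasets drawn
from the best-fitting single Gaussian null. The null covariance eigenvalues
are estimated by thresholding the sample eigenvalues against the background
noise variance `sigma_N^2 = (MAD of feature-centered entries /
qnorm(0.75))^2`:

* **hard**: `lambda~_j = max(lambda_j, sigma_N^2)`;
* **soft**: `lambda~_j = max(lambda_j - tau, sigma_N^2)`, with `tau >= 0`
  chosen so the total variance `sum(lambda~)` equals `sum(lambda)` when
  feasible (`tau = 0` if the floor alone already exceeds the target, and
  full shrinkage to `sigma_N^2` everywhere when even the largest shift
  cannot reach it).

Null data are simulated directly in the eigenbasis (independent normals
scaled by `sqrt(lambda~_j)`), which is exact because CI is rotation
invariant, and partitioned by 2-means with 10 seeded restarts. The p-value
is add-one empirical. Observed labels for module pairs are the module
assignment itself — the hypothesis under test is the distinctness of the
*assigned* modules, not of a re-fit 2-means split. No ordering between
hard- and soft-threshold p-values is assumed; none holds in general.

### Downstream association statistics

* **Coherence**: all-pairs Pearson correlations of module genes, Fisher
  z-transformed (r clipped at 1 − 1e-12); contexts are compared by Welch
  t-test on the z vectors. Welch is used wherever a t-test appears — the
  equal-variance assumption buys nothing here and fails for unbalanced
  pair counts.
* **Intrinsic/extrinsic rule**: extrinsic if cell-line mean back-transformed
  r < 0.1 and tumor median r > 0.35; intrinsic if both contexts have median
  r > 0.35; otherwise indeterminate. The 0.1 threshold operationalizes
  "essentially uncorrelated" as a testable bound.
* **Variance**: F-test on module-score variances (two-sided).
* **ROC/AUC**: rank-based AUC with ties counted 1/2; the Youden threshold
  maximizes sensitivity + specificity − 1 over observed cut-points,
  breaking ties toward higher specificity so the output is deterministic.
* **Survival / response**: per-module Cox proportional-hazards fits (Efron
  ties) and logistic fits, Wald p-values, BH adjustment across modules
  (same implementation as the bimodality FDR), optional covariate
  adjustment as continuous columns by default. Non-convergence and
  separation are flagged in the output rather than dropped.
* **Pooling**: datasets are pooled by per-dataset, per-gene mean-centering
  followed by concatenation. This removes source-level location effects —
  the piece that matters for projection scoring — and deliberately stops
  short of distribution-matching batch correction, which is out of scope.
* **Dichotomization**: median rule (strictly above) or lower tertile
  (at or below the interpolated 33.33rd percentile).

## The synthetic compendium

The generator exists so every stage is testable without external data. Each
dataset is

`baseline + effect * latent * loading + quality + noise`

on the log2 scale: per-gene baselines N(7, 1.5²) (plausible microarray
location; irrelevant after z-scoring), iid Gaussian noise (sd 1 by
default), and an additive per-array quality offset (sd 0.6) applied to all
genes of a sample — exactly the structure avg.z residualization removes.
Each planted module has a per-sample binary latent state shared by its
member genes; states across modules come from thresholding a correlated
Gaussian copula (`latent_coupling`) at the quantile matching each module's
activation probability, the simplest mechanism that produces controllable
between-module correlation such as an ER/proliferation anti-correlation.
Member genes multiply the effect by a per-gene loading
`max(0.2, 1 + N(0, 0.2²))`, drawn once per compendium so that the planted
loading direction is a well-defined truth for weight-recovery checks; the
truncation keeps every member gene participating. Modules flagged
*extrinsic* lose their shared latent in cell-line-context datasets (each
gene gets an independent latent), reproducing the signature of
microenvironment-driven co-expression. Defaults — six tumor datasets of 120
samples, 3,000 genes, five 40-gene modules, effect 3, activation 0.5 — are
the package's reference study conditions; 0.5 is the canonical balanced
on/off pattern (scenarios that need an unbalanced split set
`activation_prob` explicitly).

Clinical annotation is generated from the latent states: exponential
survival with log-hazard linear in the states and independent exponential
censoring whose rate is `h0 * c / (1 - c)` (so `c = 0` means no censoring
and a baseline sample is censored with probability c); Bernoulli pCR with
`logit P = qlogis(0.25) + sum(gamma_m s_m)`; subtype labels by a fixed rule
on the first three module states (1&2 on → LumB; 1 on → LumA; 3 on → Her2;
2 on → Basal; none → Normal); ER/HER2 status from states 1 and 3; and a
bone-vs-other metastasis site drawn for events from a logistic model on the
states.

What the generator does **not** emulate: probe-level artifacts, platform
differences, realistic batch structure beyond the additive quality term,
heavy-tailed noise, or overlapping module membership. Passing recovery
tests therefore demonstrates the pipeline's internal consistency under its
own model, not performance on real arrays.

## Numerical and design choices worth knowing

* All randomness derives from one top-level seed through a documented hash
  (`derive_seed(seed, stage, id, ...)`, a 31-ary polynomial over the key
  bytes mod 2³¹ − 1), so stages are reproducible independently of execution
  order and identical runs are byte-identical.
* Empirical nulls are cached per (n, draws, seed) within a session; one
  null serves every dataset of a given size.
* Gene universes are sorted in C-locale (radix) order for platform-stable
  reproducibility.
* The EM convergence contract (1e-8 absolute log-likelihood change, 1,000
  iterations) applies to the reported fit; restart screening is looser, as
  described above.
* Validation problem sizes: the packaged checks use the default compendium
  over 10 generator seeds for module recovery, 20 replicates of 2,000 genes
  for null calibration, 200 replicates (200 simulations each) for SigClust
  calibration, and 100–500 replicates for the clinical statistics. These
  sizes give Monte-Carlo standard errors comfortably inside the asserted
  tolerances.

## Known limitations

* FDR-adjusted bimodality detection has limited power for unbalanced
  moderate effects (see the power note above); gene-level recall of the
  end-to-end pipeline inherits this limit, and module gene sets should be
  read as high-confidence cores rather than exhaustive membership lists.
* The silhouette-based automatic module count is reliable when modules are
  well separated in score-correlation space; closely coupled modules (high
  `latent_coupling`) can merge.
* SigClust assumes the single-Gaussian null is meaningful in the
  correlation-row feature space; with very few member clusters per module
  the test is conservative and single-cluster modules are skipped.
* The strict >1/3 membership rule interacts with cluster fragmentation:
  when a dataset contributes several fragments of the same pattern, genuine
  members present in only one fragment per dataset can fall below the
  threshold.
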