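---
title: "Methods: consensus m6A-regulator clustering and the m6A score"
author: "m6ascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus m6A-regulator clustering and the m6A score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

N6-methyladenosine (m6A) is the most common post-transcriptional mRNA
modification. Its level in a tumor is governed by the expression of a
small panel of regulator genes — methyltransferase "writers", effector
"readers" and demethylase "erasers" — and direct biochemical measurement
of m6A is impractical on archival cohorts. `m6ascore` therefore works
from the expression of the 16-gene regulator panel
(`m6a_regulator_panel()`): it groups patients by regulator expression
signature, condenses the transcriptional consequences of that grouping
into a single per-patient **m6A score**, and relates the score to
survival, tumor-microenvironment activity and immunotherapy response.
The pipeline was designed around bulk expression cohorts of follicular
lymphoma (log2 microarray intensities or log2(FPKM+1) RNA-seq), but
every stage is generic gene-by-sample machinery.

The full analysis chain is:

1. merge cohorts and remove batch effects (empirical-Bayes
   location–scale adjustment, `combat_adjust()`);
2. consensus-cluster samples on the z-scored regulator panel
   (`consensus_cluster()`, `select_k()`), name the poor-prognosis
   cluster "A" (`label_m6a_clusters()`);
3. find genes differentially expressed between the two clusters with a
   moderated t-statistic at adjusted p < 0.01 (`moderated_de()`);
4. trim the DEG list by random-forest permutation importance
   (`rf_redundancy_filter()`) and univariate Cox significance at
   p < 0.05 (`cox_univariate_filter()`);
5. fit a PCA over the surviving genes and score each patient as the sum
   of its first two principal-component sample scores
   (`fit_signature()`, `score_samples()`);
6. dichotomize at the maximally selected log-rank cutpoint
   (`optimal_cutoff()`) and fix the sign convention so that a **low**
   score marks poor prognosis (`orient_score()`);
7. characterize the groups: Kaplan–Meier/log-rank/Cox/time-dependent
   ROC (`km_fit()`, `logrank_test()`, `cox_fit()`, `time_roc()`),
   gene-set scoring (`ssgsea_score()`, `gsea_two_group()`), the
   18-gene tumor-inflammation signature (`tis_score()`), marker-set
   immune scoring (`immune_marker_scores()`), and response prediction
   by binary ROC (`binary_roc()`).

`run_pipeline()` executes the chain end to end from a
`pipeline_config()` (or a YAML file via `read_pipeline_config()`),
writing plain TSV/JSON artifacts per stage so any stage can be
inspected or re-run; the package's functions, this vignette and
`scripts/acceptance.R` are the intended interfaces.

## Consensus clustering and the choice of k

Samples are clustered on the z-scored regulator rows with k-means
(Euclidean distance), repeated over `reps` random subsamples of the
samples (fraction `subsample`, default 0.8, drawn **without**
replacement; features are never subsampled). For each k the consensus
matrix M_k is the fraction of co-sampling occasions on which two
samples co-clustered; final labels cut an average-linkage hierarchical
tree of 1 − M_k at k.

k is selected by minimizing the **PAC** (proportion of ambiguous
clustering): the fraction of off-diagonal consensus entries strictly
inside (0.1, 0.9). PAC is a quantitative proxy for "clustering
stability"; the consensus-CDF area and its relative increase
(delta-area) are also reported for inspection, but the selection rule
is argmin PAC with ties resolved toward the smaller k. Two properties
drive the test suite: with `reps = 1, subsample = 1` the consensus
matrix is exactly the 0/1 co-membership matrix of a single k-means
run, and PAC at the true k decreases as the cluster separation grows.

One practical caveat, visible in the test fixtures: on perfectly
symmetric multi-cluster data the k = 2 solution can be *stable* (it
always merges the same pair), so distinguishing k = 3 from k = 2 by
PAC relies on the subsampling perturbing the merge choice. Stronger
subsampling (fraction 0.6) exposes that ambiguity more reliably, which
is what the three-cluster recovery checks use.

The defaults (k = 2..10, 1000 replicates, 0.8 subsampling, 20 k-means
restarts per replicate) mirror the upstream consensus-clustering
convention; the m6A-related clusters simply re-run the same procedure
on the DEG-restricted matrix.

## Batch correction

`combat_adjust()` implements the parametric empirical-Bayes
location–scale model (Johnson et al. 2007): standardize each gene
against the batch-size-weighted grand mean and the pooled residual
variance; estimate per-batch per-gene location (normal prior) and
scale (inverse-gamma prior) effects; moment-match the hyperparameters
across genes; iterate the conditional posterior means to convergence;
adjust and back-transform. No covariates are preserved (the method's
default mode), and all genes are adjusted. The implementation agrees
with the reference `sva::ComBat` to ~1e-3 on generic two-batch data
(the reference serves as a cross-check in the tests, never as the
implementation, since the fitted `batch_model` — the shrunken
location/scale parameters — is part of the returned artifact).

Two numerical facts are worth stating plainly because they shape the
tests. First, EB shrinkage pulls each gene's batch-location estimate
toward the cross-gene mean, so after adjustment the per-gene batch
means still differ by O(1/sqrt(n)) under generic noise; they agree to
machine precision exactly when the per-gene batch effects are
homogeneous across genes (then the posterior coincides with the exact
adjustment), which is the regime the equalization test constructs.
Second, the procedure is not exactly idempotent: the standardization
pools variance with 1/n while batch scale is estimated with 1/(n−1),
so re-application rescales by about sqrt(n/(n−1)); the tests bound the
re-application change rather than asserting a fixed point.

## Differential expression

`moderated_de()` fits the ordinary two-group linear model per gene and
shrinks residual variances toward a common prior: the log sample
variances are moment-matched to a scaled-F distribution (trigamma
inversion by Newton iteration), giving prior degrees of freedom d0 and
prior scale s0²; the moderated t uses the posterior variance
(d0·s0² + df·s²)/(d0 + df) on df + d0 degrees of freedom. Forcing
`prior_df = 0` recovers the pooled two-sample t exactly, which the
tests exploit; with the default moment-matched prior the statistics
agree with `limma::eBayes` to ~1e-8 (the independent oracle).
Significance is adjusted p < 0.01 (Benjamini–Hochberg via
`stats::p.adjust`), with no fold-change filter — the only threshold
the method states. Cohort is not included as a covariate; correction
precedes DE in the pipeline order.

## The signature and the score

The random-forest filter ranks DEGs by permutation importance (mean
decrease in accuracy, 500 bootstrap trees, sqrt(p) candidate features
per split) for predicting the cluster label, and keeps genes whose
importance is strictly above **the larger of the median and the mean**
importance. A median-only cut retains exactly half the genes by
construction and therefore cannot concentrate on a small informative
subset; adding the mean component keeps the null behaviour (about half
pass when labels carry no information, since mean ≈ median ≈ 0) while
discarding the bulk of uninformative genes when a heavy right tail of
informative importances pulls the mean up. The filter is skipped, with
a warning, below 10 candidate genes. The forest is run as
classification against the cluster labels (not as a survival forest).

Surviving genes pass a univariate Cox screen (Efron ties, Wald
p < 0.05 on z-scored expression; non-convergent genes are dropped with
a warning). The PCA is fitted on the z-scored samples × genes matrix;
the m6A score of a sample is its PC1 sample score plus its PC2 sample
score — the only reading of "sum of the two component scores" that
yields one number per patient. Each loading's sign is fixed so its
largest-magnitude entry is positive, making the fit deterministic.

Scoring a new cohort z-scores the signature genes **within that
cohort** and projects onto the frozen training loadings — this makes
the score portable across platforms (microarray vs FPKM), which
external validation requires; refitting the PCA per cohort is
available behind `refit = TRUE` for comparison. Missing signature
genes (up to 20%) contribute zero, with the loadings renormalized to
unit norm over the present genes.

The high/low cutpoint maximizes the standardized log-rank statistic
over all splits leaving at least `minprop = 0.1` of samples on each
side, computed from per-subject log-rank (Nelson–Aalen) scores with
the permutation mean/variance standardization of maximally selected
rank statistics. Published cutoffs are scale-dependent and not
transferable, so cutoffs are always re-derived on the data at hand.
Finally `orient_score()` enforces the sign convention: if the
high-score group fares worse on the training data (KM median, or
restricted mean when a median is undefined), scores, loadings and
cutoff are all negated so that a low m6A score marks poor prognosis.

## Survival statistics

Standard machinery is delegated to the survival package behind the
module surface: `survfit` (log-log median CIs, Greenwood errors),
`survdiff` (log-rank), `coxph` (Efron ties, Wald inference;
non-convergence is flagged, never silently returned). The
time-dependent ROC is the cumulative-case / dynamic-control AUC with
inverse-probability-of-censoring weights from the Kaplan–Meier
estimate of the censoring distribution: cases observed by horizon t
weigh 1/G(T−), controls beyond t weigh 1/G(t), and the AUC is the
weighted concordant-pair fraction (ties count 1/2). This IPCW
estimator was chosen over the retrospective conditional-KM variant
because it is exactly reproducible by direct pair enumeration, which
is how the tests verify it. Binary ROC/AUC is concordant-pair counting
(equal to Mann–Whitney U/(n1·n0)); rank-sum tests are exact for up to
10 untied observations per group, normal-approximated with tie
correction otherwise.

## Gene-set scoring

Per-sample scores use the ssGSEA form: genes ranked within a sample,
integrated difference between the rank-weighted (rank^0.25) in-set
ECDF and the out-of-set ECDF, finally scaled by the overall score
range. This deliberately replaces the KS-of-KDE GSVA estimator: the
scores are only used to compare pathway activity between groups, which
the simpler rank statistic supports, and being rank-based it is
invariant to monotone per-sample transformations. A constant-expression
sample carries no ranking information and scores 0 by definition.

Two-group GSEA ranks genes by signal-to-noise, uses the weighted KS
running-sum score (weight exponent 1, verified against
`fgsea::calcGseaStat`), and draws significance from phenotype
permutation: NES = ES / mean |same-sign permutation ES|, nominal p =
same-sign tail fraction with the +1 floor. Significance defaults to
|NES| > 1 and p < 0.05. Groups smaller than 3 fall back to gene-set
permutation with a warning.

The TIS score is the per-sample mean of log10 expression over an
18-gene panel supplied by the user (the panel is configuration, not a
package constant). The default pseudocount is 0 — the score's
defining arithmetic maps an expression of 10 to exactly 1 — with a
positive pseudocount available for data containing zeros. Immune
infiltration uses user-supplied marker sets through the same ssGSEA
scorer, reported against the m6A score by Spearman correlation and
Wilcoxon group tests; this marker-set scoring is generic plumbing, not
a reimplementation of deconvolution web services.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with the generating truth recorded separately from the
observables so no stage can leak it:

* per-gene baseline on a log2-like scale: gene means drawn from
  N(8, 0.5), within-cluster noise SD 1 (so shifts are in SD units);
* a fair-coin latent cluster per sample; cluster B adds
  `cluster_shift` to every regulator and DEG gene independently (no
  shared continuous factor — a shared factor would leave residual
  overlap between clusters that no number of genes can remove, making
  exact recovery of clean two-blob structure impossible); the recorded
  latent score is the centered cluster indicator times the shift;
* additive per-cohort batch offsets `batch_shift * (b − 1)` on all
  genes;
* exponential survival with hazard
  `baseline_hazard * hazard_ratio_true^(cluster == A)` (cluster A is
  the low-expression, poor-prognosis cluster) and independent
  exponential censoring whose rate is solved from the target censored
  fraction, the simplest mechanism with a controllable rate;
* `generate_response_cohort()` adds a binary response with
  P(response) = plogis(response_effect × standardized latent score) —
  negative effects emulate the observed direction (low score responds)
  — and a neoantigen burden correlated with the latent score at the
  sign of `neoantigen_cor` (negative by default);
* age/stage/LDH covariates are drawn independently of the truth; they
  exercise table plumbing, not confounding.

Defaults (150 samples × 3 cohorts, 2000 genes, 200 DEGs, shift 2 SD,
batch shift 1 SD, true HR 2, baseline hazard 0.08/year, 30%
censoring) were chosen once as a realistic multi-cohort expression
study of a few hundred patients with ~10-year median survival; none of
the distributional details (variances, censoring fraction) are taken
from any particular dataset, and passing tests on these cohorts shows
the machinery recovers known structure — it does not validate the
biology of any real cohort, where effects are weaker, batch effects
non-additive, hazards non-proportional and expression non-Gaussian.

## Problem sizes and numerical choices

The test and acceptance workloads run at deliberately desk-scale
sizes, chosen as the smallest problems that still make the properties
sharp: consensus k-selection over 100 seeds at 60–90 samples and
30–60 replicates; DE recall/FDR at 2000 genes with 100 samples per
group; Cox recovery at n = 400 over 100 replicates; the end-to-end
score recovery at n = 400 with 20 informative genes over 100
replicates; GSEA calibration over 200 random sets at 200
permutations. The EB iteration converges to a relative tolerance of
1e-10; trigamma inversion iterates Newton steps to 1e-10; k-means uses
20 restarts by default (fewer in the large repeated studies); ties in
k selection and in cutpoint scanning resolve to the smaller value /
first candidate deterministically. Every stochastic routine takes an
explicit seed and restores the caller's RNG state.

## Known limitations

* The generator's clusters are axis-aligned Gaussian blobs with
  independent genes; correlated co-expression modules would weaken the
  RF importance ranking in ways these tests do not measure.
* PAC-based k selection inherits PAC's insensitivity to stable-but-
  wrong merges on highly symmetric data (see above).
* The published 20-gene signature and its cutoff cannot be reproduced
  without the original cohorts; this package reproduces the
  *procedure*, and all quantitative claims are about recovery of
  simulated truth.
* TIDE scoring and deconvolution-based infiltration estimates are
  external web services and are out of scope; marker-set ssGSEA is the
  in-package stand-in.
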