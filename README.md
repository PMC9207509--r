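# m6ascore

Consensus clustering and prognostic scoring of m6A-regulator expression
signatures in bulk tumor transcriptomes.

N6-methyladenosine (m6A) is the most common mRNA modification; its level
in a tumor tracks the expression of a 16-gene panel of regulator genes —
eight methyltransferase *writers* (WTAP, RBM15, RBM15B, ZC3H13, METTL3,
METTL14, KIAA1429, CBLL1), seven effector *readers* (HNRNPC, HNRNPA2B1,
YTHDC1, YTHDF2, IGF2BP1, ELAVL1, LRPPRC) and the demethylase *eraser*
ALKBH5. `m6ascore` turns that panel into a per-patient prognostic score
for survival cohorts (designed around follicular lymphoma expression
studies, applicable to any gene-by-sample log-expression matrix):

1. **Merge & batch-correct** cohorts with a parametric empirical-Bayes
   location–scale adjustment (`combat_adjust`).
2. **Consensus-cluster** patients on the z-scored regulator panel with
   resampled k-means (`consensus_cluster`), pick k by minimum PAC
   (`select_k`), and name the poor-prognosis cluster "A"
   (`label_m6a_clusters`).
3. **Differential expression** between the two clusters with a
   moderated t-statistic, BH-adjusted p < 0.01 (`moderated_de`).
4. **Trim** the DEG list by random-forest permutation importance
   (`rf_redundancy_filter`) and univariate Cox significance
   (`cox_univariate_filter`).
5. **Score**: PCA over the surviving genes; the m6A score of patient
   *i* is the sum of the first two principal-component sample scores,

   score(i) = z_i' v1 + z_i' v2,

   where z_i is the patient's z-scored signature-gene vector and v1,
   v2 the frozen unit-norm loadings (`fit_signature`,
   `score_samples`). Patients split at the maximally selected log-rank
   cutpoint (`optimal_cutoff`), with the sign convention that a **low
   score marks poor prognosis** (`orient_score`).
6. **Characterize**: Kaplan–Meier, log-rank, multivariate Cox,
   IPCW time-dependent ROC (`km_fit`, `logrank_test`, `cox_fit`,
   `time_roc`), ssGSEA/GSEA gene-set scoring (`ssgsea_score`,
   `gsea_two_group`), the 18-gene tumor-inflammation signature
   (`tis_score`), marker-set immune scoring
   (`immune_marker_scores`), and immunotherapy-response ROC
   (`binary_roc`).

A synthetic-cohort generator with recorded ground truth
(`simulation_config`, `generate_cohort`, `generate_response_cohort`)
emulates the statistical structure the pipeline assumes — two latent
regulator-driven clusters, a block of cluster-differential genes,
additive cohort batch effects, cluster-dependent proportional hazards
with censoring, and score-dependent response — so every stage is tested
against known truth. See `vignettes/m6a-scoring-methods.Rmd` for the
model details and design choices.

## Worked example

Simulate a three-cohort study (100 patients per cohort, 400 genes of
which 76 regulator/DEG genes differ between clusters by 2 SD, batch
shift 1 SD, true hazard ratio 2, 30% censoring) and run the full
pipeline:

```r
library(m6ascore)

cfg <- pipeline_config(
  simulation = simulation_config(
    n_samples = 100, n_cohorts = 3, n_genes = 400, n_deg = 60,
    cluster_shift = 2, batch_shift = 1, hazard_ratio_true = 2, seed = 1),
  k_max = 6, reps = 100, seed = 2)
res <- run_pipeline(cfg)
```

The summary prints:

```
chosen k:              2   (PAC at k=2: 0.000)
DEGs (adj p < 0.01):   76
signature genes:       27
score cutoff:          -1.597
median OS low score:   5.01 years (n=152)
median OS high score:  9.22 years (n=148)
log-rank p:            3.43e-09
Cox HR (low vs high):  2.39
AUC at 5/10/15 years:  0.59 / 0.64 / 0.66
```

Reading these numbers: consensus clustering finds exactly two fully
stable clusters (PAC 0); differential expression recovers all 76
truly shifted genes; after random-forest and Cox trimming, 27 genes
carry the PCA score. After orientation, the low-score half of the
cohort has roughly half the median survival of the high-score half
(5.0 vs 9.2 years), the score group is a strong independent risk
factor in a multivariate Cox model with age and stage (HR 2.39), and
the score discriminates 5/10/15-year survival with AUCs around
0.6–0.66 — the expected magnitudes given the simulated effect sizes.

Marker-set immune scoring works on any GMT
(`inst/extdata/synthetic_immune_markers.gmt` ships a tiny synthetic
example over the simulator's gene namespace); note that rank-based
per-sample scores of gene sets *outside* the signature necessarily
shift opposite to the signature genes, so interpret marker
associations jointly, not in isolation.

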