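# tmephenotyper

Immune phenotyping of the breast tumor microenvironment (TME) from bulk
gene expression, as a tested, reusable R pipeline.

Large multi-cohort analyses of breast cancer transcriptomes score each
tumor for immune and stromal cell-type activity, group tumors into
**Hot** (immune-infiltrated), **Moderate** (immune-excluded) and
**Cold** (immune-desert) phenotypes, relate those phenotypes to
ancestry, age, stage, intrinsic subtype and survival, classify the
fibroblast compartment into normal fibroblasts (NF), inflammatory CAFs
(iCAF) and myofibroblast-like CAFs (myCAF), and follow phenotype
transitions across neoadjuvant treatment. `tmephenotyper` implements
that entire workflow for anyone who wants to run, audit or extend it:
computational biologists with their own expression matrices, and
methodologists who want the statistical machinery with planted-truth
validation.

## What it computes

* **Single-sample enrichment scores.** For gene set *S* in an
  *N*-gene matrix, each gene gets a cross-sample CDF statistic
  (Gaussian kernel with bandwidth *s*/4 for continuous data, empirical
  CDF for counts); genes are ranked per sample, weighted by the
  symmetric rank statistic |*N*/2 − *r*|, and a weighted
  Kolmogorov–Smirnov random walk yields an enrichment score
  ES ∈ [−1, 1] (maximum positive plus minimum negative deviation).
  Sixteen immune and two stromal cell-type sets plus their immune
  union (`Immune_Score`) are scored.
* **Immune phenotype assignment.** Row-scaled scores, k-means
  (k-means++ seeding, Lloyd, 25 restarts), cluster number by a
  silhouette / Calinski–Harabasz / Davies–Bouldin majority vote,
  clusters named Hot/Moderate/Cold by mean overall immune score.
* **Immune–stromal ratio.** immune ES / (endothelial ES + fibroblast
  ES), with degenerate denominators flagged.
* **Fibroblast subtypes.** Per-gene z-scoring of fixed NF/iCAF/myCAF
  marker panels (39 distinct genes), seeded k-means (seed 123, k = 3),
  cluster annotation from marker subsets (e.g. the cluster with the
  highest mean POSTN/ACTA2/MMP11/TAGLN z becomes myCAF).
* **Survival.** Kaplan–Meier, log-rank, maximally selected log-rank
  cutpoints (minprop 0.1), multivariable Cox with Efron ties.
* **Association.** Chi-square (Yates for 2×2), one-way ANOVA, pairwise
  Wilcoxon with Benjamini–Hochberg adjustment, one-vs-rest logistic
  regression (references: European, age <40, stage I, LumA), balanced
  stratified subsampling.
* **Treatment response.** 3×3 phenotype (or fibroblast) transition
  tables with conserved row sums, per-patient ΔES between timepoints,
  response-group comparisons (ypCR / ypPR / ypSD).
* **Synthetic cohorts.** A generator that plants all of the above
  structure (phenotype-graded immune shifts, stromal shifts, marker
  panels, immune-linked hazards, Markov phenotype transitions) so the
  pipeline is fully testable without downloads.

## Worked example

```r
library(tmephenotyper)

co  <- generate_cohort(cohort_config(n_samples = 120, n_genes = 600, seed = 42))
es  <- gsva_scores(co$expression, co$gene_sets)
fit <- immune_phenotype(es, k = 3, seed = 1)
print(fit)
#> Immune phenotype fit (k = 3 , seed = 1 )
#>
#>     Cold      Hot Moderate
#>       42       37       41
#> Cluster mean overall immune score:
#>      Hot Moderate     Cold
#>    0.408   -0.022   -0.370
```

The fitted object labels each of the 120 samples; the cluster mean
overall immune scores are ordered Hot > Moderate > Cold by
construction, and on this synthetic cohort the gap between Hot (0.41)
and Cold (−0.37) reflects the planted +1.5 log-unit immune shift.

```r
fc <- classify_fibroblasts(co$expression)   # seed 123
print(fc)
#> Fibroblast subtype call (seed = 123 )
#>
#>  iCAF myCAF    NF
#>    41    37    42

rec <- generate_survival(co$truth, co$config$survival, seed = 42)
cut <- optimal_cutpoint(rec$time, rec$event,
                        unname(overall_immune_score(es)),
                        variable = "immune score")
print(cut)
#> Optimal cutpoint for immune score: 0.05095 (|standardized log-rank| = 4.084, 95 candidates, minprop 0.10)
#>
#> high  low
#>   42   78
```

The cutpoint dichotomises the immune score where the standardized
log-rank statistic between the resulting groups is largest: here 0.051,
|z| = 4.08, reflecting the planted hazard ratio of 2 per immune unit
(higher immune score, higher hazard in this simulation — the sign of
the planted effect, not a biological claim). `run_pipeline()` chains
all stages (simulate/load → score → phenotype → fibroblast → ratio →
survival → association → transitions) and writes one TSV per stage plus
a manifest with every seed and a parameter hash.

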