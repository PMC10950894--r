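# omixtwas

Multi-omic transcriptome-wide association and mediation analysis with
epigenome-informed expression models, in R.

## The problem

Genome-wide association studies of complex traits such as blood pressure
flag thousands of variants but rarely name the effector gene or the
tissue where it acts. A tissue-level answer needs a chain of methods:
models that impute **genetically regulated expression (GReX)** from cis
genotypes, **TWAS** that tests imputed expression against GWAS summary
statistics, replication across independent cohorts, **Mendelian
randomization (MR)** to separate causal effects from confounding and
pleiotropy, **mediation** to route gene effects through molecular
intermediates, and **fine-mapping** to pick the causal gene among
correlated neighbours. `omixtwas` implements that whole chain for
analysts working with expression panels, epigenomic/3D-genome annotation
(BED intervals), GWAS summary statistics and a reference LD panel — plus
a synthetic-data generator with planted truth so the pipeline can be
validated end to end without restricted data.

## The models at the core

**GReX training.** For expression residuals $E$, annotated ("essential")
dosages $X_1$ and remaining dosages $X_2$, weights minimise

```
|| E - X1 b1 - X2 b2 ||^2  +  (1/2)(lambda/2) (phi ||b1||^2 + ||b2||^2)
                           +  (1/2) lambda   (phi ||b1||_1 + ||b2||_1)
```

with `phi <= 1` relaxing the penalty on epigenomically annotated
variants. The cis window `w` (TAD, loop-anchor union, ±1 Mb, ±250 kb) is
tuned jointly with `(lambda, phi)` by nested cross-validation; models are
retained when the outer-fold correlation exceeds 0.10 (p < 0.05) and
validated on an independent panel at r > 0.1.

**Summary-statistic TWAS.** `Z_g = sum_l w_l sigma_l z_l / sigma_g` with
`sigma_g^2 = w' D Sigma D w` from reference-panel LD, followed by
reciprocal two-cohort replication under Benjamini–Hochberg FDR with a
sign-consistency rule.

**MR and mediation.** LD-clumped cis instruments feed IVW (plain,
heterogeneity-penalized, correlated-instrument GLS) and MR-Egger; the
two-step mediation decomposition reports the indirect effect
`B_EM * B_MO`, the mediation proportion `MP = indirect / total`, and
delta-method standard errors. Conditional Z-scores
`(Z_gene - r Z_miRNA)/sqrt(1 - r^2)` test whether a host gene explains a
correlated feature's signal.

**Fine-mapping.** Exact spike-and-slab enumeration over causal gene
configurations yields per-gene posterior inclusion probabilities and a
95% credible set; genes in the set with PIP > 0.5 are retained.

## A worked example

```r
library(omixtwas)

cfg <- sim_config(n_genes = 3, n_train = 250, n_individuals_ref = 300,
                  n_cohort1 = 900, n_cohort2 = 900,
                  n_variants_per_locus = 30, h2_cis = 0.4,
                  alpha_grex_trait = 0.5, seed = 101)
res <- run_pipeline(pipeline_config(
  sim = cfg,
  train = train_config(lambda_n = 12, phi_grid = c(1, 0.25),
                       window_kinds = c("fixed_1mb", "fixed_250kb"),
                       outer_folds = 3, inner_folds = 3),
  n_holdout = 150))
res$funnel
#> # A tibble: 6 × 2
#>   stage                  count
#>   <chr>                  <int>
#> 1 genes_simulated            3
#> 2 models_retained            3
#> 3 models_validated           2
#> 4 genes_replicated           2
#> 5 genes_mr_passing           2
#> 6 genes_finemap_retained     2
res$mediation
#> <mediation_result> indirect 0.187 (se 0.03319); MP 0.6131 (se 0.1914)
```

All three planted genes train successfully (cv r ≈ 0.56–0.63); two clear
the independent-panel validation filter at this small holdout, and both
survive reciprocal TWAS replication and the MR causal gate. The mediation
step estimates a proportion of 0.61 (SE 0.19) against the planted
`MP = 0.5` — within one standard error at this cohort size. The funnel is
the desk-scale analogue of a real discovery funnel from trained models
down to fine-mapped causal genes. `tidy()`, `glance()` and `autoplot()`
methods summarise and plot every fitted object
(`tidy(res$models)`, `autoplot(res$finemap[[1]])`,
`plot_replication(res$replication)`).

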