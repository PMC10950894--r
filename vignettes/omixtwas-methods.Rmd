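---
title: "Models and methods behind omixtwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omixtwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixtwas)
```

# Overview

`omixtwas` implements a complete discovery chain for tissue-level
multi-omic trait genetics: genetically regulated expression (GReX) models
trained with an epigenome-informed differential penalty and 3D-genome-informed
candidate windows, summary-statistic transcriptome-wide association (TWAS)
against reference-panel linkage disequilibrium, reciprocal two-cohort
replication under false-discovery-rate control, tissue prioritisation,
two-sample Mendelian-randomization (MR) mediation, conditional Z-score
tests for correlated molecular features, and probabilistic gene-level
fine-mapping. A synthetic-data generator with planted truth makes every
stage testable end to end without any restricted human data.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where more
than one reasonable construction existed.

# The GReX model with a differential penalty

For a gene with expression residual vector $E$ across $n$ individuals,
cis dosages split into "essential" predictors $X_1$ (variants overlapping
any supplied epigenomic annotation track: H3K27ac, H3K4me3, DNase, CTCF)
and the remaining predictors $X_2$, the weights minimise

$$L(\beta_1, \beta_2; \lambda, \phi) =
  \lVert E - X_1\beta_1 - X_2\beta_2 \rVert_2^2
  + \tfrac12 \cdot \tfrac{\lambda}{2}\left(\phi\lVert\beta_1\rVert_2^2 +
    \lVert\beta_2\rVert_2^2\right)
  + \tfrac12 \lambda \left(\phi\lVert\beta_1\rVert_1 +
    \lVert\beta_2\rVert_1\right),$$

with $\phi \le 1$ so annotated variants are penalised no more than the
rest. The scaling constants are implemented exactly as written. Dividing
by $2n$ shows the $\phi = 1$ case is a conventional elastic net with
`alpha = 0.5` and `lambda_glmnet = lambda / (2n)`; for $\phi < 1$ the
penalty factor $\phi$ plays the role of a glmnet `penalty.factor` (after
compensating glmnet's internal rescaling of penalty factors to sum to the
number of variables). These mappings back the solver's oracle tests; the
solver itself is an independent cyclic coordinate descent in C++ with the
exact univariate update

$$\beta_j \leftarrow \frac{S\!\left(x_j^\top r_j,\; \lambda\,\mathrm{pf}_j/4\right)}
  {x_j^\top x_j + \lambda\,\mathrm{pf}_j/4},$$

warm starts along a decreasing $\lambda$ path, and an optional per-sweep
assertion that the objective never increases. Columns are standardized
internally; reported weights are on the dosage scale. The all-zero
solution obtains exactly when
$\lambda \ge \max_j 4\lvert x_j^\top E\rvert/\mathrm{pf}_j$, which anchors
the top of the default path: 50 values log-spaced over four decades below
that bound. The default $\phi$ grid is $\{1, 0.5, 0.25, 0.1\}$.

## Candidate windows

Four window kinds per gene, all half-open intervals on a 0-based
coordinate system (conversion to 1-based positions happens only at VCF
serialization):

* `fixed_250kb` and `fixed_1mb`, centred on the TSS;
* `tad`: the TAD containing the TSS, falling back to `fixed_1mb` when no
  TAD covers it;
* `loop`: the union of both anchors of every chromatin loop with either
  anchor overlapping `[TSS - 5 kb, TSS + 5 kb)`, plus the gene body, with
  the same fallback. The anchor-overlap rule is our choice; no standard
  gene-to-loop assignment convention exists.

## Nested cross-validation

Inner folds (default 5) select the $(\lambda, \phi, w)$ triple that
maximises the pooled out-of-fold prediction–observation correlation; ties
break toward larger $\lambda$, then larger $\phi$, then the window with
fewer variants — all three prefer the more parsimonious model. Outer folds
(default 5) produce an honest `cv_r` and a one-sided t-test `cv_p` from
predictions of models tuned without the held-out fold. A model is retained
only when `cv_r > 0.10` and `cv_p < 0.05`; final weights are refit on all
samples at the triple chosen by inner CV on the full data. Validation on
an independent panel declares a model validated when the Pearson
correlation between imputed and observed residual expression exceeds 0.1.

# Summary-statistic TWAS

With model weights $w$, per-variant GWAS z-scores $z_l$, reference-panel
dosage standard deviations $\sigma_l$ and correlation matrix $\Sigma$:

$$Z_g = \frac{\sum_l w_l \sigma_l z_l}{\sigma_g}, \qquad
  \sigma_g^2 = w^\top D \Sigma D w, \quad D = \mathrm{diag}(\sigma_l).$$

$\Sigma$ is stabilized as $(1-\varepsilon)\Sigma + \varepsilon I$ with
$\varepsilon = 0.05$ before the variance computation. Model variants
missing from the GWAS are dropped (never imputed) and the dropped fraction
reported. Reference-panel standard deviations are used throughout. An
optional interval filter (defaulting off; the human MHC would be
`chr6:28-34 Mb`) removes variants before association. The construction is
invariant to allele-coding flips and to rescaling all weights by a
positive constant; both invariances are asserted in tests, as is agreement
with individual-level GReX regression on synthetic cohorts.

Individual-level associations use OLS for quantitative traits (covariates
enter the model before the GReX term, so a GReX fully explained by
covariates is reported as a zero effect) and Jeffreys-penalized (Firth)
logistic regression for binary outcomes — Newton iterations with
step-halving on the penalized likelihood and a penalized likelihood-ratio
test, finite even under complete separation.

# Replication, loci and tissue ranking

Reciprocal replication treats each cohort in turn as discovery:
Benjamini–Hochberg FDR over the full per-trait feature set in the
discovery cohort, FDR recomputed over the followed-up subset only in the
replication cohort (the two-stage wording of the design), union over both
directions, and a strict sign-consistency requirement.

GWAS loci are sentinel variants padded by 1 Mb on both sides with
overlapping intervals merged (keeping the most significant sentinel);
features map to loci by TSS — a single-point rule that avoids double
assignment. Tissue prioritisation computes three metrics per tissue and
trait — the proportion of tested genes that are significant and mutually
independent (pairwise imputed-expression $R^2 < 0.05$ within 2 Mb, genes
further apart independent by definition, greedy pruning keeping the
largest $\lvert z\rvert$), the mean $z^2$ over that independent set, and
the count of significant genes outside all loci — and sums the three
per-metric ranks (average ranks on ties) across traits. Significance is
Bonferroni-corrected within each tissue. The greedy-by-$\lvert z\rvert$
pruning order is our choice, mirroring standard clumping conventions, and
metric 2 is computed over the independent subset.

# Mendelian randomization and mediation

Instruments are cis variants LD-clumped greedily by ascending p-value
(pairwise $r^2$ ceiling, default 0.5, with a p-value ceiling). Estimators:

* **IVW**: weighted regression of outcome on exposure effects through the
  origin, weights $1/\mathrm{se}^2_{\mathrm{out}}$. The penalized variant
  down-weights instrument $j$ by $\min(1, q_{0.95}/q_j)$ where $q_j$ is
  its Cochran-Q contribution and $q_{0.95}$ the 0.95 quantile of
  $\chi^2_1$ — a standard robust-IVW construction, adopted because the
  term "penalised IVW" fixes no unique formula.
* **Correlated-instrument forms**: generalized least squares with
  covariance $\mathrm{diag}(\mathrm{se})\,\Sigma\,\mathrm{diag}(\mathrm{se})$,
  with a light ridge rescue if the covariance is singular.
* **MR-Egger**: weighted regression with an intercept after orienting
  exposure effects non-negative; the intercept tests directional
  pleiotropy; standard errors carry a multiplicative random-effects scale
  floored at 1.

A causal call requires effect p < 0.05 and, when testable, Egger-intercept
p > 0.05.

Two-step mediation multiplies the exposure-to-mediator and
mediator-to-outcome estimates into the indirect effect,
$\mathrm{SE}_{\mathrm{ind}} = \sqrt{B_{EM}^2\mathrm{SE}_{MO}^2 +
B_{MO}^2\mathrm{SE}_{EM}^2}$, and divides by the total effect for the
mediation proportion, with
$\mathrm{SE}_{MP} = \lvert MP\rvert\sqrt{\mathrm{SE}_{\mathrm{ind}}^2/B_{\mathrm{ind}}^2 +
\mathrm{SE}_{\mathrm{tot}}^2/B_{\mathrm{tot}}^2}$ treating numerator and
denominator as independent — conservative, since no covariance is
estimable from two-sample summary data; Monte-Carlo calibration shows the
delta-method SE within 15% of the empirical SE at the tested
configuration. Per-step significance and pleiotropy gates are reported,
not silently enforced, and MP is undefined (flagged) when the total effect
is numerically zero.

The conditional Z-score for a gene given a correlated feature (e.g. a
host gene given its miRNA) is
$Z_{\mathrm{gene}\mid m} = (Z_{\mathrm{gene}} - r\,Z_m)/\sqrt{1 - r^2}$
with $r$ the Pearson correlation of the two imputed expression scores
across a reference panel; a mediation verdict requires
$\lvert r\rvert > 0.1$,
$\lvert Z_{\mathrm{gene}}\rvert > \lvert Z_{\mathrm{gene}\mid m}\rvert > 2$,
and sign agreement.

# Fine-mapping

Within a locus of $k$ genes with TWAS z-vector $z$ and predicted-expression
correlation $\Omega$ (ridge-regularized with $\varepsilon = 0.1$ and
rescaled to unit diagonal — finite-panel correlations are noisy), each
causal configuration $c$ has marginal likelihood

$$z \mid c \sim N\!\left(0,\; \Omega + n\sigma^2\,
  \Omega_{\cdot c}\Omega_{c\cdot}\right),$$

a spike-and-slab model with per-gene prior $1/k$ and prior effect scale
$n\sigma^2$ estimated as the locus mean $z^2$ excess over 1 (floored at
0). All $2^k$ configurations (null included) are enumerated exactly for
$k \le 20$ with log-sum-exp stabilization; a clearly-labelled per-gene
Bayes-factor approximation under a max-1-causal assumption serves larger
loci. PIPs are reported both null-inclusive (`pip`) and null-excluded
(`pip_norm`); the 95% credible set is built on the null-excluded scale
(the smallest PIP-ordered set reaching 0.95, ties added together), and
retention applies `pip > 0.5` on the null-inclusive scale by default with
a flag to switch — the published rule does not state which normalization
it used. Loci with a single signal are skipped: there is nothing to
disambiguate, and such genes pass through unchanged.

# Descriptive statistics

Tissue-specificity calls follow the fold-change scheme (fold 4):
`not_detected` when every tissue sits below the detection floor (default
linear abundance 2, i.e. log2 = 1), then `enriched` (top tissue at least
4x every other), `group_enriched` (a group of 2–5 tissues each at least 4x
every tissue outside), `enhanced` (top tissue at least 4x the cross-tissue
mean), else `low_specificity`. The precedence order follows the standard
tissue-atlas scheme. Transcriptome-complexity curves rank genes by
descending median abundance and accumulate their share of the total.
Enrichment tests: upper-tail hypergeometric over-representation (equal to
one-sided Fisher), one-sided two-sample Kolmogorov–Smirnov with the
caller declaring the shift direction, and permutation category enrichment
drawing same-size gene sets without replacement with
$p = (b + 1)/(m + 1)$ — the +1 floor avoids zero p-values where the plain
exceedance ratio would produce them.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with truth recorded for scoring:

* **Genotypes.** Variants live in loci of 4 Mb on a synthetic chromosome,
  grouped into LD blocks. Two latent Gaussian AR(1) haplotype chains per
  individual are thresholded at the block allele frequency; because
  thresholding attenuates correlation, the latent correlation is
  calibrated numerically (via the bivariate-normal orthant probability) so
  that the realised adjacent *dosage* correlation equals the configured
  `ld_decay_rho`. One allele frequency is drawn per block — for unequal
  frequencies the attainable dosage correlation is bounded well below 1,
  and tightly linked variants sharing a frequency is the realistic regime.
  Blocks are independent; loci are independent.
* **Expression.** Per gene, a small set of causal cis variants is drawn
  with odds multiplied by `essential_enrichment` for annotated variants;
  effect sizes are scaled so the genetic variance fraction equals
  `h2_cis`, with Gaussian noise making total variance 1.
* **Cohorts.** The trait is
  `direct * G + c * M + gamma * C + eps` with `G` the summed true genetic
  expression of causal genes, `M = G + W + e_m` the mediator (`W` a
  genetic score over a dedicated mediator locus outside every gene's cis
  window — without such mediator-specific instruments the
  mediator-to-outcome MR step would be confounded by the exposure path),
  and `C` a shared confound. Setting `c = MP * alpha` and
  `direct = (1 - MP) * alpha` makes the total exposure effect `alpha` and
  the mediated share exactly `MP` in expectation. Summary statistics come
  from actually regressing the simulated trait on each dosage, so
  summary-level and individual-level pipelines can be cross-checked.

Default scales are desk-sized analogues of the real study: a training
panel of 400 (hundreds of kidneys), a reference panel of 500 (a
1000-Genomes-like panel), cohorts of 2000 (stand-ins for the two
six-figure GWAS resources), `h2_cis = 0.3`, `maf in [0.05, 0.5]`,
`ld_decay_rho = 0.7`, 3 causal eQTLs per gene with 5-fold essential
enrichment, and `MP = 0.5`. What the generator does **not** emulate:
realistic human haplotype structure, sex chromosomes, imputation
uncertainty, population stratification beyond the single confound, or
cross-locus LD — so passing tests demonstrate correctness of the
machinery under the stated model, not robustness to every pathology of
real data.

# Problem sizes used in checks

The packaged checks run at sizes a single CPU handles comfortably, chosen
once: solver oracles on up to 6 variants; summary-vs-individual TWAS
agreement on 200 genes at cohort size 1000; null replication over 20
two-cohort simulations of 100 genes at cohort size 500; mediation
calibration over 200 summary-level replicates with 20 instruments;
fine-mapping exactness at up to 10 genes against a naive enumerator and
recovery over 60 planted loci of 3–6 genes. Planted fine-mapping signals
use a prior effect scale of $n\sigma^2 = 100$ (causal TWAS
$\lvert z\rvert \approx 10$), the power regime of a ~750,000-sample GWAS,
and predicted-expression correlations at typical $\lvert r\rvert \approx
0.3$; at materially weaker signal or near-duplicate expression models the
causal gene is not identifiable by any method and the posterior correctly
splits.

# Known limitations

* PEER-style latent-factor inference is replaced by an explicit covariate
  table (optionally including expression principal components); the
  published factor counts are tied to real cohort sizes.
* The gene-level causal screen uses the IVW + Egger family rather than a
  joint-likelihood pleiotropy model; outputs are labelled accordingly.
* The elastic-net/differential-penalty machinery covers linear Gaussian
  expression models only; no trans effects, rare-variant burdens or
  cross-ancestry portability.
* Drug-repurposing scoring, colocalisation and upstream sequence
  processing are out of scope; TADs, loops and annotation tracks are
  consumed as interval files.

# Example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 3, seed = 1)
study <- simulate_study(cfg)
models <- train_grex_models(study$train, study$expression,
                            study$annot$annotations, study$annot$windows,
                            train_config(lambda_n = 15,
                                         phi_grid = c(1, 0.25),
                                         outer_folds = 3, inner_folds = 3))
tidy(models)
ld <- ld_reference(study$reference)
twas1 <- twas_scan(models, study$gwas$cohort1, ld)
twas2 <- twas_scan(models, study$gwas$cohort2, ld)
reciprocal_replicate(twas1, twas2)
```

The single-command variant of the whole chain is `run_pipeline()`, whose
funnel output (models trained, validated, replicated, MR-passing,
fine-mapped) is the synthetic analogue of the published discovery funnel.
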