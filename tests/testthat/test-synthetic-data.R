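test_that("identical configs give byte-identical outputs", {
  cfg <- small_config(seed = 21)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$gwas$cohort1, s2$gwas$cohort1)
})

test_that("LD generator hits its adjacent-correlation target", {
  adjacent_r <- function(rho, seed) {
    cfg <- sim_config(n_genes = 2, n_variants_per_locus = 30,
                      ld_block_size = 10, ld_decay_rho = rho, seed = seed)
    g <- simulate_genotypes(cfg, n = 2000)
    v <- g$variants
    adj <- which(diff(v$block) == 0 & v$locus_id[-1] == v$locus_id[-nrow(v)])
    mean(vapply(adj, function(j) cor(g$dosages[, j], g$dosages[, j + 1]),
                numeric(1)))
  }
  expect_lt(abs(adjacent_r(0, 5)), 0.05)          # independence case
  expect_lt(abs(adjacent_r(0.9, 6) - 0.9), 0.05)  # strong-LD calibration
})

test_that("allele frequencies respect maf_range and dosages are 0..2", {
  cfg <- sim_config(n_genes = 3, maf_range = c(0.1, 0.4), seed = 9)
  g <- simulate_genotypes(cfg, n = 1500)
  af <- colMeans(g$dosages) / 2
  expect_true(all(g$dosages %in% 0:2))
  expect_true(all(af > 0.04 & af < 0.5))
})

test_that("invalid configurations error", {
  expect_error(sim_config(n_genes = 0), class = "omix_config_error")
  expect_error(sim_config(h2_cis = 1.3), class = "omix_config_error")
  expect_error(sim_config(ld_decay_rho = 1), class = "omix_config_error")
  expect_error(sim_config(maf_range = c(0.2, 0.6)),
               class = "omix_config_error")
})

test_that("fixed windows follow the +-250kb / +-1Mb arithmetic", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 500000L,
                          start = 500000L, end = 550000L, strand = "+")
  w <- build_windows(genes)
  w250 <- w[w$kind == "fixed_250kb", ]
  expect_equal(c(w250$start, w250$end), c(250000, 750000))
  w1m <- w[w$kind == "fixed_1mb", ]
  expect_equal(c(w1m$start, w1m$end), c(0, 1500000))
})

test_that("TAD windows contain the TSS; loop windows fall back to 1 Mb", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 500000L,
                          start = 500000L, end = 550000L, strand = "+")
  tads <- tibble::tibble(chrom = "chr1", start = 400000L, end = 900000L)
  w <- build_windows(genes, tads = tads, loops = NULL)
  wt <- w[w$kind == "tad", ]
  expect_equal(c(wt$start, wt$end), c(400000, 900000))
  # no loop anchor near the TSS -> fall back to the fixed_1mb window
  loops <- tibble::tibble(chrom = "chr1", a_start = 2e6, a_end = 2.01e6,
                          b_start = 3e6, b_end = 3.01e6)
  wl <- build_windows(genes, loops = loops)
  wl <- wl[wl$kind == "loop", ]
  expect_equal(c(wl$start, wl$end), c(0, 1500000))
  # a TSS-anchored loop contributes both anchors plus the gene body
  loops2 <- tibble::tibble(chrom = "chr1", a_start = 497000L,
                           a_end = 503000L, b_start = 800000L,
                           b_end = 810000L)
  wl2 <- build_windows(genes, loops = loops2)
  wl2 <- wl2[wl2$kind == "loop", ]
  expect_equal(nrow(wl2), 3)
  expect_true(any(wl2$start == 800000))
})

test_that("planted cis heritability is recovered by an oracle regression", {
  cfg <- sim_config(n_genes = 4, n_train = 1000, h2_cis = 0.5, seed = 31)
  g <- simulate_genotypes(cfg, n = 1000)
  ann <- simulate_annotations_and_windows(cfg, g)
  ex <- simulate_expression(g, ann, cfg)
  r2 <- vapply(names(ex$truth$causal_variants), function(gn) {
    X <- g$dosages[, ex$truth$causal_variants[[gn]], drop = FALSE]
    summary(lm(ex$expression[gn, ] ~ X))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.05)
})

test_that("h2_cis = 0 gives expression independent of genotype", {
  cfg <- sim_config(n_genes = 2, h2_cis = 0, seed = 13)
  g <- simulate_genotypes(cfg, n = 500)
  ann <- simulate_annotations_and_windows(cfg, g)
  ex <- simulate_expression(g, ann, cfg)
  r2 <- vapply(names(ex$truth$causal_variants), function(gn) {
    X <- g$dosages[, ex$truth$causal_variants[[gn]], drop = FALSE]
    summary(lm(ex$expression[gn, ] ~ X))$r.squared
  }, numeric(1))
  expect_true(all(r2 < 0.05))
})

test_that("causal draws are uniform over annotation when enrichment is 1", {
  # pool causal-vs-essential counts over replicate simulations
  ess_tab <- matrix(0, 2, 2)
  for (s in 1:25) {
    cfg <- sim_config(n_genes = 8, n_train = 60, essential_enrichment = 1,
                      n_causal_eqtl = 3, seed = 100 + s)
    g <- simulate_genotypes(cfg, n = 60)
    ann <- simulate_annotations_and_windows(cfg, g)
    ex <- simulate_expression(g, ann, cfg)
    ess <- flag_essential(g$variants, ann$annotations)
    caus <- g$variants$variant_id %in%
      unlist(ex$truth$causal_variants)
    ess_tab <- ess_tab + table(factor(caus, c(FALSE, TRUE)),
                               factor(ess, c(FALSE, TRUE)))
  }
  expect_gt(suppressWarnings(chisq.test(ess_tab)$p.value), 0.001)
})

test_that("enrichment > 1 concentrates causal variants in annotations", {
  cfg <- sim_config(n_genes = 20, n_train = 60, essential_enrichment = 20,
                    n_causal_eqtl = 3, seed = 41)
  g <- simulate_genotypes(cfg, n = 60)
  ann <- simulate_annotations_and_windows(cfg, g)
  ex <- simulate_expression(g, ann, cfg)
  ess <- flag_essential(g$variants, ann$annotations)
  caus_ids <- unlist(ex$truth$causal_variants)
  frac_caus_ess <- mean(ess[match(caus_ids, g$variants$variant_id)])
  expect_gt(frac_caus_ess, mean(ess) + 0.15)
})

test_that("complete mediation removes the GReX effect after adjustment", {
  cfg <- sim_config(n_genes = 2, mediation_proportion_true = 1,
                    alpha_grex_trait = 0.5, n_cohort1 = 4000, seed = 51)
  st <- simulate_study(cfg, keep_individual = TRUE)
  ind <- st$gwas$individual$cohort1
  fit <- summary(lm(ind$trait ~ ind$grex_true + ind$mediator))
  expect_lt(abs(fit$coefficients["ind$grex_true", "Estimate"]), 0.08)
})

test_that("cohort z-scores agree for causal genes and not for null genes", {
  one <- function(i, alpha) {
    cfg <- sim_config(n_genes = 2, alpha_grex_trait = alpha,
                      n_cohort1 = 800, n_cohort2 = 800,
                      seed = 600 + i)
    st <- simulate_study(cfg)
    ld <- ld_reference(st$reference)
    wt <- truth_weights(st)
    c(twas_scan(wt, st$gwas$cohort1, ld)$z[1],
      twas_scan(wt, st$gwas$cohort2, ld)$z[1])
  }
  zc <- sapply(1:8, one, alpha = 0.4)
  z0 <- sapply(9:16, one, alpha = 0)
  # causal genes carry the same strong signal in both cohorts
  expect_gt(mean(sign(zc[1, ]) == sign(zc[2, ])), 0.8)
  expect_gt(mean(abs(zc)), 2)
  # pooled causal + null replicates: clearly positive cross-cohort r
  both <- cbind(zc, z0)
  expect_gt(cor(both[1, ], both[2, ]), 0.3)
  # null genes alone show no systematic signal
  expect_lt(mean(abs(z0)), 1.5)
})

test_that("two-step MR on the generator's summary stats recovers true MP", {
  cfg <- sim_config(n_genes = 2, n_cohort1 = 8000, n_cohort2 = 500,
                    n_train = 300, alpha_grex_trait = 0.5,
                    mediation_proportion_true = 0.5, seed = 71)
  st <- simulate_study(cfg)
  ld <- ld_reference(st$reference)
  g <- st$truth$causal_genes[1]
  gm <- st$genes[st$genes$gene_id == g, ]
  expr <- st$expression[g, ]
  eq <- cis_eqtl_scan(expr, st$train, gm)
  cl <- ld_clump(eq, ld, p_max = 1e-3, r2_max = 0.3)
  i_em <- instrument_set(cl, st$gwas$mediator, ld = ld)
  i_eo <- instrument_set(cl, st$gwas$cohort1, ld = ld)
  med_ids <- st$gwas$mediator_instruments$variant_id
  med_stats <- st$gwas$mediator[st$gwas$mediator$variant_id %in% med_ids, ]
  i_mo <- instrument_set(med_stats, st$gwas$cohort1, ld = ld)
  m <- two_step_mediation(mr_ivw(i_em, penalized = TRUE),
                          mr_ivw(i_mo, penalized = TRUE),
                          mr_ivw(i_eo, penalized = TRUE))
  expect_lt(abs(m$MP - 0.5), 0.12)
})
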