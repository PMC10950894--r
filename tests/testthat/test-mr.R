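make_instr <- function(bx, by, sx = NULL, sy = NULL, S = NULL) {
  structure(list(variant_id = paste0("v", seq_along(bx)),
                 beta_exposure = bx,
                 se_exposure = sx %||% rep(0.05, length(bx)),
                 beta_outcome = by,
                 se_outcome = sy %||% rep(0.05, length(bx)),
                 correlation = S),
            class = "instrument_set")
}

test_that("LD clumping keeps the strongest of correlated variants", {
  set.seed(1)
  x <- rbinom(400, 2, 0.3)
  dos <- cbind(v1 = x, v2 = x, v3 = rbinom(400, 2, 0.3))
  v <- tibble::tibble(variant_id = c("v1", "v2", "v3"), chrom = "chr1",
                      pos = 1:3 * 1000L, a1 = "A", a2 = "G")
  ld <- ld_reference(omixtwas:::new_geno_(dos, v))
  eq <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                       beta = c(.5, .5, .2), se = .1,
                       p = c(1e-8, 2e-8, 1e-4))
  kept <- ld_clump(eq, ld, p_max = 1e-3, r2_max = 0.5)
  expect_setequal(kept$variant_id, c("v1", "v3"))  # v2 is r2=1 with v1
  # mutually independent variants all kept
  set.seed(2)
  dos2 <- sapply(1:5, function(i) rbinom(400, 2, 0.3))
  colnames(dos2) <- paste0("w", 1:5)
  v2 <- tibble::tibble(variant_id = paste0("w", 1:5), chrom = "chr1",
                       pos = 1:5 * 1000L, a1 = "A", a2 = "G")
  ld2 <- ld_reference(omixtwas:::new_geno_(dos2, v2))
  eq2 <- tibble::tibble(variant_id = paste0("w", 1:5), beta = .3, se = .1,
                        p = rep(1e-6, 5))
  expect_equal(nrow(ld_clump(eq2, ld2, 1e-3, 0.5)), 5)
  expect_error(ld_clump(eq2[0, ], ld2, 1e-3, 0.5),
               class = "omix_no_instruments")
})

test_that("greedy clumping equals brute-force evaluation of the rule", {
  set.seed(3)
  n <- 500
  L <- matrix(rnorm(100), 10, 10)
  Z <- matrix(rnorm(n * 10), n, 10) %*% L     # correlated dosenoise
  dos <- apply(Z, 2, function(c) as.numeric(cut(c, 3)) - 1)
  colnames(dos) <- paste0("v", 1:10)
  v <- tibble::tibble(variant_id = paste0("v", 1:10), chrom = "chr1",
                      pos = 1:10 * 100L, a1 = "A", a2 = "G")
  ld <- ld_reference(omixtwas:::new_geno_(dos, v))
  eq <- tibble::tibble(variant_id = paste0("v", 1:10), beta = .2, se = .05,
                       p = runif(10) * 1e-4)
  got <- ld_clump(eq, ld, p_max = 1e-3, r2_max = 0.3)$variant_id
  # brute force: walk the p-sorted list applying the rule literally
  S <- ld_cor(ld, eq$variant_id[order(eq$p)])
  keep <- c()
  for (i in seq_len(10)) {
    if (length(keep) == 0 || all(S[i, keep]^2 < 0.3)) keep <- c(keep, i)
  }
  expect_equal(got, eq$variant_id[order(eq$p)][keep])
})

test_that("IVW reduces to the Wald ratio and the homogeneous case", {
  one <- make_instr(0.4, 0.2, sx = 0.01, sy = 0.05)
  r <- mr_ivw(one)
  expect_equal(r$estimate, 0.5, tolerance = 1e-12)
  expect_equal(r$se, 0.05 / 0.4, tolerance = 1e-12)  # delta method
  # identical ratios: estimate = b, penalization changes nothing
  bx <- c(0.2, 0.3, 0.5); by <- 0.7 * bx
  hom <- make_instr(bx, by)
  expect_equal(mr_ivw(hom)$estimate, 0.7, tolerance = 1e-12)
  expect_equal(mr_ivw(hom, penalized = TRUE)$estimate, 0.7,
               tolerance = 1e-12)
})

test_that("IVW with identity correlation equals uncorrelated IVW", {
  set.seed(4)
  bx <- runif(8, 0.1, 0.5); by <- 0.5 * bx + rnorm(8, sd = 0.03)
  i1 <- make_instr(bx, by)
  i2 <- make_instr(bx, by, S = diag(8))
  r1 <- mr_ivw(i1)
  r2 <- mr_ivw(i2, use_correlation = TRUE)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
})

test_that("IVW recovers a planted causal effect", {
  set.seed(5)
  ests <- replicate(200, {
    bx <- runif(20, 0.1, 0.6)
    sx <- rep(0.01, 20); sy <- rep(0.02, 20)
    by <- 0.5 * (bx + rnorm(20, sd = sx)) + rnorm(20, sd = sy)
    mr_ivw(make_instr(bx, by, sx, sy))$estimate
  })
  expect_lt(abs(mean(ests) - 0.5), 0.03)
})

test_that("MR-Egger detects planted directional pleiotropy", {
  set.seed(6)
  bx <- runif(30, 0.1, 0.6)
  by <- 0.4 * bx + 0.1 + rnorm(30, sd = 0.02)   # +0.1 on every outcome
  r <- mr_egger(make_instr(bx, by, sy = rep(0.02, 30)))
  expect_lt(abs(r$egger_intercept - 0.1), 0.03)
  expect_lt(r$egger_intercept_p, 0.05)
  expect_lt(abs(r$estimate - 0.4), 0.1)
  # identical exposure betas -> inestimable slope
  expect_error(mr_egger(make_instr(rep(0.3, 5), rnorm(5))),
               "inestimable")
  expect_error(mr_egger(make_instr(c(.1, .2), c(.1, .2))), "at least 3")
})

test_that("Egger intercept test is calibrated under no pleiotropy", {
  set.seed(7)
  ps <- replicate(400, {
    bx <- runif(15, 0.1, 0.6)
    by <- 0.4 * bx + rnorm(15, sd = 0.02)
    mr_egger(make_instr(bx, by, sy = rep(0.02, 15)))$egger_intercept_p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("mediation arithmetic and delta-method SEs are exact", {
  em <- make_instr(0.4, 0.4)  # unused inputs; construct results directly
  r_em <- omixtwas:::new_mr_result_(1, 0.1, "ivw", 5)
  r_mo <- omixtwas:::new_mr_result_(0.5, 0.05, "ivw", 5)
  r_eo <- omixtwas:::new_mr_result_(1, 0.1, "ivw", 5)
  m <- two_step_mediation(r_em, r_mo, r_eo)
  expect_equal(m$B_indirect, 0.5, tolerance = 1e-12)
  expect_equal(m$MP, 0.5, tolerance = 1e-12)
  expect_equal(m$SE_indirect,
               sqrt(1^2 * 0.05^2 + 0.5^2 * 0.1^2), tolerance = 1e-12)
  expect_equal(m$SE_MP,
               abs(m$MP) * sqrt(m$SE_indirect^2 / m$B_indirect^2 +
                                  0.1^2 / 1^2), tolerance = 1e-12)
  # zero SEs propagate to zero indirect SE
  r0a <- omixtwas:::new_mr_result_(1, 1e-300, "ivw", 5)
  r0b <- omixtwas:::new_mr_result_(0.5, 1e-300, "ivw", 5)
  m0 <- two_step_mediation(r0a, r0b, r_eo)
  expect_lt(m0$SE_indirect, 1e-290)
  # near-zero total effect flags MP undefined
  rz <- omixtwas:::new_mr_result_(0, 0.1, "ivw", 5)
  expect_warning(mz <- two_step_mediation(r_em, r_mo, rz), "undefined")
  expect_true(is.na(mz$MP))
})

test_that("noiseless decomposition returns the planted direct effect", {
  # B_total - B_indirect equals the direct path when inputs are exact
  r_em <- omixtwas:::new_mr_result_(0.8, 1e-12, "ivw", 5)
  r_mo <- omixtwas:::new_mr_result_(0.25, 1e-12, "ivw", 5)
  r_eo <- omixtwas:::new_mr_result_(0.5, 1e-12, "ivw", 5)
  m <- two_step_mediation(r_em, r_mo, r_eo)
  expect_equal(m$B_total - m$B_indirect, 0.5 - 0.2, tolerance = 1e-6)
})

test_that("conditional Z follows the closed form and the verdict rules", {
  # r = 0: identity, verdict negative by the |r| > 0.1 gate
  r0 <- conditional_z(3, 5, 0)
  expect_equal(r0$z_conditional, 3)
  expect_false(r0$mediation_verdict)
  # worked examples
  ex1 <- conditional_z(3, 5, 0.5)
  expect_equal(ex1$z_conditional, 0.5 / sqrt(0.75), tolerance = 1e-10)
  expect_false(ex1$mediation_verdict)           # |Z_cond| < 2
  ex2 <- conditional_z(5, 2, 0.3)
  expect_equal(ex2$z_conditional, (5 - 0.6) / sqrt(0.91), tolerance = 1e-10)
  expect_true(ex2$mediation_verdict)
  # sign flip of the conditional score breaks the verdict
  ex3 <- conditional_z(2.5, 9, 0.6)
  expect_lt(ex3$z_conditional, 0)
  expect_false(ex3$mediation_verdict)
  # continuous in r on (-1, 1): matches the closed form on a dense grid,
  # with step sizes shrinking proportionally to the grid spacing
  rs <- seq(-0.9, 0.9, 0.001)
  zc <- conditional_z(3, 2, rs)$z_conditional
  expect_equal(zc, (3 - rs * 2) / sqrt(1 - rs^2), tolerance = 1e-12)
  expect_lt(max(abs(diff(zc))), 0.06)
  expect_error(conditional_z(3, 2, 1), ">= 1")
})

test_that("genetic correlation of imputed features behaves correctly", {
  cfg <- sim_config(n_genes = 2, n_individuals_ref = 300, seed = 15)
  g <- simulate_genotypes(cfg, n = 300)
  w1 <- tibble::tibble(gene_id = "m1",
                       variant_id = g$variants$variant_id[1:3],
                       a1 = "A", a2 = "G", weight = c(0.5, -0.2, 0.1))
  expect_equal(grex_genetic_correlation(w1, w1, g), 1, tolerance = 1e-12)
  # disjoint variants in different loci: near-zero correlation
  ids2 <- g$variants$variant_id[g$variants$locus_id == "locus2"][1:3]
  w2 <- tibble::tibble(gene_id = "m2", variant_id = ids2,
                       a1 = "A", a2 = "G", weight = c(0.3, 0.3, 0.2))
  expect_lt(abs(grex_genetic_correlation(w1, w2, g)), 0.15)
  # analytic value from LD algebra for single-variant models
  wa <- tibble::tibble(gene_id = "a",
                       variant_id = g$variants$variant_id[1],
                       a1 = "A", a2 = "G", weight = 1)
  wb <- tibble::tibble(gene_id = "b",
                       variant_id = g$variants$variant_id[2],
                       a1 = "A", a2 = "G", weight = 1)
  r_emp <- grex_genetic_correlation(wa, wb, g)
  r_ld <- ld_cor(ld_reference(g), g$variants$variant_id[1:2])[1, 2]
  expect_equal(r_emp, r_ld, tolerance = 1e-10)
  # zero-variance score flagged
  wz <- dplyr::mutate(w1, weight = 0)
  expect_warning(rz <- grex_genetic_correlation(wz, w1, g),
                 "zero-variance")
  expect_true(is.na(rz))
})

test_that("two-step MR on summary statistics recovers the planted MP", {
  set.seed(16)
  k <- 20
  mps <- replicate(100, {
    bx <- runif(k, 0.2, 0.8)
    sx <- rep(0.01, k); s_m <- rep(0.02, k); s_o <- rep(0.02, k)
    # planted: EM = 1, MO = 0.25, direct = 0.25 => total 0.5, MP 0.5
    b_em <- 1 * bx + rnorm(k, sd = s_m)
    b_eo <- 0.5 * bx + rnorm(k, sd = s_o)
    b_m_obs <- b_em
    i_em <- make_instr(bx, b_m_obs, sx, s_m)
    i_eo <- make_instr(bx, b_eo, sx, s_o)
    # mediator -> outcome instruments: independent set
    bm <- runif(k, 0.2, 0.8)
    b_mo <- 0.25 * bm + rnorm(k, sd = s_o)
    i_mo <- make_instr(bm, b_mo, rep(0.01, k), s_o)
    two_step_mediation(mr_ivw(i_em), mr_ivw(i_mo), mr_ivw(i_eo))$MP
  })
  expect_lt(abs(mean(mps) - 0.5), 0.05)
})
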