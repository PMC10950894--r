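#' Greedy LD clumping of cis-eQTL instruments
#'
#' Variants are visited by ascending p-value; a variant is kept iff its
#' squared correlation with every previously kept variant is below
#' `r2_max`. Variants with `p > p_max` are never kept.
#'
#' @param eqtl Cis-eQTL summary tibble (`variant_id, beta, se, p`).
#' @param ld An `omix_ld`.
#' @param p_max Instrument p-value ceiling (e.g. 1e-3).
#' @param r2_max Pairwise LD ceiling (default 0.5).
#' @return The kept rows of `eqtl`, in p order; errors if empty.
#' @export
ld_clump <- function(eqtl, ld, p_max = 1e-3, r2_max = 0.5) {
  x <- eqtl |> filter(.data$p <= p_max) |> arrange(.data$p)
  if (nrow(x) == 0)
    abort("LD clumping produced no instruments; MR cannot run",
          class = "omix_no_instruments")
  S <- ld_cor(ld, x$variant_id)
  kept <- integer(0)
  for (i in seq_len(nrow(x))) {
    if (all(S[i, kept]^2 < r2_max)) kept <- c(kept, i)
  }
  x[kept, , drop = FALSE]
}

#' Assemble a harmonized instrument set
#'
#' @param exposure Exposure summary (`variant_id, a1, a2, beta, se`).
#' @param outcome Outcome summary (same dialect).
#' @param ld Optional `omix_ld` supplying the instrument correlation
#'   matrix.
#' @return List of class `instrument_set`: `variant_id, beta_exposure,
#'   se_exposure, beta_outcome, se_outcome, correlation` (NULL when `ld`
#'   not given).
#' @export
instrument_set <- function(exposure, outcome, ld = NULL) {
  h <- harmonize_alleles(
    select(exposure, "variant_id", "a1", "a2", "beta", "se"),
    select(outcome, "variant_id", "a1", "a2", "beta", "se"))
  if (nrow(h) == 0) abort("no harmonizable instruments")
  S <- if (!is.null(ld)) ld_cor(ld, h$variant_id) else NULL
  structure(list(variant_id = h$variant_id,
                 beta_exposure = h$beta, se_exposure = h$se,
                 beta_outcome = h$beta_b, se_outcome = h$se_b,
                 correlation = S),
            class = "instrument_set")
}

new_mr_result_ <- function(estimate, se, method, k,
                           egger_intercept = NA_real_,
                           egger_intercept_p = NA_real_) {
  z <- estimate / se
  p <- 2 * pnorm(-abs(z))
  pleio_tested <- is.finite(egger_intercept_p)
  structure(list(estimate = estimate, se = se, z = z, p = p,
                 method = method, n_instruments = k,
                 egger_intercept = egger_intercept,
                 egger_intercept_p = egger_intercept_p,
                 significant_causal = p < 0.05 &&
                   (!pleio_tested || egger_intercept_p > 0.05)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result> ", x$method, ": estimate ", signif(x$estimate, 4),
      " (se ", signif(x$se, 4), "), p ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_outcome^2`. The penalized variant
#' down-weights heterogeneous instruments by `w_j * min(1, q_crit / q_j)`
#' with `q_j` the instrument's Cochran-Q contribution and `q_crit` the 0.95
#' chi-square(1) quantile. With an instrument correlation matrix the
#' estimator is generalized least squares with covariance
#' `diag(se) S diag(se)`.
#'
#' @param instr An `instrument_set`.
#' @param penalized Apply heterogeneity penalization.
#' @param use_correlation Use the stored instrument correlation (GLS).
#' @return An `mr_result`.
#' @export
mr_ivw <- function(instr, penalized = FALSE, use_correlation = FALSE) {
  bx <- instr$beta_exposure; by <- instr$beta_outcome
  sy <- instr$se_outcome
  k <- length(bx)
  if (k < 1) abort("IVW needs at least one instrument")
  meth <- if (penalized) "ivw_penalized" else "ivw"
  if (use_correlation && !is.null(instr$correlation) && k > 1) {
    S <- instr$correlation
    O <- diag(sy) %*% S %*% diag(sy)
    Oi <- tryCatch(solve(O), error = function(e) {
      solve(0.95 * O + 0.05 * diag(diag(O)))
    })
    denom <- as.numeric(t(bx) %*% Oi %*% bx)
    est <- as.numeric(t(bx) %*% Oi %*% by) / denom
    se <- sqrt(1 / denom)
    return(new_mr_result_(est, se, paste0(meth, "_correlated"), k))
  }
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  if (penalized && k >= 2) {
    q <- w * (by - est * bx)^2
    w <- w * pmin(1, stats::qchisq(0.95, 1) / pmax(q, 1e-300))
    est <- sum(w * bx * by) / sum(w * bx^2)
  }
  se <- sqrt(1 / sum(w * bx^2))
  new_mr_result_(est, se, meth, k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept, after orienting all exposure effects non-negative; the
#' intercept tests directional horizontal pleiotropy. Standard errors use a
#' multiplicative random-effects scale floored at 1. The correlated form is
#' GLS with the instrument correlation.
#'
#' @param instr An `instrument_set` with at least 3 instruments.
#' @param use_correlation Use the stored instrument correlation.
#' @return An `mr_result` with `egger_intercept` and its p-value.
#' @export
mr_egger <- function(instr, use_correlation = FALSE) {
  k <- length(instr$beta_exposure)
  if (k < 3) abort("MR-Egger needs at least 3 instruments")
  flip <- sign(instr$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instr$beta_exposure * flip
  by <- instr$beta_outcome * flip
  sy <- instr$se_outcome
  if (sd(bx) == 0)
    abort("identical exposure effects: Egger slope is inestimable")
  X <- cbind(1, bx)
  if (use_correlation && !is.null(instr$correlation)) {
    S <- (instr$correlation * flip) * rep(flip, each = k)
    O <- diag(sy) %*% S %*% diag(sy)
    Oi <- solve(O)
    A <- solve(t(X) %*% Oi %*% X)
    est <- as.vector(A %*% t(X) %*% Oi %*% by)
    resid <- by - X %*% est
    scale2 <- max(1, as.numeric(t(resid) %*% Oi %*% resid) / (k - 2))
    V <- A * scale2
  } else {
    w <- 1 / sy^2
    A <- solve(crossprod(X, X * w))
    est <- as.vector(A %*% crossprod(X, w * by))
    resid <- by - X %*% est
    scale2 <- max(1, sum(w * resid^2) / (k - 2))
    V <- A * scale2
  }
  int_p <- 2 * pnorm(-abs(est[1] / sqrt(V[1, 1])))
  out <- new_mr_result_(est[2], sqrt(V[2, 2]),
                        if (use_correlation) "egger_correlated" else "egger",
                        k, egger_intercept = est[1],
                        egger_intercept_p = int_p)
  out
}

#' Two-step Mendelian-randomization mediation
#'
#' Combines three univariable MR analyses — exposure to mediator (EM),
#' mediator to outcome (MO) and exposure to outcome (EO, the total effect)
#' — into the mediation decomposition: indirect = B_EM * B_MO with
#' delta-method SE `sqrt(B_EM^2 SE_MO^2 + B_MO^2 SE_EM^2)`; mediation
#' proportion MP = indirect / total with its delta-method SE treating
#' numerator and denominator as independent. Per-step significance and
#' pleiotropy gates are reported, not silently enforced.
#'
#' @param mr_em,mr_mo,mr_eo `mr_result`s for the three steps.
#' @param egger_em,egger_mo,egger_eo Optional `mr_result`s from MR-Egger
#'   used to report the pleiotropy gate.
#' @return List of class `mediation_result` with `B_EM, SE_EM, B_MO, SE_MO,
#'   B_total, SE_total, B_indirect, SE_indirect, MP, SE_MP`, two-sided
#'   p-values, and the gate report.
#' @export
two_step_mediation <- function(mr_em, mr_mo, mr_eo,
                               egger_em = NULL, egger_mo = NULL,
                               egger_eo = NULL) {
  b_em <- mr_em$estimate; s_em <- mr_em$se
  b_mo <- mr_mo$estimate; s_mo <- mr_mo$se
  b_t <- mr_eo$estimate; s_t <- mr_eo$se
  b_ind <- b_em * b_mo
  s_ind <- sqrt(b_em^2 * s_mo^2 + b_mo^2 * s_em^2)
  if (abs(b_t) < 1e-12) {
    mp <- NA_real_; s_mp <- NA_real_
    warn("total effect is ~0: mediation proportion undefined")
  } else {
    mp <- b_ind / b_t
    s_mp <- abs(mp) * sqrt(ifelse(b_ind == 0, 0, s_ind^2 / b_ind^2) +
                             s_t^2 / b_t^2)
  }
  gates <- tibble(
    step = c("EM", "MO", "EO"),
    estimate_p = c(mr_em$p, mr_mo$p, mr_eo$p),
    pleiotropy_p = c(egger_em$egger_intercept_p %||% NA_real_,
                     egger_mo$egger_intercept_p %||% NA_real_,
                     egger_eo$egger_intercept_p %||% NA_real_)) |>
    mutate(passes = .data$estimate_p < 0.05 &
             (is.na(.data$pleiotropy_p) | .data$pleiotropy_p > 0.05))
  structure(list(B_EM = b_em, SE_EM = s_em, B_MO = b_mo, SE_MO = s_mo,
                 B_total = b_t, SE_total = s_t,
                 B_indirect = b_ind, SE_indirect = s_ind,
                 MP = mp, SE_MP = s_mp,
                 p_indirect = 2 * pnorm(-abs(b_ind / max(s_ind, 1e-300))),
                 p_MP = if (is.na(mp)) NA_real_ else
                   2 * pnorm(-abs(mp / max(s_mp, 1e-300))),
                 gates = gates),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> indirect ", signif(x$B_indirect, 4), " (se ",
      signif(x$SE_indirect, 4), "); MP ", signif(x$MP, 4), " (se ",
      signif(x$SE_MP, 4), ")\n", sep = "")
  invisible(x)
}

#' Conditional Z-score of a gene given a correlated feature
#'
#' \deqn{Z_{gene|m} = (Z_{gene} - r Z_m) / \sqrt{1 - r^2}}
#' Mediation verdict: significant iff `|r| > 0.1`,
#' `|Z_gene| > |Z_cond| > 2`, and `sign(Z_cond) == sign(Z_gene)`.
#'
#' @param z_gene,z_mirna TWAS z-scores for the gene and the conditioning
#'   feature (e.g. a miRNA).
#' @param r Cis-regulated genetic correlation in (-1, 1); `|r| >= 1`
#'   errors.
#' @return Tibble `z_conditional, mediation_verdict` plus the inputs.
#' @export
conditional_z <- function(z_gene, z_mirna, r) {
  if (any(abs(r) >= 1))
    abort("|r| >= 1 is degenerate for the conditional Z computation")
  z_cond <- (z_gene - r * z_mirna) / sqrt(1 - r^2)
  verdict <- abs(r) > 0.1 & abs(z_gene) > abs(z_cond) & abs(z_cond) > 2 &
    sign(z_cond) == sign(z_gene)
  tibble(z_gene = z_gene, z_mirna = z_mirna, r = r,
         z_conditional = z_cond, mediation_verdict = verdict)
}

#' Cis genetic correlation of two imputed features
#'
#' Pearson correlation of the two imputed scores across a reference panel.
#'
#' @param model_a,model_b `grex_model`s or one-gene weight tibbles.
#' @param reference_geno Reference `omix_geno` (>= 100 samples
#'   recommended).
#' @return Correlation (NA with a warning when a score has zero variance).
#' @export
grex_genetic_correlation <- function(model_a, model_b, reference_geno) {
  wt <- function(m, tag) {
    if (inherits(m, "grex_model")) mutate(m$weights, gene_id = m$gene_id)
    else mutate(as_tibble(m), gene_id = unique(m$gene_id) %||% tag)
  }
  wa <- wt(model_a, "a"); wb <- wt(model_b, "b")
  wa$gene_id <- "feature_a"; wb$gene_id <- "feature_b"
  sc <- predict_grex(bind_rows(wa, wb), reference_geno)
  if (sd(sc[, 1], na.rm = TRUE) == 0 || sd(sc[, 2], na.rm = TRUE) == 0) {
    warn("zero-variance imputed score: genetic correlation undefined")
    return(NA_real_)
  }
  cor(sc[, 1], sc[, 2], use = "complete.obs")
}
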