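#' Build a reference LD panel
#'
#' Wraps a reference genotype panel for correlation look-ups: per-variant
#' dosage standard deviations and on-demand correlation sub-matrices.
#'
#' @param geno Reference `omix_geno`.
#' @return List of class `omix_ld` with `variants`, `sd`, and the dosage
#'   matrix for correlation queries.
#' @export
ld_reference <- function(geno) {
  stopifnot(inherits(geno, "omix_geno"))
  structure(list(variants = geno$variants,
                 sd = apply(geno$dosages, 2, sd),
                 dosages = geno$dosages),
            class = "omix_ld")
}

#' Correlation sub-matrix from a reference panel
#'
#' @param ld An `omix_ld`.
#' @param variant_ids Variants to correlate.
#' @param ridge Shrinkage toward the identity, `(1 - e) S + e I`
#'   (default 0, applied by callers as needed).
#' @return Correlation matrix with unit diagonal.
#' @export
ld_cor <- function(ld, variant_ids, ridge = 0) {
  idx <- match(variant_ids, ld$variants$variant_id)
  if (anyNA(idx))
    abort(paste0("variants absent from LD reference: ",
                 paste(variant_ids[is.na(idx)], collapse = ", ")))
  S <- suppressWarnings(cor(ld$dosages[, idx, drop = FALSE]))
  S[is.na(S)] <- 0
  diag(S) <- 1
  if (ridge > 0) {
    S <- (1 - ridge) * S + ridge * diag(nrow(S))
  }
  S
}

#' Summary-statistic TWAS for one gene
#'
#' Combines model weights with GWAS z-scores against reference LD:
#' \deqn{Z_g = \frac{\sum_l w_l \sigma_l z_l}{\sigma_g},\qquad
#'   \sigma_g^2 = w^\top D \Sigma D w,\; D = diag(\sigma_l)}
#' The LD matrix is stabilized as `(1 - e) S + e I` with `e = 0.05` before
#' the variance computation. Model variants absent from the GWAS (or the
#' reference) are dropped and counted.
#'
#' @param model A `grex_model` or a one-gene weight tibble.
#' @param gwas GWAS summary tibble (dialect of [read_gwas_tsv()]).
#' @param ld An `omix_ld`.
#' @param ridge LD stabilization weight (default 0.05).
#' @param mhc_exclude Optional `c(chrom, start_bp, end_bp)` interval whose
#'   variants are removed before association (e.g.
#'   `c("chr6", 28e6, 34e6)`).
#'
#' @return One-row tibble `feature_id, trait, cohort, z, p,
#'   effect_direction, n_variants_used, frac_dropped`.
#' @export
twas_summary <- function(model, gwas, ld, ridge = 0.05,
                         mhc_exclude = NULL) {
  w <- if (inherits(model, "grex_model")) {
    if (is.null(model$weights) || nrow(model$weights) == 0)
      abort("model has no weights")
    mutate(model$weights, gene_id = model$gene_id)
  } else as_tibble(model)
  gene <- w$gene_id[1]
  if (!is.null(mhc_exclude)) {
    v <- ld$variants[match(w$variant_id, ld$variants$variant_id), ]
    drop <- !is.na(v$chrom) & v$chrom == mhc_exclude[1] &
      v$pos >= as.numeric(mhc_exclude[2]) & v$pos <= as.numeric(mhc_exclude[3])
    w <- w[!drop, , drop = FALSE]
  }
  n_model <- nrow(w)
  h <- harmonize_alleles(select(w, "variant_id", "a1", "a2", "weight"),
                         select(gwas, "variant_id", "a1", "a2", "z"))
  h <- h[h$variant_id %in% ld$variants$variant_id, , drop = FALSE]
  if (nrow(h) == 0) abort("no model variants matched the GWAS/LD panel")
  S <- ld_cor(ld, h$variant_id, ridge = ridge)
  sig <- ld$sd[match(h$variant_id, ld$variants$variant_id)]
  num <- sum(h$weight * sig * h$z_b)
  var_g <- as.numeric(t(h$weight * sig) %*% S %*% (h$weight * sig))
  if (var_g <= 0) abort("non-positive model variance after regularization")
  z <- num / sqrt(var_g)
  tibble(feature_id = gene,
         trait = gwas$trait[1] %||% NA_character_,
         cohort = gwas$cohort[1] %||% NA_character_,
         z = z, p = 2 * pnorm(-abs(z)),
         effect_direction = sign(z),
         n_variants_used = nrow(h),
         frac_dropped = 1 - nrow(h) / n_model)
}

#' Summary-statistic TWAS over a model set
#'
#' @param models `grex_model_set` or weight table.
#' @inheritParams twas_summary
#' @param retained_only Restrict to retained models.
#' @return Tibble with one row per gene (genes with no usable variants are
#'   skipped with a warning).
#' @export
twas_scan <- function(models, gwas, ld, ridge = 0.05, mhc_exclude = NULL,
                      retained_only = TRUE) {
  wt <- if (is.data.frame(models)) models else
    weights_table(models, retained_only = retained_only)
  purrr::map_dfr(unique(wt$gene_id), function(g) {
    tryCatch(twas_summary(wt[wt$gene_id == g, ], gwas, ld, ridge,
                          mhc_exclude),
             error = function(e) {
               warn(paste0("twas_scan skipped ", g, ": ",
                           conditionMessage(e)))
               NULL
             })
  })
}

#' Individual-level GReX-phenotype association (linear)
#'
#' OLS of a quantitative phenotype on a GReX score with covariate
#' adjustment; collinear covariates are dropped with a warning.
#'
#' @param grex Per-sample GReX vector.
#' @param phenotype Quantitative phenotype vector.
#' @param covariates Optional data frame / matrix of covariates.
#' @return Tibble `estimate, se, z, p` (two-sided).
#' @export
grex_phenotype_linear <- function(grex, phenotype, covariates = NULL) {
  df <- if (is.null(covariates)) data.frame(.y = phenotype)
        else cbind(data.frame(.y = phenotype), as.data.frame(covariates))
  df$.g <- grex  # GReX enters last so covariates absorb shared signal
  fit <- lm(.y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) warn("collinear terms dropped from the adjustment model")
  if (is.na(cf[".g"])) {
    warn("GReX is collinear with the covariates; no effect attributable")
    return(tibble(estimate = 0, se = NA_real_, z = NA_real_, p = 1))
  }
  sm <- summary(fit)$coefficients
  est <- unname(sm[".g", ])
  tibble(estimate = est[1], se = est[2], z = est[3], p = est[4])
}

# Firth (Jeffreys-penalized) logistic log-likelihood and Newton solver.
firth_fit_ <- function(X, y, max_iter = 50, tol = 1e-8) {
  p_ <- ncol(X)
  beta <- rep(0, p_)
  loglik_pen <- function(beta) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    I <- crossprod(X, X * W)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * as.numeric(determinant(I, logarithm = TRUE)$modulus)
  }
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    I <- crossprod(X, XW)
    Iinv <- solve(I)
    # hat diagonal of the weighted design
    H <- rowSums((X %*% Iinv) * XW)
    U <- crossprod(X, y - mu + H * (0.5 - mu))
    step <- as.vector(Iinv %*% U)
    # step-halving on the penalized likelihood
    ll0 <- loglik_pen(beta)
    s <- 1
    repeat {
      beta_new <- beta + s * step
      if (loglik_pen(beta_new) >= ll0 - 1e-10 || s < 1e-4) break
      s <- s / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    trace <- c(trace, delta)
    if (delta < tol) {
      eta <- as.vector(X %*% beta)
      mu <- stats::plogis(eta)
      I <- crossprod(X, X * (mu * (1 - mu)))
      return(list(beta = beta, vcov = solve(I), converged = TRUE,
                  iterations = it, loglik = loglik_pen(beta),
                  loglik_fun = loglik_pen))
    }
  }
  abort(paste0("Firth logistic regression did not converge; step trace: ",
               paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))
}

#' Firth penalized logistic regression of disease status on GReX
#'
#' Jeffreys-prior penalized likelihood maximized by Newton iterations with
#' step-halving; finite estimates are returned even under complete
#' separation. The p-value is from the penalized likelihood-ratio test for
#' the GReX coefficient.
#'
#' @param grex Per-sample GReX vector.
#' @param status Binary outcome (0/1); at least one case and one control.
#' @param covariates Optional covariates.
#' @return Tibble `estimate, se, p` (`estimate` is the log-odds per unit
#'   GReX).
#' @export
grex_phenotype_firth <- function(grex, status, covariates = NULL) {
  y <- as.numeric(status)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    abort("status must contain at least one case and one control")
  Xc <- if (is.null(covariates)) NULL else
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                               drop = FALSE]
  X <- cbind(`(Intercept)` = 1, grex = grex, Xc)
  fit <- firth_fit_(X, y)
  # penalized LRT for the grex term
  X0 <- X[, colnames(X) != "grex", drop = FALSE]
  fit0 <- firth_fit_(X0, y)
  lrt <- 2 * as.numeric(fit$loglik - fit0$loglik)
  j <- which(colnames(X) == "grex")
  tibble(estimate = fit$beta[j], se = sqrt(fit$vcov[j, j]),
         p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE))
}

#' Cis-eQTL scan for one gene
#'
#' Simple regression of the residualized expression on each dosage within
#' `window_bp` of the TSS. Monomorphic variants are skipped.
#'
#' @param expression_residuals Named vector (by sample) or matrix row.
#' @param geno `omix_geno`.
#' @param gene_meta One-row tibble with `gene_id`, `chrom`, `tss`.
#' @param window_bp Cis window half-width (default 1e6).
#' @return Tibble `gene_id, variant_id, chrom, pos, a1, a2, beta, se, z, p,
#'   n`.
#' @export
cis_eqtl_scan <- function(expression_residuals, geno, gene_meta,
                          window_bp = 1e6) {
  y <- as.numeric(expression_residuals)
  v <- geno$variants
  sel <- which(v$chrom == gene_meta$chrom &
                 abs(v$pos - gene_meta$tss) <= window_bp)
  mono <- apply(geno$dosages[, sel, drop = FALSE], 2, sd) == 0
  if (any(mono))
    warn(paste0(sum(mono), " monomorphic variant(s) skipped"))
  sel <- sel[!mono]
  if (!length(sel)) return(tibble())
  out <- marginal_gwas_(geno$dosages[, sel, drop = FALSE], y,
                        trait_name = gene_meta$gene_id, cohort_name = "eqtl",
                        v[sel, ])
  out |> rename(gene_id = "trait") |> select(-"cohort")
}
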