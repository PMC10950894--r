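#' Fit the differential-penalty expression model at fixed tuning values
#'
#' Minimizes, by cyclic coordinate descent,
#' \deqn{||E - X_1 b_1 - X_2 b_2||_2^2
#'   + \tfrac{1}{2}\cdot\tfrac{\lambda}{2}(\phi ||b_1||_2^2 + ||b_2||_2^2)
#'   + \tfrac{1}{2}\lambda(\phi ||b_1||_1 + ||b_2||_1)}
#' where \eqn{X_1} are the "essential" (epigenomically annotated)
#' predictors and \eqn{X_2} the rest. With \eqn{\phi \le 1}, annotated
#' predictors are penalised no more than the others; at \eqn{\phi = 1} the
#' objective is an ordinary elastic net with L2 weight \eqn{\lambda/4} and
#' L1 weight \eqn{\lambda/2} (glmnet mapping: `alpha = 0.5`,
#' `lambda = lambda / (2 n)`).
#'
#' @param X Dosage matrix (samples x variants).
#' @param y Expression residual vector.
#' @param essential Logical vector over columns of `X`.
#' @param lambda Penalty strength (> 0, on the standardized scale).
#' @param phi Relative penalty on essential predictors, in (0, 1].
#' @param standardize Standardize columns to unit variance before fitting
#'   (the returned `weights` are always on the dosage scale).
#' @param tol Convergence tolerance on the largest standardized coefficient
#'   change per sweep.
#' @param max_iter Maximum sweeps; non-convergence is flagged.
#' @param check_objective Assert the objective is non-increasing each sweep.
#'
#' @return List with `beta_std` (standardized scale), `weights` (dosage
#'   scale), `intercept`, `objective`, `converged`, `iterations`.
#' @export
fit_pumice_single <- function(X, y, essential, lambda, phi = 1,
                              standardize = TRUE, tol = 1e-9,
                              max_iter = 100000L, check_objective = FALSE) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(essential) == ncol(X))
  if (phi <= 0 || phi > 1) abort("phi must be in (0, 1]")
  ym <- mean(y); yc <- y - ym
  xm <- colMeans(X)
  xs <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  pf <- ifelse(essential, phi, 1)
  fit <- .pumice_cd(Xs, yc, pf, lambda, rep(0, ncol(X)), tol,
                    as.integer(max_iter), check_objective)
  beta_std <- as.numeric(fit$beta)
  w <- beta_std / xs
  list(beta_std = beta_std, weights = w,
       intercept = ym - sum(w * xm),
       objective = fit$objective, converged = fit$converged,
       iterations = fit$iterations)
}

#' Smallest penalty with an all-zero solution
#'
#' From the subgradient condition, every coefficient is zero iff
#' `lambda >= max_j 4 |x_j' y| / pf_j` on the standardized scale.
#'
#' @inheritParams fit_pumice_single
#' @return The critical `lambda`.
#' @export
pumice_lambda_max <- function(X, y, essential, phi = 1) {
  X <- as.matrix(X)
  yc <- y - mean(y)
  xm <- colMeans(X); xs <- apply(X, 2, sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  pf <- ifelse(essential, phi, 1)
  max(4 * abs(crossprod(Xs, yc)) / pf)
}

# Pathwise fit over a decreasing lambda grid (standardized internally);
# returns dosage-scale weight matrix (variants x lambdas) plus intercepts.
pumice_path_ <- function(X, y, essential, phi, lambdas, tol = 1e-7,
                         max_iter = 100000L) {
  ym <- mean(y); yc <- y - ym
  xm <- colMeans(X); xs <- apply(X, 2, sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  pf <- ifelse(essential, phi, 1)
  B <- .pumice_cd_path(Xs, yc, pf, lambdas, tol, as.integer(max_iter))
  W <- B / xs
  list(weights = W, intercepts = ym - as.vector(crossprod(W, xm)))
}

#' Training configuration for GReX models
#'
#' @param lambda_n Number of penalty values on the log-spaced path.
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @param phi_grid Candidate relative penalties, each in (0, 1].
#' @param window_kinds Candidate cis-window kinds.
#' @param outer_folds,inner_folds Nested cross-validation folds.
#' @param seed Fold-assignment seed.
#' @param tol,max_iter Solver controls.
#' @return List of class `train_config`.
#' @export
train_config <- function(lambda_n = 50, lambda_min_ratio = 1e-4,
                         phi_grid = c(1, 0.5, 0.25, 0.1),
                         window_kinds = c("tad", "loop", "fixed_1mb",
                                          "fixed_250kb"),
                         outer_folds = 5, inner_folds = 5, seed = 1L,
                         tol = 1e-7, max_iter = 100000L) {
  if (any(phi_grid <= 0 | phi_grid > 1))
    abort("phi_grid values must be in (0, 1]")
  if (!length(phi_grid) || !lambda_n)
    abort("tuning grids must be non-empty")
  structure(list(lambda_n = as.integer(lambda_n),
                 lambda_min_ratio = lambda_min_ratio,
                 phi_grid = sort(phi_grid, decreasing = TRUE),
                 window_kinds = window_kinds,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "train_config")
}

# Variant columns of `geno` inside the gene's windows of one kind.
window_variants_ <- function(geno, windows, gene_id, kind) {
  w <- windows[windows$gene_id == gene_id & windows$kind == kind, ,
               drop = FALSE]
  if (!nrow(w)) return(integer(0))
  v <- geno$variants
  sel <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(w)))
    sel <- sel | (v$chrom == w$chrom[i] & w$start[i] <= v$pos - 1 &
                    v$pos - 1 < w$end[i])
  which(sel)
}

fold_ids_ <- function(n, k, seed) {
  with_seed_(seed, sample(rep_len(seq_len(k), n)))
}

# Inner-CV selection of (window, phi, lambda) maximizing out-of-fold r.
# Ties break toward larger lambda, then larger phi, then smaller window.
inner_select_ <- function(Xw, ess_w, y, config, seed) {
  folds <- fold_ids_(length(y), config$inner_folds, seed)
  width <- vapply(Xw, ncol, integer(1))  # parsimony proxy: variant count
  cand <- NULL
  for (w in names(Xw)) {
    X <- Xw[[w]]
    if (is.null(X) || ncol(X) == 0) next
    ess <- ess_w[[w]]
    for (phi in config$phi_grid) {
      lmax <- pumice_lambda_max(X, y, ess, phi)
      if (!is.finite(lmax) || lmax <= 0) next
      lambdas <- exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
                         length.out = config$lambda_n))
      pred <- matrix(NA_real_, length(y), length(lambdas))
      for (f in seq_len(config$inner_folds)) {
        tr <- folds != f
        if (sum(tr) < 3 || sum(!tr) < 1) next
        fit <- pumice_path_(X[tr, , drop = FALSE], y[tr], ess, phi,
                            lambdas, config$tol, config$max_iter)
        pred[!tr, ] <- X[!tr, , drop = FALSE] %*% fit$weights +
          rep(fit$intercepts, each = sum(!tr))
      }
      r <- suppressWarnings(apply(pred, 2, function(pz) {
        if (all(is.na(pz)) || sd(pz, na.rm = TRUE) == 0) return(NA_real_)
        cor(pz, y, use = "complete.obs")
      }))
      cand <- bind_rows(cand, tibble(window = w, phi = phi,
                                     lambda = lambdas, score = r,
                                     width = width[[w]]))
    }
  }
  if (is.null(cand) || all(is.na(cand$score))) return(NULL)
  cand <- cand[!is.na(cand$score), ]
  best <- max(cand$score)
  top <- cand[cand$score >= best - 1e-12, ]
  top <- top[order(-top$lambda, -top$phi, top$width), ]
  top[1, ]
}

#' Train one gene's GReX model by nested cross-validation
#'
#' Inner folds pick the (lambda, phi, window) triple maximizing the pooled
#' out-of-fold prediction-observation correlation; outer folds give an
#' honest `cv_r`/`cv_p` from predictions of models tuned without the
#' held-out fold. The model is retained iff `cv_r > 0.10` and one-sided
#' `cv_p < 0.05`; final weights are refit on all samples at the tuple
#' chosen by inner CV on the full data.
#'
#' @param gene_id Gene to train.
#' @param geno `omix_geno` training genotypes.
#' @param expression Named expression-residual vector (by sample) or a
#'   features x samples matrix containing `gene_id`.
#' @param annotations Annotation tibble (defines essential variants).
#' @param windows Window tibble from [build_windows()].
#' @param config A [train_config()].
#' @param method `"pumice"` (full grid) or `"elastic_net"` (phi fixed at 1,
#'   window fixed at `fixed_1mb`).
#'
#' @return A `grex_model` list (weights on the dosage scale, tuning
#'   choices, `cv_r`, `cv_p`, `retained`, `reason`).
#' @export
nested_cv_train <- function(gene_id, geno, expression, annotations, windows,
                            config = train_config(), method = "pumice") {
  y <- if (is.matrix(expression)) expression[gene_id, ] else expression
  y <- as.numeric(y)
  cfg <- config
  if (method == "elastic_net") {
    cfg$phi_grid <- 1
    cfg$window_kinds <- "fixed_1mb"
  }
  ess_all <- flag_essential(geno$variants, annotations)
  Xw <- list(); ess_w <- list()
  for (k in cfg$window_kinds) {
    idx <- window_variants_(geno, windows, gene_id, k)
    idx <- idx[apply(geno$dosages[, idx, drop = FALSE], 2, sd) > 0]
    if (length(idx)) {
      Xw[[k]] <- geno$dosages[, idx, drop = FALSE]
      ess_w[[k]] <- ess_all[idx]
    }
  }
  reject <- function(reason) structure(
    list(gene_id = gene_id, weights = NULL, method = method,
         retained = FALSE, reason = reason, cv_r = NA_real_,
         cv_p = NA_real_), class = "grex_model")
  if (!length(Xw)) return(reject("no variants in any candidate window"))
  # outer CV for honest performance
  outer <- fold_ids_(length(y), cfg$outer_folds, cfg$seed + 17L)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(cfg$outer_folds)) {
    tr <- outer != f
    sel <- inner_select_(lapply(Xw, function(X) X[tr, , drop = FALSE]),
                         ess_w, y[tr], cfg, cfg$seed + 100L + f)
    if (is.null(sel)) next
    X <- Xw[[sel$window]]
    fit <- fit_pumice_single(X[tr, , drop = FALSE], y[tr],
                             ess_w[[sel$window]], sel$lambda, sel$phi,
                             tol = cfg$tol, max_iter = cfg$max_iter)
    if (!fit$converged) next
    oof[!tr] <- X[!tr, , drop = FALSE] %*% fit$weights + fit$intercept
  }
  ok <- !is.na(oof)
  if (sum(ok) < 10 || sd(oof[ok]) == 0)
    return(reject("degenerate out-of-fold predictions"))
  cv_r <- cor(oof[ok], y[ok])
  df <- sum(ok) - 2
  tstat <- cv_r * sqrt(df / max(1 - cv_r^2, 1e-12))
  cv_p <- pt(tstat, df, lower.tail = FALSE)  # one-sided
  # final tuple + refit on all samples
  sel <- inner_select_(Xw, ess_w, y, cfg, cfg$seed + 7L)
  if (is.null(sel)) return(reject("inner CV produced no usable candidate"))
  X <- Xw[[sel$window]]
  fit <- fit_pumice_single(X, y, ess_w[[sel$window]], sel$lambda, sel$phi,
                           tol = cfg$tol, max_iter = cfg$max_iter)
  if (!fit$converged) return(reject("solver did not converge"))
  nz <- which(fit$weights != 0)
  v <- geno$variants[match(colnames(X), geno$variants$variant_id), ]
  weights <- tibble(variant_id = colnames(X)[nz],
                    a1 = v$a1[nz], a2 = v$a2[nz],
                    weight = fit$weights[nz],
                    essential = ess_w[[sel$window]][nz])
  retained <- length(nz) > 0 && cv_r > 0.10 && cv_p < 0.05
  structure(list(gene_id = gene_id, weights = weights,
                 intercept = fit$intercept,
                 chosen_lambda = sel$lambda, chosen_phi = sel$phi,
                 chosen_window = sel$window, cv_r = cv_r, cv_p = cv_p,
                 method = method, n_train = length(y),
                 retained = retained,
                 reason = if (retained) NA_character_ else
                   "failed cv_r/cv_p retention filter"),
            class = "grex_model")
}

#' Elastic-net baseline trainer
#'
#' Identical to [nested_cv_train()] with `phi` fixed at 1 and the window
#' fixed at `fixed_1mb` — the conventional cis elastic net.
#' @inheritParams nested_cv_train
#' @return A `grex_model`.
#' @export
fit_elastic_net_baseline <- function(gene_id, geno, expression, windows,
                                     config = train_config()) {
  nested_cv_train(gene_id, geno, expression,
                  annotations = NULL, windows = windows,
                  config = config, method = "elastic_net")
}

#' Train GReX models for many genes
#'
#' @inheritParams nested_cv_train
#' @param gene_ids Genes to train (default: all rows of `expression`).
#' @return A `grex_model_set` (list of `grex_model`s, named by gene).
#' @export
train_grex_models <- function(geno, expression, annotations, windows,
                              config = train_config(), method = "pumice",
                              gene_ids = rownames(expression)) {
  models <- purrr::map(gene_ids, function(g)
    nested_cv_train(g, geno, expression, annotations, windows, config,
                    method))
  names(models) <- gene_ids
  structure(models, class = "grex_model_set")
}

#' @export
print.grex_model <- function(x, ...) {
  cat("<grex_model> ", x$gene_id, " [", x$method, "] ",
      if (isTRUE(x$retained)) "retained" else paste0("rejected: ", x$reason),
      "\n", sep = "")
  if (!is.null(x$weights))
    cat("  ", nrow(x$weights), " weights; window ", x$chosen_window %||% "-",
        ", phi ", signif(x$chosen_phi %||% NA, 3), ", cv_r ",
        signif(x$cv_r, 3), "\n", sep = "")
  invisible(x)
}

#' Flatten a model set to the weight-database table
#'
#' @param models A `grex_model_set` (or list of `grex_model`s).
#' @param retained_only Keep only retained models (default TRUE).
#' @return Tibble `gene_id, variant_id, a1, a2, weight, essential, method,
#'   chosen_window, chosen_phi, chosen_lambda, cv_r, cv_p`.
#' @export
weights_table <- function(models, retained_only = TRUE) {
  purrr::map_dfr(models, function(m) {
    if (is.null(m$weights) || nrow(m$weights) == 0) return(NULL)
    if (retained_only && !isTRUE(m$retained)) return(NULL)
    mutate(m$weights, gene_id = m$gene_id, method = m$method,
           chosen_window = m$chosen_window, chosen_phi = m$chosen_phi,
           chosen_lambda = m$chosen_lambda, cv_r = m$cv_r, cv_p = m$cv_p) |>
      select("gene_id", dplyr::everything())
  })
}

#' Impute genetically regulated expression
#'
#' Applies model weights to dosages, harmonizing allele codings (a swapped
#' allele pair contributes `2 - dosage`).
#'
#' @param weights Weight tibble (as from [weights_table()]) or a
#'   `grex_model_set`.
#' @param geno Target `omix_geno`.
#' @return Samples x genes matrix of GReX scores; genes with no matching
#'   variants are all-NA columns.
#' @export
predict_grex <- function(weights, geno) {
  if (inherits(weights, "grex_model_set") || (is.list(weights) &&
      !is.data.frame(weights) && inherits(weights[[1]], "grex_model")))
    weights <- weights_table(weights, retained_only = FALSE)
  v <- geno$variants
  genes <- unique(weights$gene_id)
  out <- matrix(NA_real_, nrow(geno$dosages), length(genes),
                dimnames = list(geno$sample_ids, genes))
  for (g in genes) {
    w <- weights[weights$gene_id == g, ]
    idx <- match(w$variant_id, v$variant_id)
    keep <- !is.na(idx)
    if (!any(keep)) next
    w <- w[keep, ]; idx <- idx[keep]
    same <- toupper(w$a1) == toupper(v$a1[idx]) &
      toupper(w$a2) == toupper(v$a2[idx])
    swap <- toupper(w$a1) == toupper(v$a2[idx]) &
      toupper(w$a2) == toupper(v$a1[idx])
    use <- same | swap
    if (!any(use)) next
    d <- geno$dosages[, idx[use], drop = FALSE]
    d[, swap[use]] <- 2 - d[, swap[use]]
    out[, g] <- d %*% w$weight[use]
  }
  out
}

#' Validate GReX models on a holdout panel
#'
#' @param models `grex_model_set` or weight tibble.
#' @param holdout_geno Holdout `omix_geno` (samples disjoint from
#'   training).
#' @param holdout_expression Features x samples matrix of expression
#'   residuals.
#' @return Tibble `gene_id, holdout_r, holdout_p, validated` (validated iff
#'   `holdout_r > 0.1`); degenerate (zero-variance) predictions yield NA
#'   and `validated = FALSE`.
#' @export
validate_models <- function(models, holdout_geno, holdout_expression) {
  if (nrow(holdout_geno$dosages) < 3)
    abort("validation requires at least 3 holdout samples")
  grex <- predict_grex(models, holdout_geno)
  genes <- intersect(colnames(grex), rownames(holdout_expression))
  purrr::map_dfr(genes, function(g) {
    p <- grex[, g]; e <- holdout_expression[g, ]
    if (all(is.na(p)) || sd(p, na.rm = TRUE) == 0 || sd(e) == 0)
      return(tibble(gene_id = g, holdout_r = NA_real_,
                    holdout_p = NA_real_, validated = FALSE))
    ct <- cor.test(p, e)
    tibble(gene_id = g, holdout_r = unname(ct$estimate),
           holdout_p = ct$p.value,
           validated = unname(ct$estimate) > 0.1)
  })
}
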