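# Shared fixtures: small, fast configurations and truth-based model tables.

small_config <- function(seed = 11, ...) {
  sim_config(n_genes = 3, n_train = 250, n_individuals_ref = 300,
             n_cohort1 = 600, n_cohort2 = 600,
             n_variants_per_locus = 30, ld_block_size = 10,
             h2_cis = 0.4, seed = seed, ...)
}

fast_train_config <- function(seed = 1) {
  train_config(lambda_n = 15, phi_grid = c(1, 0.25),
               window_kinds = c("fixed_1mb", "fixed_250kb"),
               outer_folds = 3, inner_folds = 3, seed = seed)
}

# Weight table built from the planted truth: the "oracle" GReX models.
truth_weights <- function(sim) {
  purrr::map_dfr(names(sim$truth$eqtl_betas), function(g) {
    b <- sim$truth$eqtl_betas[[g]]
    v <- sim$train$variants[match(names(b), sim$train$variants$variant_id), ]
    tibble::tibble(gene_id = g, variant_id = names(b),
                   a1 = v$a1, a2 = v$a2, weight = unname(b))
  })
}

# Reference objective for the differential-penalty fit, evaluated directly.
pumice_objective_ref <- function(X, y, beta, essential, lambda, phi) {
  pf <- ifelse(essential, phi, 1)
  sum((y - X %*% beta)^2) +
    0.5 * (lambda / 2) * sum(pf * beta^2) +
    0.5 * lambda * sum(pf * abs(beta))
}

# Independent naive fine-mapping enumerator (kept deliberately simple and
# separate from the package implementation).
naive_finemap <- function(z, omega, n_sigma2, prior) {
  k <- length(z)
  dmv <- function(z, V) {
    -0.5 * (k * log(2 * pi) + determinant(V, TRUE)$modulus[1] +
              t(z) %*% solve(V) %*% z)
  }
  pips <- numeric(k); total <- 0; p_null <- NA
  posts <- numeric(2^k)
  for (code in 0:(2^k - 1)) {
    cc <- as.logical(bitwAnd(code, 2^(0:(k - 1))))
    V <- omega
    if (any(cc))
      V <- V + n_sigma2 * omega[, cc, drop = FALSE] %*%
        omega[cc, , drop = FALSE]
    lp <- as.numeric(dmv(z, V)) + sum(log(ifelse(cc, prior, 1 - prior)))
    posts[code + 1] <- lp
  }
  w <- exp(posts - max(posts)); w <- w / sum(w)
  for (code in 0:(2^k - 1)) {
    cc <- as.logical(bitwAnd(code, 2^(0:(k - 1))))
    pips[cc] <- pips[cc] + w[code + 1]
    if (!any(cc)) p_null <- w[code + 1]
  }
  list(pip = pips, p_null = p_null)
}

# Brute-force HWE exact test: enumerate all heterozygote counts.
hwe_brute <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hets, function(h) {
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
          lfactorial(hom_c) + h * log(2) + lfactorial(rare) +
          lfactorial(2 * n - rare) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == n_ab] * (1 + 1e-10)])
}

# Textbook step-up BH, written independently of the implementation.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
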