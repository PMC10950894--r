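#' Exact Hardy-Weinberg equilibrium test
#'
#' Wigginton-style exact test: the two-sided p-value is the summed
#' probability of all heterozygote counts (given the observed allele counts)
#' no more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom-ref, het, hom-alt).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab          # rarer allele recoded below
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  # all heterozygote counts compatible with the allele counts share parity
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  # log-probability of each het count under HWE given allele counts
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[match(het_obs, hets)] * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Filters variants by minor allele frequency, missingness and exact
#' Hardy-Weinberg equilibrium, preserving variant order. Fractional dosages
#' are rounded to hard calls for the HWE test only.
#'
#' @param geno An `omix_geno`.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param missing_max Maximum missingness rate (default 0.05).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-3).
#' @return A filtered `omix_geno`; warns (does not error) if nothing
#'   survives.
#' @export
variant_qc <- function(geno, maf_min = 0.05, missing_max = 0.05,
                       hwe_p_min = 1e-3) {
  stopifnot(inherits(geno, "omix_geno"))
  d <- geno$dosages
  miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    g <- round(d[, j]); g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  keep <- maf >= maf_min & miss <= missing_max & hwe >= hwe_p_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warn("variant_qc removed every variant")
  out <- geno
  out$dosages <- d[, keep, drop = FALSE]
  out$variants <- geno$variants[keep, , drop = FALSE]
  out
}

#' Filter features by expression evidence
#'
#' Keeps features whose abundance and read count both clear their thresholds
#' in at least `sample_frac` of samples; in miRNA mode features with an
#' interquartile range of zero are additionally removed.
#'
#' @param abundance Features x samples matrix (TPM or RPM).
#' @param counts Features x samples read-count matrix (same dimensions);
#'   required.
#' @param abundance_min Abundance threshold (exceed strictly; default 0.1).
#' @param count_min Read-count threshold (default 5; genes must exceed it
#'   strictly, miRNA mode requires `>=`).
#' @param sample_frac Minimum passing sample fraction (default 0.2 for
#'   genes; the miRNA convention is 0.1).
#' @param mirna_mode Apply miRNA rules (`count >= count_min`, IQR-0
#'   exclusion).
#' @return The filtered abundance matrix.
#' @export
filter_expressed <- function(abundance, counts, abundance_min = 0.1,
                             count_min = 5, sample_frac = 0.2,
                             mirna_mode = FALSE) {
  if (missing(counts) || is.null(counts))
    abort("filter_expressed requires a paired read-count matrix")
  stopifnot(all(dim(abundance) == dim(counts)))
  pass <- if (mirna_mode) (abundance > abundance_min) & (counts >= count_min)
          else (abundance > abundance_min) & (counts > count_min)
  frac <- rowMeans(pass)
  keep <- frac >= sample_frac
  if (mirna_mode) {
    iqr <- apply(abundance, 1, function(x) diff(quantile(x, c(.25, .75))))
    keep <- keep & iqr > 0
  }
  abundance[keep, , drop = FALSE]
}

# Rank-based inverse-normal transform with the Blom offset c = 3/8;
# ties get average ranks.
inverse_normal_ <- function(x, c_offset = 3 / 8) {
  r <- rank(x, ties.method = "average")
  qnorm((r - c_offset) / (length(x) + 1 - 2 * c_offset))
}

#' Normalize an expression matrix and residualize on covariates
#'
#' Per the standard pipeline: `log2(x + 1)`, cross-sample quantile
#' normalization to the mean empirical distribution, rank-based
#' inverse-normal transform per feature (Blom offset 3/8), then residuals
#' from a per-feature linear model on the covariates. Output features have
#' mean ~ 0.
#'
#' @param values Features x samples non-negative abundance matrix.
#' @param covariates Optional samples x covariates data frame / matrix.
#' @param log_transform,quantile_normalize,inverse_normal Toggles for the
#'   individual steps (all on by default).
#' @return Matrix of normalized residuals (features x samples). Constant
#'   features come back as zero rows with a warning.
#' @export
normalize_expression <- function(values, covariates = NULL,
                                 log_transform = TRUE,
                                 quantile_normalize = TRUE,
                                 inverse_normal = TRUE) {
  x <- as.matrix(values)
  if (log_transform) x <- log2(x + 1)
  if (quantile_normalize) {
    if (requireNamespace("limma", quietly = TRUE)) {
      x <- t(limma::normalizeQuantiles(t(x)))
    } else {
      # mean-of-sorted-values reference across samples
      ref <- rowMeans(apply(x, 2, sort))
      x <- apply(x, 2, function(col) {
        ref[rank(col, ties.method = "average")]
      }) |> matrix(nrow(values), ncol(values),
                   dimnames = dimnames(values))
    }
  }
  const <- apply(x, 1, function(r) sd(r) == 0 || !is.finite(sd(r)))
  if (any(const))
    warn(paste0(sum(const), " constant feature(s) set to zero"))
  out <- t(apply(x, 1, function(r) {
    if (sd(r) == 0 || !is.finite(sd(r))) return(rep(0, length(r)))
    if (inverse_normal) inverse_normal_(r) else r
  }))
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    qr_cm <- qr(cm)
    if (qr_cm$rank < ncol(cm))
      warn("collinear covariates dropped in residualization")
    out <- t(apply(out, 1, function(r) {
      if (all(r == 0)) return(r)
      as.vector(stats::lm.fit(cm, r)$residuals)
    }))
  }
  out <- out - rowMeans(out)
  dimnames(out) <- dimnames(values)
  out
}

#' Harmonize alleles between two summary tables
#'
#' Joins on `variant_id`; where the allele pair is swapped between the two
#' sides, the second side's effect columns are sign-flipped. Strand
#' ambiguous (A/T, C/G) variants and unmatched or allele-incompatible
#' records are dropped, with counts attached as attributes.
#'
#' @param a,b Tibbles each carrying `variant_id`, `a1`, `a2` plus effect
#'   columns.
#' @param flip_cols Columns of `b` to sign-flip on allele swap (default:
#'   any of beta, z, se is detected automatically; `se` is never flipped).
#' @return Joined tibble with `b`'s columns suffixed `_b` and signs
#'   corrected onto `a`'s allele coding; attributes `n_dropped_ambiguous`,
#'   `n_dropped_unmatched`, `n_flipped`.
#' @export
harmonize_alleles <- function(a, b, flip_cols = NULL) {
  if (anyDuplicated(a$variant_id) || anyDuplicated(b$variant_id))
    abort("duplicate variant ids are not allowed in harmonize_alleles")
  ambiguous <- function(x1, x2) {
    p <- paste0(toupper(x1), toupper(x2))
    p %in% c("AT", "TA", "CG", "GC")
  }
  amb_a <- ambiguous(a$a1, a$a2)
  amb_b <- ambiguous(b$a1, b$a2)
  a2 <- a[!amb_a, , drop = FALSE]
  b2 <- b[!amb_b, , drop = FALSE]
  names(b2)[names(b2) != "variant_id"] <-
    paste0(names(b2)[names(b2) != "variant_id"], "_b")
  j <- inner_join(a2, b2, by = "variant_id")
  if (nrow(j) == 0) {
    warn("harmonize_alleles: no variants matched")
  }
  same <- toupper(j$a1) == toupper(j$a1_b) & toupper(j$a2) == toupper(j$a2_b)
  swap <- toupper(j$a1) == toupper(j$a2_b) & toupper(j$a2) == toupper(j$a1_b)
  keep <- same | swap
  j <- j[keep, , drop = FALSE]
  swap <- swap[keep]
  if (is.null(flip_cols))
    flip_cols <- intersect(c("beta_b", "z_b", "weight_b"), names(j))
  for (cl in flip_cols) j[[cl]][swap] <- -j[[cl]][swap]
  j$allele_flipped <- swap
  attr(j, "n_dropped_ambiguous") <- sum(amb_a) + sum(amb_b)
  attr(j, "n_dropped_unmatched") <-
    (nrow(a2) - nrow(j)) + (nrow(b2) - nrow(j))
  attr(j, "n_flipped") <- sum(swap)
  j
}
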