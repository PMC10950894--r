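#' Classify tissue specificity of features
#'
#' Human-Protein-Atlas-style categories from a feature x tissue abundance
#' matrix (linear scale): `not_detected` when every tissue sits below the
#' detection threshold; `enriched` when one tissue is at least
#' `fold` times every other; `group_enriched` when a group of 2-5 tissues
#' is each at least `fold` times every tissue outside the group;
#' `enhanced` when one tissue is at least `fold` times the cross-tissue
#' mean; otherwise `low_specificity`. Calls are invariant to rescaling all
#' abundances by a positive constant only when `detect_threshold` is
#' rescaled too; the ratio rules themselves are scale-free.
#'
#' @param expr Feature x tissue abundance matrix (linear scale, e.g. RPM).
#' @param fold Fold-change defining enrichment (default 4).
#' @param detect_threshold Detection floor on the linear scale (default 2,
#'   i.e. log2 abundance of 1).
#' @return Tibble `feature_id, category, supporting_tissues`.
#' @export
classify_specificity <- function(expr, fold = 4, detect_threshold = 2) {
  if (ncol(expr) < 2) abort("specificity needs at least 2 tissues")
  tn <- colnames(expr) %||% paste0("tissue", seq_len(ncol(expr)))
  purrr::map_dfr(seq_len(nrow(expr)), function(i) {
    x <- as.numeric(expr[i, ])
    fid <- rownames(expr)[i] %||% paste0("feature", i)
    mk <- function(cat, sup) tibble(feature_id = fid, category = cat,
                                    supporting_tissues =
                                      paste(sup, collapse = ";"))
    if (all(x < detect_threshold)) return(mk("not_detected", character(0)))
    o <- order(x, decreasing = TRUE)
    xs <- x[o]
    if (xs[1] >= fold * xs[2]) return(mk("enriched", tn[o[1]]))
    for (g in 2:min(5, length(x) - 1)) {
      if (xs[g] >= fold * xs[g + 1]) return(mk("group_enriched", tn[o[1:g]]))
    }
    if (xs[1] >= fold * mean(x)) return(mk("enhanced", tn[o[1]]))
    mk("low_specificity", character(0))
  })
}

#' Transcriptome complexity curve
#'
#' Genes are ranked by descending median abundance; the curve is the
#' cumulative fraction of the (median-abundance) transcriptome carried by
#' the top-ranked genes. Non-decreasing and terminating at 1.
#'
#' @param expr Gene x sample non-negative abundance matrix.
#' @return List with `curve` (tibble `rank, gene_id, share, cumulative`)
#'   and `quartiles` (cumulative fractions at 25/50/75% of genes).
#' @export
complexity_curve <- function(expr) {
  med <- apply(expr, 1, median)
  if (all(med == 0)) abort("all-zero expression matrix")
  o <- order(med, decreasing = TRUE)
  share <- med[o] / sum(med)
  cum <- cumsum(share)
  g <- length(med)
  q <- vapply(c(0.25, 0.5, 0.75), function(f) cum[max(1, floor(f * g))],
              numeric(1))
  list(curve = tibble(rank = seq_len(g),
                      gene_id = (rownames(expr) %||%
                                   paste0("gene", seq_len(g)))[o],
                      share = share, cumulative = cum),
       quartiles = setNames(q, c("q25", "q50", "q75")))
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability of the observed overlap between a query hit list
#' and a gene set within a universe; the odds ratio comes from the 2x2
#' table.
#'
#' @param hits Query genes (subset of `universe`).
#' @param set Gene set (subset of `universe`).
#' @param universe Background gene identifiers.
#' @return Tibble `test, overlap, expected, odds_ratio, p`.
#' @export
ora_hypergeometric <- function(hits, set, universe) {
  if (length(universe) == 0) abort("empty universe")
  hits <- intersect(hits, universe)
  set <- intersect(set, universe)
  k <- length(intersect(hits, set))
  m <- length(set); n <- length(universe) - m; q <- length(hits)
  p <- phyper(k - 1, m, n, q, lower.tail = FALSE)
  a <- k; b <- q - k; cc <- m - k; d <- n - b
  or <- (a * d) / max(b * cc, .Machine$double.eps)
  tibble(test = "hypergeometric", overlap = k,
         expected = q * m / length(universe), odds_ratio = or, p = p)
}

#' One-sided two-sample Kolmogorov-Smirnov shift test
#'
#' Tests whether the class values are shifted relative to background
#' (`direction = "higher"` or `"lower"`); the statistic is the one-sided
#' supremum of the CDF difference with asymptotic p.
#'
#' @param values_in_class,values_background Numeric samples (>= 3 each).
#' @param direction `"higher"` or `"lower"` shift of the class relative to
#'   background; must be given.
#' @return Tibble `test, statistic, p, direction`.
#' @export
ks_shift_enrichment <- function(values_in_class, values_background,
                                direction = c("higher", "lower")) {
  if (length(direction) != 1 || !direction %in% c("higher", "lower"))
    abort("direction must be \"higher\" or \"lower\"")
  if (length(values_in_class) < 3 || length(values_background) < 3)
    abort("need at least 3 values per group")
  # R's two-sample alternative = "greater" tests CDF(class) > CDF(bg),
  # i.e. the class stochastically SMALLER; map directions accordingly.
  alt <- if (direction == "higher") "less" else "greater"
  kt <- suppressWarnings(ks.test(values_in_class, values_background,
                                 alternative = alt))
  tibble(test = "ks_one_sided", statistic = unname(kt$statistic),
         p = kt$p.value, direction = direction)
}

#' Permutation test for category enrichment in a query gene set
#'
#' For each category, the null distribution is the category count in
#' random same-size gene sets drawn without replacement from the universe;
#' the one-sided p is `(exceedances + 1) / (n_perm + 1)` (never below the
#' `1/(n_perm + 1)` floor).
#'
#' @param query_genes Query set (subset of `universe`).
#' @param category_assignment Named character vector: gene -> category.
#' @param universe Background genes.
#' @param n_perm Number of permutations (default 1e5).
#' @param seed RNG seed.
#' @param categories Categories to test (default: all observed).
#' @return Tibble `test, category, observed, null_mean, p, n_permutations`.
#' @export
permutation_category_enrichment <- function(query_genes,
                                            category_assignment, universe,
                                            n_perm = 100000, seed = 1L,
                                            categories = NULL) {
  query_genes <- intersect(query_genes, universe)
  cats <- categories %||% sort(unique(unname(category_assignment)))
  qn <- length(query_genes)
  cat_of <- category_assignment[universe]
  with_seed_(seed, {
    counts <- matrix(0L, n_perm, length(cats),
                     dimnames = list(NULL, cats))
    for (b in seq_len(n_perm)) {
      smp <- cat_of[sample.int(length(universe), qn)]
      tb <- table(factor(smp, levels = cats))
      counts[b, ] <- as.integer(tb)
    }
    obs <- table(factor(cat_of[match(query_genes, universe)], levels = cats))
    purrr::map_dfr(cats, function(cl) {
      in_universe <- any(cat_of == cl, na.rm = TRUE)
      if (!in_universe) {
        warn(paste0("category absent from universe: ", cl))
        return(tibble(test = "permutation", category = cl,
                      observed = 0L, null_mean = 0,
                      p = 1, n_permutations = n_perm))
      }
      o <- as.integer(obs[[cl]])
      exceed <- sum(counts[, cl] > o)   # strict exceedance, +1 floor
      tibble(test = "permutation", category = cl, observed = o,
             null_mean = mean(counts[, cl]),
             p = (exceed + 1) / (n_perm + 1), n_permutations = n_perm)
    })
  })
}
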