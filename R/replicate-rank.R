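#' Benjamini-Hochberg step-up q-values
#'
#' Order-preserving BH adjustment with enforced monotonicity (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values in `[0, 1]`; NA is an error.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) abort("bh_fdr: p-values must not be NA")
  if (any(p < 0 | p > 1)) abort("bh_fdr: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Reciprocal two-cohort replication
#'
#' Each cohort serves in turn as the discovery set: discovery FDR is
#' computed per trait over the full feature universe, significant features
#' are followed up in the other cohort with FDR recomputed on the
#' followed-up subset only, and the two discovery directions are unioned.
#' A feature is reported as replicated only when discovery and replication
#' q-values are both below the threshold and the association signs agree.
#'
#' @param results_c1,results_c2 TWAS result tibbles (`feature_id, trait, z,
#'   p`), one per cohort, covering the same features per trait.
#' @param fdr_threshold FDR level (default 0.05).
#' @return Tibble `feature_id, trait, z_cohort1, z_cohort2, q_c1_full,
#'   q_c2_full, q_c1_sub, q_c2_sub, discovered_in, direction_consistent,
#'   replicated`, with only replicated rows flagged `TRUE` retained in the
#'   `replicated` column sense; all followed-up rows are returned.
#' @export
reciprocal_replicate <- function(results_c1, results_c2,
                                 fdr_threshold = 0.05) {
  traits1 <- sort(unique(results_c1$trait))
  traits2 <- sort(unique(results_c2$trait))
  if (!identical(traits1, traits2))
    abort("cohorts cover different traits")
  purrr::map_dfr(traits1, function(tr) {
    a <- filter(results_c1, .data$trait == tr)
    b <- filter(results_c2, .data$trait == tr)
    j <- inner_join(select(a, "feature_id", z1 = "z", p1 = "p"),
                    select(b, "feature_id", z2 = "z", p2 = "p"),
                    by = "feature_id")
    j$q1_full <- bh_fdr(j$p1)
    j$q2_full <- bh_fdr(j$p2)
    disc1 <- j$q1_full < fdr_threshold
    disc2 <- j$q2_full < fdr_threshold
    j$q2_sub <- NA_real_
    if (any(disc1)) j$q2_sub[disc1] <- bh_fdr(j$p2[disc1])
    j$q1_sub <- NA_real_
    if (any(disc2)) j$q1_sub[disc2] <- bh_fdr(j$p1[disc2])
    dir_ok <- sign(j$z1) == sign(j$z2)
    rep1 <- disc1 & !is.na(j$q2_sub) & j$q2_sub < fdr_threshold & dir_ok
    rep2 <- disc2 & !is.na(j$q1_sub) & j$q1_sub < fdr_threshold & dir_ok
    sel <- disc1 | disc2
    if (!any(sel)) return(NULL)
    tibble(feature_id = j$feature_id[sel], trait = tr,
           z_cohort1 = j$z1[sel], z_cohort2 = j$z2[sel],
           q_c1_full = j$q1_full[sel], q_c2_full = j$q2_full[sel],
           q_c1_sub = j$q1_sub[sel], q_c2_sub = j$q2_sub[sel],
           discovered_in = dplyr::case_when(
             disc1[sel] & disc2[sel] ~ "both",
             disc1[sel] ~ "cohort1", TRUE ~ "cohort2"),
           direction_consistent = dir_ok[sel],
           replicated = (rep1 | rep2)[sel])
  })
}

#' Build merged GWAS loci from sentinel variants
#'
#' Each sentinel spawns a +-1 Mb interval; overlapping intervals are merged
#' and the most significant sentinel (smallest p, if given) labels the
#' merged locus. Merging is idempotent and order-independent.
#'
#' @param sentinels Tibble `variant_id, chrom, pos` and optionally `p`.
#' @param flank_bp Half-width (default 1e6).
#' @return Tibble `locus_id, chrom, start, end, sentinel` (0-based
#'   half-open intervals).
#' @export
build_locus_set <- function(sentinels, flank_bp = 1e6) {
  if (is.null(sentinels) || nrow(sentinels) == 0)
    return(tibble(locus_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  sentinel = character()))
  s <- sentinels |>
    mutate(start = pmax(0, .data$pos - 1 - flank_bp),
           end = .data$pos - 1 + flank_bp + 1,
           p_rank = if ("p" %in% names(sentinels)) .data$p else
             seq_len(nrow(sentinels))) |>
    arrange(.data$chrom, .data$start)
  out <- NULL
  for (ch in unique(s$chrom)) {
    x <- s[s$chrom == ch, ]
    cur_start <- x$start[1]; cur_end <- x$end[1]
    cur_best <- 1
    rows <- list()
    if (nrow(x) > 1) for (i in 2:nrow(x)) {
      if (x$start[i] <= cur_end) {
        cur_end <- max(cur_end, x$end[i])
        if (x$p_rank[i] < x$p_rank[cur_best]) cur_best <- i
      } else {
        rows[[length(rows) + 1]] <-
          tibble(chrom = ch, start = cur_start, end = cur_end,
                 sentinel = x$variant_id[cur_best])
        cur_start <- x$start[i]; cur_end <- x$end[i]; cur_best <- i
      }
    }
    rows[[length(rows) + 1]] <-
      tibble(chrom = ch, start = cur_start, end = cur_end,
             sentinel = x$variant_id[cur_best])
    out <- bind_rows(out, bind_rows(rows))
  }
  out |> arrange(.data$chrom, .data$start) |>
    mutate(locus_id = paste0("gwas_locus", row_number())) |>
    select("locus_id", "chrom", "start", "end", "sentinel")
}

#' Assign features to GWAS loci by TSS
#'
#' A feature belongs to the locus whose half-open interval contains its
#' TSS; features outside every locus are labelled novel.
#'
#' @param features Tibble `feature_id, chrom, tss`.
#' @param loci A locus set from [build_locus_set()].
#' @return `features` with `locus_id` (NA if outside) and `outside_loci`.
#' @export
map_features_to_loci <- function(features, loci) {
  assign_one <- function(ch, tss) {
    hit <- loci$locus_id[loci$chrom == ch & loci$start <= tss - 1 &
                           tss - 1 < loci$end]
    if (length(hit)) hit[1] else NA_character_
  }
  features |>
    mutate(locus_id = purrr::map2_chr(.data$chrom, .data$tss, assign_one),
           outside_loci = is.na(.data$locus_id))
}

# Greedy independence pruning: order by |z| descending; a gene is kept iff
# every kept gene is either > dist_bp away or has imputed-expression
# R^2 < r2_max with it. Genes further apart than dist_bp are independent
# by definition.
prune_independent_ <- function(genes, grex_cor = NULL, r2_max = 0.05,
                               dist_bp = 2e6) {
  if (nrow(genes) == 0) return(genes)
  g <- arrange(genes, desc(abs(.data$z)))
  kept <- integer(0)
  for (i in seq_len(nrow(g))) {
    ok <- TRUE
    for (k in kept) {
      near <- g$chrom[i] == g$chrom[k] && abs(g$tss[i] - g$tss[k]) <= dist_bp
      if (near) {
        r2 <- if (is.null(grex_cor)) 0 else {
          ids <- c(g$feature_id[i], g$feature_id[k])
          if (all(ids %in% rownames(grex_cor)))
            grex_cor[ids[1], ids[2]]^2 else 0
        }
        if (r2 >= r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  g[kept, , drop = FALSE]
}

#' Rank tissues by three TWAS-based relevance metrics
#'
#' Per tissue and trait: (1) the proportion of tested genes that are
#' significant and mutually independent (pairwise imputed-expression
#' R^2 < 0.05 within 2 Mb; farther genes independent by definition;
#' greedy pruning keeps the strongest |z|); (2) the mean squared z over the
#' independent significant genes; (3) the count of significant genes
#' outside the supplied GWAS loci. Tissues are ranked per metric (average
#' ranks on ties, best = largest value) and the overall score is the sum of
#' the three ranks, summed across traits. Significance is
#' Bonferroni-adjusted p < 0.05 within each tissue.
#'
#' @param results Tibble `tissue, trait, feature_id, chrom, tss, z, p` with
#'   one row per tested gene.
#' @param loci GWAS locus set from [build_locus_set()].
#' @param grex_cor Optional named list (by tissue) of gene-gene imputed
#'   expression correlation matrices; absent pairs are treated as
#'   independent.
#' @param alpha Bonferroni level (default 0.05).
#' @return Tibble with per-tissue per-trait metrics and ranks plus the
#'   cross-trait `overall_rank_score` (smaller = more relevant).
#' @export
rank_tissues <- function(results, loci, grex_cor = NULL, alpha = 0.05) {
  per <- results |> group_by(.data$tissue, .data$trait) |>
    dplyr::group_modify(function(d, key) {
      n_tested <- nrow(d)
      sig <- d[d$p < alpha / n_tested, , drop = FALSE]
      if (nrow(sig) == 0)
        return(tibble(prop_independent_genes = 0, mean_sq_z = 0,
                      n_outside_loci = 0, n_significant = 0))
      cm <- if (!is.null(grex_cor)) grex_cor[[key$tissue[1]]] else NULL
      ind <- prune_independent_(sig, cm)
      mapped <- map_features_to_loci(sig, loci)
      tibble(prop_independent_genes = nrow(ind) / n_tested,
             mean_sq_z = mean(ind$z^2),
             n_outside_loci = sum(mapped$outside_loci),
             n_significant = nrow(sig))
    }) |> ungroup()
  ranked <- per |> group_by(.data$trait) |>
    mutate(rank_prop = rank(-.data$prop_independent_genes),
           rank_meanz = rank(-.data$mean_sq_z),
           rank_outside = rank(-.data$n_outside_loci),
           rank_sum = .data$rank_prop + .data$rank_meanz +
             .data$rank_outside) |> ungroup()
  overall <- ranked |> group_by(.data$tissue) |>
    summarise(overall_rank_score = sum(.data$rank_sum), .groups = "drop")
  left_join(ranked, overall, by = "tissue") |>
    arrange(.data$overall_rank_score, .data$tissue)
}
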