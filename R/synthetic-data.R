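#' Simulation configuration for the synthetic multi-omic study
#'
#' Builds the configuration object that drives every synthetic-data
#' generator in the package. The defaults describe a desk-scale analogue of
#' a kidney multi-omic blood-pressure study: a few hundred expression-panel
#' samples, two GWAS cohorts of a few thousand individuals, block-structured
#' linkage disequilibrium, a sparse annotation-enriched cis-eQTL
#' architecture, and a molecular mediator carrying a stated fraction of the
#' expression-to-trait effect.
#'
#' @param n_individuals_ref Reference (LD) panel size.
#' @param n_train Expression training-panel size.
#' @param n_cohort1,n_cohort2 GWAS cohort sizes.
#' @param n_genes Number of genes.
#' @param genes_per_locus Genes sharing one fine-mapping locus (same variant
#'   panel); exactly one gene per locus is trait-causal when > 1.
#' @param n_variants_per_locus Variants per locus.
#' @param ld_block_size Variants per LD block.
#' @param ld_decay_rho Target adjacent-variant dosage correlation within a
#'   block, in `[0, 1)`; decays as `rho^distance` inside the block and is 0
#'   across blocks.
#' @param maf_range Minor-allele-frequency range, each in `(0, 0.5]`. One
#'   frequency is drawn per LD block (shared by its variants) so that the
#'   target dosage correlation is attainable.
#' @param n_causal_eqtl Causal cis variants per gene.
#' @param essential_enrichment Odds multiplier (>= 1) favouring annotated
#'   ("essential") variants when causal eQTLs are drawn.
#' @param h2_cis Cis heritability of expression in `[0, 1]`.
#' @param alpha_grex_trait Trait effect per unit of genetic expression.
#' @param mediation_proportion_true Fraction of the expression-to-trait
#'   effect routed through the mediator, in `[0, 1]`.
#' @param prop_causal Fraction of loci whose lead gene affects the trait.
#' @param confound_gamma Effect of the shared confound on the trait.
#' @param mediator_noise_sd Residual SD of the mediator.
#' @param seed Integer seed; fully determines all outputs.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals_ref = 500, n_train = 400,
                       n_cohort1 = 2000, n_cohort2 = 2000,
                       n_genes = 20, genes_per_locus = 1,
                       n_variants_per_locus = 60, ld_block_size = 10,
                       ld_decay_rho = 0.7, maf_range = c(0.05, 0.5),
                       n_causal_eqtl = 3, essential_enrichment = 5,
                       h2_cis = 0.3, alpha_grex_trait = 0.3,
                       mediation_proportion_true = 0.5, prop_causal = 1,
                       confound_gamma = 0.5, mediator_noise_sd = 1,
                       seed = 1L) {
  counts <- c(n_individuals_ref = n_individuals_ref, n_train = n_train,
              n_cohort1 = n_cohort1, n_cohort2 = n_cohort2,
              n_genes = n_genes, genes_per_locus = genes_per_locus,
              n_variants_per_locus = n_variants_per_locus,
              ld_block_size = ld_block_size, n_causal_eqtl = n_causal_eqtl)
  if (any(counts < 1))
    abort(paste0("all counts must be positive; offending: ",
                 paste(names(counts)[counts < 1], collapse = ", ")),
          class = "omix_config_error")
  if (ld_decay_rho < 0 || ld_decay_rho >= 1)
    abort("ld_decay_rho must be in [0, 1)", class = "omix_config_error")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    abort("maf_range must be two frequencies in (0, 0.5]",
          class = "omix_config_error")
  if (h2_cis < 0 || h2_cis > 1)
    abort("h2_cis must be in [0, 1]", class = "omix_config_error")
  if (mediation_proportion_true < 0 || mediation_proportion_true > 1)
    abort("mediation_proportion_true must be in [0, 1]",
          class = "omix_config_error")
  if (essential_enrichment < 1)
    abort("essential_enrichment must be >= 1", class = "omix_config_error")
  if (n_causal_eqtl > n_variants_per_locus)
    abort("n_causal_eqtl cannot exceed n_variants_per_locus",
          class = "omix_config_error")
  structure(list(
    n_individuals_ref = as.integer(n_individuals_ref),
    n_train = as.integer(n_train),
    n_cohort1 = as.integer(n_cohort1), n_cohort2 = as.integer(n_cohort2),
    n_genes = as.integer(n_genes),
    genes_per_locus = as.integer(genes_per_locus),
    n_variants_per_locus = as.integer(n_variants_per_locus),
    ld_block_size = as.integer(ld_block_size),
    ld_decay_rho = ld_decay_rho, maf_range = maf_range,
    n_causal_eqtl = as.integer(n_causal_eqtl),
    essential_enrichment = essential_enrichment, h2_cis = h2_cis,
    alpha_grex_trait = alpha_grex_trait,
    mediation_proportion_true = mediation_proportion_true,
    prop_causal = prop_causal, confound_gamma = confound_gamma,
    mediator_noise_sd = mediator_noise_sd, seed = as.integer(seed)),
    class = "sim_config")
}

# Run code with a local RNG state so generators do not disturb the caller's.
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bivariate standard-normal CDF P(Z1 < a, Z2 < b) with correlation rho,
# by 1-D quadrature (used only for LD calibration at generation time).
pbinorm_ <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a) * pnorm(b))
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((b - rho * z) / s),
            lower = -8.5, upper = a, rel.tol = 1e-10)$value
}

# Pearson correlation of two Bernoulli(p) indicators thresholded from
# latent normals with correlation rho (equal frequencies).
binary_corr_ <- function(rho, p) {
  a <- qnorm(p)
  (pbinorm_(a, a, rho) - p^2) / (p * (1 - p))
}

# Latent correlation whose thresholded-indicator correlation equals target.
calibrate_latent_rho_ <- function(target, p) {
  if (target <= 0) return(0)
  if (binary_corr_(0.9999, p) <= target) return(0.9999)
  uniroot(function(r) binary_corr_(r, p) - target,
          lower = 0, upper = 0.9999, tol = 1e-7)$root
}

# Deterministic genome layout shared by all cohorts drawn from one config:
# locus coordinates, variant positions, per-block allele frequencies and
# calibrated latent AR(1) correlations, gene TSSs.
derive_genome_ <- function(config) {
  with_seed_(config$seed, {
    n_gene_loci <- ceiling(config$n_genes / config$genes_per_locus)
    # one extra locus hosts the mediator's own genetic instruments,
    # independent of every gene's cis window
    n_loci <- n_gene_loci + 1L
    locus_span <- 4e6
    m <- config$n_variants_per_locus
    loci <- tibble(
      locus_id = c(paste0("locus", seq_len(n_gene_loci)), "locusM"),
      chrom = "chr1",
      start = (seq_len(n_loci) - 1) * locus_span,
      end = seq_len(n_loci) * locus_span)
    variants <- purrr::map_dfr(seq_len(n_loci), function(l) {
      centre <- loci$start[l] + locus_span / 2
      pos <- sort(round(seq(centre - 1e6 + 5e3, centre + 1e6 - 5e3,
                            length.out = m)))
      blk <- (seq_len(m) - 1) %/% config$ld_block_size
      maf_blk <- runif(max(blk) + 1, config$maf_range[1], config$maf_range[2])
      tibble(variant_id = paste0("rs", l, "_", seq_len(m)),
             chrom = "chr1", pos = as.integer(pos),
             a1 = "A", a2 = "G",
             locus_id = loci$locus_id[l], block = blk,
             maf = maf_blk[blk + 1])
    })
    # latent adjacent correlation per block frequency (cached on unique mafs)
    umaf <- unique(variants$maf)
    lat <- vapply(umaf, function(p)
      calibrate_latent_rho_(config$ld_decay_rho, p), numeric(1))
    variants$latent_rho <- lat[match(variants$maf, umaf)]
    genes <- purrr::map_dfr(seq_len(n_gene_loci), function(l) {
      k <- min(config$genes_per_locus,
               config$n_genes - (l - 1) * config$genes_per_locus)
      centre <- loci$start[l] + locus_span / 2
      tss <- round(seq(centre - 4e5, centre + 4e5, length.out = max(k, 2)))[seq_len(k)]
      tibble(gene_id = paste0("gene", (l - 1) * config$genes_per_locus + seq_len(k)),
             chrom = "chr1", tss = as.integer(tss),
             start = as.integer(tss), end = as.integer(tss + 5e4),
             strand = "+", locus_id = loci$locus_id[l])
    })
    list(loci = loci, variants = variants, genes = genes)
  })
}

# Draw n individuals' dosages for one genome layout. Two latent AR(1)
# haplotype chains per individual are thresholded at the block allele
# frequency; the latent correlation is calibrated so the realised adjacent
# dosage correlation matches ld_decay_rho.
sample_dosages_ <- function(genome, n, seed) {
  v <- genome$variants
  m <- nrow(v)
  with_seed_(seed, {
    dos <- matrix(0L, n, m)
    grp <- paste(v$locus_id, v$block)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      k <- length(idx)
      p <- v$maf[idx[1]]
      rho <- v$latent_rho[idx[1]]
      thr <- qnorm(p)
      hap_sum <- matrix(0L, n, k)
      for (h in 1:2) {
        z <- matrix(rnorm(n * k), n, k)
        if (k > 1 && rho > 0) {
          s <- sqrt(1 - rho^2)
          for (j in 2:k) z[, j] <- rho * z[, j - 1] + s * z[, j]
        }
        hap_sum <- hap_sum + (z < thr)
      }
      dos[, idx] <- hap_sum
    }
    colnames(dos) <- v$variant_id
    rownames(dos) <- paste0("id", seq_len(n))
    dos
  })
}

#' Simulate block-LD genotype dosages
#'
#' Generates a dosage matrix with AR(1)-style linkage disequilibrium inside
#' blocks (adjacent-variant dosage correlation `ld_decay_rho`, decaying with
#' distance) and independence across blocks. A Gaussian copula over two
#' haplotype chains is thresholded at the block allele frequency; the latent
#' correlation is calibrated so the dosage-scale correlation hits its target
#' despite threshold attenuation.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals (default: the reference-panel size).
#' @param seed Seed for the individual draw (default: derived from the
#'   config seed). The variant panel itself depends only on the config.
#'
#' @return A list of class `omix_geno` with elements `dosages` (individuals
#'   x variants integer matrix in 0..2), `variants` (tibble: `variant_id`,
#'   `chrom`, `pos` (1-based), `a1`, `a2`, `maf`, `locus_id`, `block`) and
#'   `sample_ids`.
#' @export
simulate_genotypes <- function(config, n = config$n_individuals_ref,
                               seed = config$seed + 1000L) {
  stopifnot(inherits(config, "sim_config"))
  if (n < 1) abort("n must be positive", class = "omix_config_error")
  genome <- derive_genome_(config)
  dos <- sample_dosages_(genome, n, seed)
  new_geno_(dos, genome$variants, genome = genome)
}

new_geno_ <- function(dosages, variants, genome = NULL) {
  structure(list(dosages = dosages,
                 variants = as_tibble(variants),
                 sample_ids = rownames(dosages),
                 genome = genome),
            class = "omix_geno")
}

#' @export
print.omix_geno <- function(x, ...) {
  cat("<omix_geno> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " variants\n", sep = "")
  invisible(x)
}

#' Simulate epigenomic annotation tracks and candidate cis windows
#'
#' Lays four binary annotation tracks (H3K27ac, H3K4me3, DNase, CTCF) over
#' the synthetic genome as BED-style half-open intervals, simulates a TAD
#' partition and chromatin loops per locus, and derives the four candidate
#' window kinds per gene via [build_windows()].
#'
#' @param config A [sim_config()].
#' @param geno An `omix_geno` carrying the genome layout.
#' @param track_coverage Fraction of each locus covered per track.
#'
#' @return A list with `annotations` (tibble: `track`, `chrom`, `start`,
#'   `end`; 0-based half-open), `tads`, `loops`, `windows` (tibble:
#'   `gene_id`, `kind`, `chrom`, `start`, `end`) and `genes`.
#' @export
simulate_annotations_and_windows <- function(config, geno,
                                             track_coverage = 0.15) {
  stopifnot(inherits(geno, "omix_geno"))
  genome <- geno$genome
  if (is.null(genome)) abort("geno does not carry a genome layout")
  with_seed_(config$seed + 2000L, {
    tracks <- c("H3K27ac", "H3K4me3", "DNase", "CTCF")
    ann <- purrr::map_dfr(tracks, function(tr) {
      purrr::map_dfr(seq_len(nrow(genome$loci)), function(l) {
        span <- genome$loci$end[l] - genome$loci$start[l]
        k <- 6L
        w <- round(track_coverage * span / k)
        s <- sort(sample.int(span - w, k)) + genome$loci$start[l]
        tibble(track = tr, chrom = genome$loci$chrom[l],
               start = as.integer(s), end = as.integer(s + w))
      })
    })
    tads <- purrr::map_dfr(seq_len(nrow(genome$loci)), function(l) {
      s <- genome$loci$start[l]
      bounds <- s
      while (max(bounds) < genome$loci$end[l])
        bounds <- c(bounds, min(max(bounds) + round(runif(1, 4e5, 1.4e6)),
                                genome$loci$end[l]))
      tibble(chrom = genome$loci$chrom[l],
             start = as.integer(bounds[-length(bounds)]),
             end = as.integer(bounds[-1]))
    })
    loops <- purrr::map_dfr(seq_len(nrow(genome$genes)), function(gi) {
      g <- genome$genes[gi, ]
      out <- NULL
      if (runif(1) < 0.7) {  # TSS-anchored loop to a distal element
        d <- sample(c(-1, 1), 1) * round(runif(1, 1.5e5, 9e5))
        out <- tibble(chrom = g$chrom,
                      a_start = as.integer(g$tss - 5e3),
                      a_end = as.integer(g$tss + 5e3),
                      b_start = as.integer(g$tss + d - 5e3),
                      b_end = as.integer(g$tss + d + 5e3))
      }
      # decoy loop elsewhere in the locus
      s <- genome$loci[genome$loci$locus_id == g$locus_id, ]
      x <- round(runif(2, s$start + 1e4, s$end - 2e4))
      bind_rows(out, tibble(chrom = g$chrom,
                            a_start = as.integer(x[1]),
                            a_end = as.integer(x[1] + 1e4),
                            b_start = as.integer(x[2]),
                            b_end = as.integer(x[2] + 1e4)))
    })
    windows <- build_windows(genome$genes, tads, loops)
    list(annotations = ann, tads = tads, loops = loops,
         windows = windows, genes = genome$genes)
  })
}

#' Build candidate cis windows for each gene
#'
#' Four window kinds per gene, all half-open `[start, end)` on the 0-based
#' synthetic coordinate system: `fixed_1mb` and `fixed_250kb` centred on the
#' TSS; `tad` = the TAD interval containing the TSS (falling back to
#' `fixed_1mb` when no TAD covers it); `loop` = the union of both anchors of
#' every loop with either anchor overlapping `[TSS - 5kb, TSS + 5kb)`, plus
#' the gene body (falling back to `fixed_1mb` when no loop qualifies).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `start`, `end`.
#' @param tads Tibble with `chrom`, `start`, `end` (may be NULL).
#' @param loops Tibble with `chrom`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (may be NULL).
#'
#' @return Tibble `gene_id`, `kind`, `chrom`, `start`, `end` (a window kind
#'   may span several rows, e.g. loop anchors).
#' @export
build_windows <- function(genes, tads = NULL, loops = NULL) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    fixed <- tibble(
      gene_id = g$gene_id,
      kind = c("fixed_1mb", "fixed_250kb"),
      chrom = g$chrom,
      start = as.integer(pmax(0, c(g$tss - 1e6, g$tss - 2.5e5))),
      end = as.integer(c(g$tss + 1e6, g$tss + 2.5e5)))
    f1 <- fixed[fixed$kind == "fixed_1mb", ]
    tad_w <- NULL
    if (!is.null(tads) && nrow(tads)) {
      hit <- tads[tads$chrom == g$chrom & tads$start <= g$tss &
                    g$tss < tads$end, ]
      if (nrow(hit) >= 1)
        tad_w <- tibble(gene_id = g$gene_id, kind = "tad", chrom = g$chrom,
                        start = hit$start[1], end = hit$end[1])
    }
    if (is.null(tad_w))
      tad_w <- mutate(f1, kind = "tad")
    loop_w <- NULL
    if (!is.null(loops) && nrow(loops)) {
      ts <- g$tss - 5e3; te <- g$tss + 5e3
      sel <- loops$chrom == g$chrom &
        ((loops$a_start < te & ts < loops$a_end) |
           (loops$b_start < te & ts < loops$b_end))
      if (any(sel)) {
        anc <- loops[sel, ]
        loop_w <- tibble(gene_id = g$gene_id, kind = "loop", chrom = g$chrom,
                         start = c(anc$a_start, anc$b_start, g$start),
                         end = c(anc$a_end, anc$b_end, g$end))
      }
    }
    if (is.null(loop_w))
      loop_w <- mutate(f1, kind = "loop")
    bind_rows(fixed, tad_w, loop_w)
  })
}

#' Flag variants overlapping any annotation track
#'
#' A variant at 1-based position `p` overlaps a 0-based half-open interval
#' `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (1-based).
#' @param annotations Tibble with `chrom`, `start`, `end`.
#' @return Logical vector along rows of `variants`.
#' @export
flag_essential <- function(variants, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0)
    return(rep(FALSE, nrow(variants)))
  vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1
    any(annotations$chrom == variants$chrom[i] &
          annotations$start <= p0 & p0 < annotations$end)
  }, logical(1))
}

#' Simulate expression with a planted annotation-enriched cis architecture
#'
#' Per gene, `n_causal_eqtl` causal variants are drawn from the gene's
#' `fixed_1mb` window with odds multiplied by `essential_enrichment` for
#' annotated variants; expression is the causal dosage combination plus
#' Gaussian noise scaled so the genetic fraction of variance equals
#' `h2_cis` in the generating population.
#'
#' @param geno `omix_geno` training genotypes.
#' @param annot Result of [simulate_annotations_and_windows()].
#' @param config A [sim_config()].
#'
#' @return List with `expression` (genes x samples matrix), `truth` (list of
#'   class `synthetic_truth`: per-gene `causal_variants`, `eqtl_betas`,
#'   `causal_gene_per_locus`, `true_MP`, `true_alpha`) and `genes`.
#' @export
simulate_expression <- function(geno, annot, config) {
  stopifnot(inherits(geno, "omix_geno"), inherits(config, "sim_config"))
  genes <- annot$genes
  ess <- flag_essential(geno$variants, annot$annotations)
  v <- geno$variants
  with_seed_(config$seed + 3000L, {
    expr <- matrix(NA_real_, nrow(genes), nrow(geno$dosages),
                   dimnames = list(genes$gene_id, geno$sample_ids))
    causal <- vector("list", nrow(genes)); names(causal) <- genes$gene_id
    betas <- vector("list", nrow(genes)); names(betas) <- genes$gene_id
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      in_cis <- which(v$chrom == g$chrom & abs(v$pos - g$tss) <= 1e6)
      w <- ifelse(ess[in_cis], config$essential_enrichment, 1)
      k <- min(config$n_causal_eqtl, length(in_cis))
      pick <- sample(in_cis, k, prob = w)
      b <- rnorm(k)
      G <- geno$dosages[, pick, drop = FALSE] %*% b
      vg <- var(as.vector(G))
      if (config$h2_cis > 0 && vg > 0) {
        b <- b * sqrt(config$h2_cis / vg)
        G <- G * sqrt(config$h2_cis / vg)
      } else {
        b <- b * 0; G <- G * 0
      }
      e <- rnorm(nrow(geno$dosages), sd = sqrt(max(1 - config$h2_cis, 0)))
      expr[i, ] <- as.vector(G) + e
      causal[[i]] <- v$variant_id[pick]
      betas[[i]] <- setNames(as.vector(b), v$variant_id[pick])
    }
    locus_lead <- genes |> group_by(.data$locus_id) |>
      summarise(causal_gene = .data$gene_id[1], .groups = "drop")
    n_caus <- max(1L, round(config$prop_causal * nrow(locus_lead)))
    causal_loci <- locus_lead$locus_id[seq_len(n_caus)]
    truth <- structure(list(
      causal_variants = causal, eqtl_betas = betas,
      causal_gene_per_locus = setNames(locus_lead$causal_gene,
                                       locus_lead$locus_id),
      causal_loci = causal_loci,
      causal_genes = locus_lead$causal_gene[locus_lead$locus_id %in% causal_loci],
      true_MP = config$mediation_proportion_true,
      true_alpha = config$alpha_grex_trait), class = "synthetic_truth")
    list(expression = expr, truth = truth, genes = genes)
  })
}

# Vectorised per-variant simple regression of y on each dosage column.
marginal_gwas_ <- function(dosages, y, trait_name, cohort_name, variants) {
  n <- length(y)
  x_mean <- colMeans(dosages)
  xc <- sweep(dosages, 2, x_mean)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  syy <- sum(yc^2)
  beta <- unname(ifelse(sxx > 0, sxy / sxx, NA_real_))
  rss <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
  se <- unname(sqrt(pmax(rss, 1e-300) / ((n - 2) * pmax(sxx, 1e-300))))
  se[sxx <= 0] <- NA_real_
  z <- beta / se
  tibble(variant_id = variants$variant_id, chrom = variants$chrom,
         pos = variants$pos, a1 = variants$a1, a2 = variants$a2,
         beta = beta, se = se, z = z,
         p = 2 * pnorm(-abs(z)), n = n,
         trait = trait_name, cohort = cohort_name)
}

#' Simulate two GWAS cohorts and a mediator GWAS with planted truth
#'
#' The trait model is `trait = direct * G + c * M + gamma * C + eps`, where
#' `G` is the sum of true genetic expression over causal genes, the mediator
#' is `M = G + W + e_m` with `W` a genetic score over a dedicated mediator
#' locus (its variants sit outside every gene's cis window, giving the
#' mediator valid instruments of its own), `C` a shared confound, and the
#' loadings are chosen so the mediated fraction of the total
#' expression-to-trait effect equals `mediation_proportion_true` exactly in
#' expectation: with the exposure-to-mediator loading fixed at 1,
#' `c = MP * alpha` and `direct = (1 - MP) * alpha`, so the total exposure
#' effect is `direct + c = alpha` and the mediated share `c / alpha = MP`.
#' Summary statistics are obtained by actually regressing the simulated
#' trait on each dosage, so summary-level and individual-level analyses can
#' be cross-checked.
#'
#' @param config A [sim_config()].
#' @param truth A `synthetic_truth` from [simulate_expression()].
#' @param trait_name,cohort_names Labels for the emitted summary sets.
#' @param keep_individual Keep individual-level cohort data (genotypes,
#'   trait, mediator) in the result for oracle checks.
#'
#' @return List with `cohort1`, `cohort2`, `mediator` GWAS summary tibbles
#'   (`variant_id, chrom, pos, a1, a2, beta, se, z, p, n, trait, cohort`),
#'   and, if requested, `individual` data per cohort.
#' @export
simulate_gwas_cohorts <- function(config, truth,
                                  trait_name = "trait",
                                  cohort_names = c("cohort1", "cohort2"),
                                  keep_individual = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  genome <- derive_genome_(config)
  alpha <- truth$true_alpha
  mp <- truth$true_MP
  c_med <- mp * alpha
  direct <- (1 - mp) * alpha
  # mediator-specific instruments: spaced variants in the dedicated locus,
  # weights scaled to unit expected variance (2 p (1 - p) per dosage)
  vM <- genome$variants[genome$variants$locus_id == "locusM", ]
  med_idx <- round(seq(1, nrow(vM),
                       length.out = min(5, nrow(vM))))
  med_w <- with_seed_(config$seed + 7000L, rnorm(length(med_idx)))
  vfreq <- vM$maf[med_idx]
  med_w <- med_w / sqrt(sum(med_w^2 * 2 * vfreq * (1 - vfreq)))
  med_ids <- vM$variant_id[med_idx]
  one_cohort <- function(n, seed, label, with_mediator_stats = FALSE) {
    dos <- sample_dosages_(genome, n, seed)
    G <- numeric(n)
    for (g in truth$causal_genes) {
      b <- truth$eqtl_betas[[g]]
      G <- G + as.vector(dos[, names(b), drop = FALSE] %*% b)
    }
    W <- as.vector(dos[, med_ids, drop = FALSE] %*% med_w)
    with_seed_(seed + 1L, {
      C <- rnorm(n)
      e_m <- rnorm(n, sd = config$mediator_noise_sd)
      eps <- rnorm(n)
      M <- G + W + e_m
      trait <- direct * G + c_med * M + config$confound_gamma * C + eps
      out <- list(
        summary = marginal_gwas_(dos, trait, trait_name, label,
                                 genome$variants),
        individual = list(dosages = dos, trait = trait, mediator = M,
                          grex_true = G, mediator_genetic = W))
      if (with_mediator_stats)
        out$mediator_summary <- marginal_gwas_(dos, M, "mediator",
                                               label, genome$variants)
      out
    })
  }
  c1 <- one_cohort(config$n_cohort1, config$seed + 4000L, cohort_names[1])
  c2 <- one_cohort(config$n_cohort2, config$seed + 5000L, cohort_names[2])
  cm <- one_cohort(config$n_cohort1, config$seed + 6000L, "mediator_cohort",
                   with_mediator_stats = TRUE)
  res <- list(cohort1 = c1$summary, cohort2 = c2$summary,
              mediator = cm$mediator_summary,
              mediator_instruments = tibble(variant_id = med_ids,
                                            weight = med_w))
  if (keep_individual)
    res$individual <- list(cohort1 = c1$individual, cohort2 = c2$individual,
                           mediator_cohort = cm$individual)
  res
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()] (reference and
#' training panels), [simulate_annotations_and_windows()],
#' [simulate_expression()] and [simulate_gwas_cohorts()] from one config.
#'
#' @param config A [sim_config()].
#' @param keep_individual Passed to [simulate_gwas_cohorts()].
#' @return List of class `omix_sim` with `reference`, `train`, `annot`,
#'   `expression`, `truth`, `genes`, `gwas`.
#' @export
simulate_study <- function(config, keep_individual = FALSE) {
  reference <- simulate_genotypes(config, n = config$n_individuals_ref,
                                  seed = config$seed + 1000L)
  train <- simulate_genotypes(config, n = config$n_train,
                              seed = config$seed + 1500L)
  annot <- simulate_annotations_and_windows(config, train)
  ex <- simulate_expression(train, annot, config)
  gwas <- simulate_gwas_cohorts(config, ex$truth,
                                keep_individual = keep_individual)
  structure(list(reference = reference, train = train, annot = annot,
                 expression = ex$expression, truth = ex$truth,
                 genes = ex$genes, gwas = gwas, config = config),
            class = "omix_sim")
}
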