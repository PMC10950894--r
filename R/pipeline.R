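#' Pipeline configuration
#'
#' One object driving the end-to-end synthetic analysis: simulate, QC,
#' train, validate, associate, replicate, MR-gate, fine-map, mediate.
#'
#' @param sim A [sim_config()].
#' @param train A [train_config()] (grids may be reduced for speed).
#' @param fdr FDR threshold (default 0.05).
#' @param validate_r Validation correlation threshold (default 0.1).
#' @param clump_p,clump_r2 Instrument selection thresholds (defaults 1e-3,
#'   0.5).
#' @param mhc Optional `c(chrom, start, end)` exclusion interval.
#' @param maf_min,hwe_p_min Variant QC thresholds.
#' @param n_holdout Validation-panel size.
#' @param out_dir Optional run directory for stage TSVs and the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), train = train_config(),
                            fdr = 0.05, validate_r = 0.1,
                            clump_p = 1e-3, clump_r2 = 0.5, mhc = NULL,
                            maf_min = 0.05, hwe_p_min = 1e-3,
                            n_holdout = 200, out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(train, "train_config"))
  if (fdr <= 0 || fdr >= 1) abort("fdr must be in (0,1)")
  structure(list(sim = sim, train = train, fdr = fdr,
                 validate_r = validate_r, clump_p = clump_p,
                 clump_r2 = clump_r2, mhc = mhc, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, n_holdout = as.integer(n_holdout),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end synthetic analysis
#'
#' Stages: simulate -> variant QC -> normalize -> train GReX models ->
#' validate on an independent holdout panel -> summary-statistic TWAS in
#' both cohorts -> reciprocal replication -> MR causal gates (penalized
#' IVW + Egger pleiotropy) -> gene-level fine-mapping -> mediation for the
#' planted mediator. Each stage's counts feed the discovery funnel, which
#' is monotone: retained fine-mapped genes are a subset of MR-passing
#' genes, themselves a subset of replicated genes, themselves a subset of
#' validated models. When `out_dir` is set, stage TSVs and a JSON manifest
#' (seeds, thresholds, file hashes, counts) are written.
#'
#' @param config A [pipeline_config()].
#' @return List of class `omix_pipeline` with all stage outputs and
#'   `funnel` counts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_study(config$sim)

  train_geno <- variant_qc(sim$train, maf_min = config$maf_min,
                           hwe_p_min = config$hwe_p_min)
  expr <- normalize_expression(sim$expression, log_transform = FALSE,
                               quantile_normalize = FALSE)
  models <- train_grex_models(train_geno, expr, sim$annot$annotations,
                              sim$annot$windows, config$train,
                              method = "pumice")
  retained <- purrr::keep(models, ~ isTRUE(.x$retained))

  holdout_geno <- simulate_genotypes(config$sim, n = config$n_holdout,
                                     seed = config$sim$seed + 9000L)
  holdout_expr <- simulate_expression(holdout_geno, sim$annot, config$sim)
  validation <- if (length(retained))
    validate_models(structure(retained, class = "grex_model_set"),
                    holdout_geno,
                    normalize_expression(holdout_expr$expression,
                                         log_transform = FALSE,
                                         quantile_normalize = FALSE))
  else tibble(gene_id = character(), validated = logical())
  validated_genes <- validation$gene_id[validation$validated]
  val_models <- retained[intersect(names(retained), validated_genes)]

  ld <- ld_reference(sim$reference)
  twas <- list()
  funnel_hits <- list()
  rep_hits <- NULL
  if (length(val_models)) {
    ms <- structure(val_models, class = "grex_model_set")
    twas$cohort1 <- twas_scan(ms, sim$gwas$cohort1, ld,
                              mhc_exclude = config$mhc)
    twas$cohort2 <- twas_scan(ms, sim$gwas$cohort2, ld,
                              mhc_exclude = config$mhc)
    if (nrow(twas$cohort1) && nrow(twas$cohort2))
      rep_hits <- reciprocal_replicate(twas$cohort1, twas$cohort2,
                                       fdr_threshold = config$fdr)
  }
  replicated <- if (!is.null(rep_hits) && nrow(rep_hits))
    unique(rep_hits$feature_id[rep_hits$replicated]) else character(0)

  # MR causal gate per replicated gene
  mr_results <- purrr::map(replicated, function(g) {
    gm <- sim$genes[sim$genes$gene_id == g, ]
    eq <- cis_eqtl_scan(expr[g, ], train_geno, gm)
    instr <- tryCatch({
      cl <- ld_clump(eq, ld, p_max = config$clump_p,
                     r2_max = config$clump_r2)
      instrument_set(cl, sim$gwas$cohort1, ld = ld)
    }, error = function(e) NULL)
    if (is.null(instr)) return(NULL)
    ivw <- mr_ivw(instr, penalized = TRUE,
                  use_correlation = !is.null(instr$correlation) &&
                    length(instr$variant_id) > 1)
    egger <- if (length(instr$variant_id) >= 3)
      tryCatch(mr_egger(instr, use_correlation = TRUE),
               error = function(e) NULL) else NULL
    pleio_p <- egger$egger_intercept_p %||% NA_real_
    list(gene_id = g, ivw = ivw, egger = egger,
         passes = ivw$p < 0.05 && (is.na(pleio_p) || pleio_p > 0.05))
  })
  mr_results <- purrr::compact(mr_results)
  mr_passing <- purrr::map_chr(purrr::keep(mr_results, "passes"),
                               "gene_id")

  # fine-mapping over simulation loci restricted to MR-passing genes
  finemap <- list(); finemap_retained <- character(0)
  if (length(mr_passing)) {
    blocks <- sim$train$genome$loci
    tw1 <- twas$cohort1[twas$cohort1$feature_id %in% mr_passing, ]
    loci_in <- build_locus_inputs(tw1,
                                  structure(val_models,
                                            class = "grex_model_set"),
                                  sim$reference,
                                  select(blocks, "chrom", "start", "end"),
                                  select(sim$genes, "gene_id", "chrom",
                                         "tss"),
                                  mhc = config$mhc)
    multi_gene <- unlist(purrr::map(loci_in, "gene_ids"))
    finemap <- purrr::map(loci_in, function(li)
      enumerate_posteriors(li$z, li$omega))
    fm_ret <- unlist(purrr::map(finemap, function(f)
      f$genes$gene_id[f$genes$retained]))
    # single-signal loci need no fine-mapping and pass through
    finemap_retained <- union(setdiff(mr_passing, multi_gene),
                              fm_ret %||% character(0))
  }

  # mediation for the planted causal gene (when it survived the funnel)
  mediation <- NULL
  med_gene <- intersect(sim$truth$causal_genes, mr_passing)
  if (length(med_gene)) {
    g <- med_gene[1]
    gm <- sim$genes[sim$genes$gene_id == g, ]
    eq <- cis_eqtl_scan(expr[g, ], train_geno, gm)
    mediation <- tryCatch({
      cl <- ld_clump(eq, ld, p_max = config$clump_p,
                     r2_max = config$clump_r2)
      i_em <- instrument_set(cl, sim$gwas$mediator, ld = ld)
      i_eo <- instrument_set(cl, sim$gwas$cohort1, ld = ld)
      # mediator instruments must not act through the exposure: drop
      # variants within any trained gene's cis window (Steiger-style
      # exclusion restricted to cis regions)
      med_sig <- sim$gwas$mediator |> filter(.data$p <= config$clump_p)
      in_cis <- purrr::map_lgl(seq_len(nrow(med_sig)), function(i)
        any(med_sig$chrom[i] == sim$genes$chrom &
              abs(med_sig$pos[i] - sim$genes$tss) <= 1e6))
      med_sig <- med_sig[!in_cis, , drop = FALSE]
      cl_m <- ld_clump(med_sig, ld, p_max = config$clump_p,
                       r2_max = config$clump_r2)
      i_mo <- instrument_set(cl_m, sim$gwas$cohort1, ld = ld)
      two_step_mediation(mr_ivw(i_em, penalized = TRUE),
                         mr_ivw(i_mo, penalized = TRUE),
                         mr_ivw(i_eo, penalized = TRUE))
    }, error = function(e) NULL)
  }

  funnel <- tibble(
    stage = c("genes_simulated", "models_retained", "models_validated",
              "genes_replicated", "genes_mr_passing",
              "genes_finemap_retained"),
    count = c(config$sim$n_genes, length(retained), length(val_models),
              length(replicated), length(mr_passing),
              length(finemap_retained)))

  out <- structure(list(
    sim = sim, models = models, validation = validation, twas = twas,
    replication = rep_hits, mr = mr_results, mr_passing = mr_passing,
    finemap = finemap, finemap_retained = finemap_retained,
    mediation = mediation, funnel = funnel, config = config),
    class = "omix_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs_(out)
  out
}

write_pipeline_outputs_ <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(res$config$out_dir, f)
  write_vcf(res$sim$train, p("train_genotypes.vcf"))
  write_expression_tsv(res$sim$expression, p("expression.tsv"))
  write_bed(res$sim$annot$annotations, p("annotations.bed"))
  write_gwas_tsv(res$sim$gwas$cohort1, p("gwas_cohort1.tsv"))
  write_gwas_tsv(res$sim$gwas$cohort2, p("gwas_cohort2.tsv"))
  write_gwas_tsv(res$sim$gwas$mediator, p("gwas_mediator.tsv"))
  write_truth_json(res$sim$truth, p("truth.json"))
  wt <- weights_table(res$models, retained_only = TRUE)
  if (nrow(wt)) write_weights_tsv(wt, p("weights.tsv"))
  readr::write_tsv(res$validation, p("validation.tsv"))
  if (!is.null(res$twas$cohort1)) {
    readr::write_tsv(res$twas$cohort1, p("twas_cohort1.tsv"))
    readr::write_tsv(res$twas$cohort2, p("twas_cohort2.tsv"))
  }
  if (!is.null(res$replication))
    readr::write_tsv(res$replication, p("replication.tsv"))
  readr::write_tsv(res$funnel, p("funnel.tsv"))
  files <- list.files(res$config$out_dir, full.names = TRUE)
  md5 <- tools::md5sum(files)
  names(md5) <- basename(files)
  manifest <- list(
    seed = res$config$sim$seed,
    thresholds = list(fdr = res$config$fdr,
                      validate_r = res$config$validate_r,
                      clump_p = res$config$clump_p,
                      clump_r2 = res$config$clump_r2),
    counts = setNames(as.list(res$funnel$count), res$funnel$stage),
    files = as.list(md5))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(res)
}

#' @export
print.omix_pipeline <- function(x, ...) {
  cat("<omix_pipeline> discovery funnel:\n")
  print(x$funnel)
  invisible(x)
}
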