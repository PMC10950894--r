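#' Write genotypes to a VCF 4.2 file
#'
#' Emits one record per variant with `GT` (hard call, unphased) and `DS`
#' (dosage) fields. Positions are 1-based in the file; the in-memory
#' convention everywhere else in the package is 0-based half-open for
#' intervals and 1-based for point positions.
#'
#' @param geno An `omix_geno`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "omix_geno"))
  v <- geno$variants
  d <- geno$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(geno$sample_ids, collapse = "\t"))), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- d[, j]
    hard <- pmin(pmax(round(ds), 0), 2)
    gt <- ifelse(is.na(ds), "./.", gt_codes[hard + 1])
    samp <- paste0(gt, ":", ifelse(is.na(ds), ".", format(ds, trim = TRUE)))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$a2[j],
                       v$a1[j], ".", "PASS", ".", "GT:DS", samp),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses via `vcfR`; uses the `DS` field when present, otherwise allele
#' counts from `GT`. The ALT allele is taken as the effect allele `a1`.
#'
#' @param path VCF path.
#' @return An `omix_geno`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("read_vcf requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- tibble(variant_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF)
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(al) {
        if (any(al == ".")) return(NA_real_)
        sum(as.numeric(al))
      }, numeric(1))
    })
  }
  dos <- t(fmt)  # samples x variants
  colnames(dos) <- variants$variant_id
  new_geno_(dos, variants)
}

#' Read/write BED intervals
#'
#' BED is 0-based half-open. Three mandatory columns plus an optional name
#' column are supported (BED3/BED4).
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name` (or
#'   `track`, used as the name column).
#' @param path File path.
#' @return `write_bed` returns `path` invisibly; `read_bed` a tibble.
#' @export
write_bed <- function(x, path) {
  nm <- if ("name" %in% names(x)) x$name
        else if ("track" %in% names(x)) x$track else NULL
  df <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
  if (!is.null(nm)) df$name <- nm
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  as_tibble(df)
}

#' Read/write GWAS summary statistics TSV
#'
#' The dialect carries `variant_id, chrom, pos, a1, a2, beta, se, z, n`
#' (plus any extra columns); `z` is checked for consistency with
#' `beta / se` on read.
#'
#' @param x Summary tibble.
#' @param path File path.
#' @export
write_gwas_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("variant_id", "chrom", "pos", "a1", "a2", "beta", "se", "z", "n")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(paste0("GWAS TSV missing columns: ", paste(miss, collapse = ", ")))
  bad <- abs(x$z - x$beta / x$se) > 1e-4 * pmax(1, abs(x$z))
  if (any(bad, na.rm = TRUE))
    warn(paste0(sum(bad, na.rm = TRUE), " records with z inconsistent with beta/se"))
  as_tibble(x)
}

#' Read/write an expression matrix TSV (features x samples)
#'
#' First column `feature_id`, remaining columns one per sample.
#' @param mat Features x samples numeric matrix with dimnames.
#' @param path File path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read/write a GReX weight table TSV
#'
#' Columns: `gene_id, variant_id, a1, a2, weight` plus model metadata
#' (`method, chosen_window, chosen_phi, chosen_lambda, cv_r, cv_p`).
#' @param weights Weight tibble (e.g. from [weights_table()]).
#' @param path File path.
#' @export
write_weights_tsv <- function(weights, path) {
  readr::write_tsv(weights, path)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "variant_id", "a1", "a2", "weight")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(paste0("weight TSV missing columns: ", paste(miss, collapse = ", ")))
  as_tibble(x)
}

#' Serialize the planted simulation truth to JSON
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$eqtl_betas <- lapply(x$eqtl_betas, as.list)  # keep variant names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$causal_variants <- as.list(x$causal_variants)
  x$eqtl_betas <- lapply(x$eqtl_betas, unlist)
  structure(x, class = "synthetic_truth")
}
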