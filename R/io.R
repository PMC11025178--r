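# Readers/writers for the plain-text interchange formats: TSV dosage
# matrices, minimal VCF, cohort/incidence/summary-statistic/PRS tables.
# Delimited IO goes through readr; VCF reading through vcfR.

#' Write / read a TSV dosage matrix
#'
#' One row per variant: the metadata columns then one dosage column per
#' sample (missing as `NA`).
#'
#' @param g A [geno_matrix()].
#' @param path File path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns a [geno_matrix()].
#' @export
write_dosage_tsv <- function(g, path) {
  meta <- g$variants[, c("variant_id", "chr", "pos", "effect_allele",
                         "other_allele")]
  dos <- as.data.frame(t(g$dosages))
  names(dos) <- g$samples
  readr::write_tsv(dplyr::bind_cols(meta, dos), path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele")
  check_cols(df, meta_cols, "dosage TSV")
  samples <- setdiff(names(df), meta_cols)
  dos <- t(as.matrix(df[, samples]))
  geno_matrix(dos, mutate(df[, meta_cols], chr = as.character(.data$chr)),
              samples = samples)
}

#' Write genotypes as a minimal VCF
#'
#' VCFv4.2 with hard-call `GT` entries; the effect allele is written as ALT
#' so the dosage is the ALT-allele count. Missing genotypes become `./.`.
#'
#' @param g A [geno_matrix()].
#' @param path Output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = ncol(g$dosages), ncol = nrow(g$dosages))
  for (j in seq_len(ncol(g$dosages))) {
    x <- g$dosages[, j]
    gt[j, !is.na(x)] <- gt_code[as.character(x[!is.na(x)])]
  }
  v <- g$variants
  body <- cbind(v$chr, v$pos, v$variant_id, v$other_allele, v$effect_allele,
                ".", "PASS", ".", "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=onsetprs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Extracts hard-call GT fields via vcfR and returns ALT-allele dosages.
#'
#' @param path VCF path.
#' @return A [geno_matrix()] (effect allele = ALT).
#' @export
read_vcf_geno <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_input("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c("./.", ".|."), NA_real_,
           stringr::str_count(s, "1"))
  }
  dos <- t(apply(gt, 1, count_alt))
  variants <- tibble(variant_id = fix$ID, chr = as.character(fix$CHROM),
                     pos = as.integer(fix$POS),
                     effect_allele = fix$ALT, other_allele = fix$REF)
  geno_matrix(t(dos), variants, samples = colnames(gt))
}

#' Cohort, incidence, summary-statistic and PRS-model tables
#'
#' Thin readr wrappers that validate the expected schemas: cohorts need
#' `sample_id`, `entry_age`, `exit_age`, `event`; incidence tables need
#' `age_start`, `age_end`, `rate_per_100k`; summary statistics use the
#' `variant_id, chr, pos, ea, oa, eaf, beta, se, p` layout; PRS models use
#' `variant_id, effect_allele, weight` plus optional metadata.
#'
#' @param x Object to write (tibble, or scan output for sumstats).
#' @param path File path.
#' @name table_io
#' @return Readers return validated tibbles (`read_prs_model` a
#'   [prs_model()]); writers return `path` invisibly.
NULL

#' @rdname table_io
#' @export
read_cohort_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("sample_id", "entry_age", "exit_age", "event"),
             "cohort TSV")
  df
}

#' @rdname table_io
#' @export
read_incidence_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("age_start", "age_end", "rate_per_100k"),
             "incidence TSV")
  df
}

#' @rdname table_io
#' @export
write_sumstats_tsv <- function(x, path) {
  x <- as_tibble(x)
  if ("effect_allele" %in% names(x)) {
    x <- rename(x, ea = "effect_allele", oa = "other_allele")
  }
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sumstats_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("variant_id", "ea", "oa", "beta", "se", "p"),
             "summary-statistic TSV")
  mutate(df, chr = as.character(.data$chr))
}

#' @rdname table_io
#' @export
write_prs_model_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_prs_model_tsv <- function(path) {
  prs_model(readr::read_tsv(path, show_col_types = FALSE))
}
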