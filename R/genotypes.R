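#' Construct a genotype matrix object
#'
#' Container for effect-allele dosages with variant metadata, the common
#' currency of the association-scan, LD and PRS functions. Dosages are hard
#' calls in \{0, 1, 2\} with `NA` marking missing genotypes.
#'
#' @param dosages Numeric matrix, samples in rows and variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants Data frame with one row per column of `dosages` and
#'   columns `variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`.
#' @param samples Character vector of sample identifiers, one per row of
#'   `dosages`. Defaults to the matrix rownames or `s1, s2, ...`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (matrix with dimnames set), `variants` (tibble) and `samples`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0, 1, 2, 1, 0, 2), nrow = 3),
#'   tibble::tibble(variant_id = c("v1", "v2"), chr = "1",
#'                  pos = c(100L, 200L),
#'                  effect_allele = c("A", "C"), other_allele = c("G", "T"))
#' )
#' g
geno_matrix <- function(dosages, variants, samples = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as_tibble(variants)
  check_cols(variants, c("variant_id", "chr", "pos", "effect_allele",
                         "other_allele"), "`variants`")
  if (nrow(variants) != ncol(dosages)) {
    abort_input("`variants` must have one row per dosage column")
  }
  if (anyDuplicated(variants$variant_id)) {
    abort_input("variant ids must be unique")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) > 0L && !all(bad %in% c(0, 1, 2))) {
    abort_input("dosage values must be 0, 1, 2 or NA")
  }
  if (is.null(samples)) {
    samples <- rownames(dosages) %||% sprintf("s%d", seq_len(nrow(dosages)))
  }
  if (length(samples) != nrow(dosages)) {
    abort_input("`samples` must name every dosage row")
  }
  dimnames(dosages) <- list(samples, variants$variant_id)
  structure(list(dosages = dosages, variants = variants,
                 samples = as.character(samples)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

# subset variants (by id or logical/integer index), keeping metadata aligned
subset_variants <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$variants$variant_id)
  geno_matrix(g$dosages[, keep, drop = FALSE],
              g$variants[keep, , drop = FALSE], g$samples)
}

subset_samples <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$samples)
  geno_matrix(g$dosages[keep, , drop = FALSE], g$variants, g$samples[keep])
}

#' Per-variant allele frequencies and call rates
#'
#' @param g A [geno_matrix()].
#' @return A tibble with `variant_id`, `eaf` (effect-allele frequency among
#'   non-missing calls), `maf`, `call_rate` and `n_called`.
#' @export
variant_freq <- function(g) {
  d <- g$dosages
  n_called <- colSums(!is.na(d))
  eaf <- colMeans(d, na.rm = TRUE) / 2
  eaf[n_called == 0L] <- NA_real_
  tibble(variant_id = g$variants$variant_id,
         eaf = eaf,
         maf = pmin(eaf, 1 - eaf),
         call_rate = n_called / nrow(d),
         n_called = as.integer(n_called))
}
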