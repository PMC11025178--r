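# LD computation, greedy clumping, PRS construction/standardization and the
# merged-PRS rule (reported variants absorb scan hits in LD with them).

#' Construct a PRS model
#'
#' An ordered weight table: one row per variant with the allele whose
#' dosage the weight multiplies. Weights are log odds or log hazard ratios.
#'
#' @param entries Tibble with `variant_id`, `effect_allele`, `weight`, and
#'   optionally `chr`, `pos`, `other_allele`, `provenance`.
#' @param name Model label.
#' @return Tibble of class `prs_model`.
#' @export
prs_model <- function(entries, name = "prs") {
  entries <- as_tibble(entries)
  check_cols(entries, c("variant_id", "effect_allele", "weight"),
             "`entries`")
  if (anyDuplicated(entries$variant_id)) {
    abort_input("PRS model variant ids must be unique")
  }
  if (any(!is.finite(entries$weight))) {
    abort_input("PRS weights must be finite")
  }
  if (!"provenance" %in% names(entries)) entries$provenance <- "gwas"
  structure(entries, class = c("prs_model", class(entries)), name = name)
}

#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two dosage vectors
#' over samples with both calls non-missing.
#'
#' @param g A [geno_matrix()].
#' @param v1,v2 Variant ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, v1, v2) {
  j1 <- match(v1, g$variants$variant_id)
  j2 <- match(v2, g$variants$variant_id)
  if (is.na(j1) || is.na(j2)) abort_input("variant not present in matrix")
  x <- g$dosages[, j1]; y <- g$dosages[, j2]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) {
    abort_input("fewer than 2 pairwise-complete samples",
                class = "onsetprs_insufficient_data")
  }
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    abort_input("a variant is constant over the complete pairs",
                class = "onsetprs_insufficient_variation")
  }
  cor(x[ok], y[ok])^2
}

# r^2 of one variant against a set of columns, pairwise-complete; returns 0
# where undefined (constant or <2 pairs) so clumping treats it as unlinked
r2_vector <- function(d, j, js) {
  x <- d[, j]
  vapply(js, function(k) {
    y <- d[, k]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) return(0)
    if (var(x[ok]) == 0 || var(y[ok]) == 0) return(0)
    cor(x[ok], y[ok])^2
  }, numeric(1))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unassigned variant with the lowest p-value below
#' `p_index` as an index and assigns to its clump every unassigned variant
#' on the same chromosome within `window_kb` whose r-squared with the index
#' is at least `r2_max`. Index variants are the retained "independent"
#' variants; members are discarded for scoring. Ties on p are broken by
#' smaller `(chr, pos)` so the result does not depend on input row order.
#'
#' @param stats Tibble of per-variant statistics with `variant_id`, `chr`,
#'   `pos`, `p` (e.g. from [cox_scan()]).
#' @param g A [geno_matrix()] covering the same variants (the LD reference).
#' @param p_index Index-variant p-value threshold.
#' @param r2_max r-squared at or above which a variant joins the clump (the
#'   PRS pipeline keeps variants with pairwise r-squared below this; the MR
#'   instrument selection uses a much stricter 0.001).
#' @param window_kb Clumping window in kilobases each side of the index.
#' @return List of class `clump_result`: `clumps` (tibble `index_variant`,
#'   `members` list-column), `index_variants`, and the thresholds used. No
#'   variant below `p_index` yields an empty result, not an error.
#' @export
clump <- function(stats, g, p_index = 1e-5, r2_max = 0.8,
                  window_kb = 10000) {
  check_cols(stats, c("variant_id", "chr", "pos", "p"), "`stats`")
  stats <- filter(stats, !is.na(.data$p), .data$p < p_index)
  stats <- arrange(stats, .data$p, .data$chr, .data$pos)
  stats <- filter(stats, .data$variant_id %in% g$variants$variant_id)
  res <- list()
  unassigned <- stats
  d <- g$dosages
  while (nrow(unassigned) > 0L) {
    index <- unassigned[1L, ]
    rest <- unassigned[-1L, , drop = FALSE]
    near <- rest$chr == index$chr &
      abs(rest$pos - index$pos) <= window_kb * 1000
    members <- character(0)
    if (any(near)) {
      jx <- match(index$variant_id, g$variants$variant_id)
      jn <- match(rest$variant_id[near], g$variants$variant_id)
      r2 <- r2_vector(d, jx, jn)
      members <- rest$variant_id[near][r2 >= r2_max]
    }
    res[[length(res) + 1L]] <- tibble(index_variant = index$variant_id,
                                      members = list(members))
    unassigned <- rest[!(rest$variant_id %in% members), , drop = FALSE]
  }
  clumps <- if (length(res)) bind_rows(res) else
    tibble(index_variant = character(0), members = list())
  structure(list(clumps = clumps,
                 index_variants = clumps$index_variant,
                 p_index = p_index, r2_max = r2_max, window_kb = window_kb),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf(
    "<clump_result> %d clumps (p < %g, r2 >= %g, window %g kb)\n",
    nrow(x$clumps), x$p_index, x$r2_max, x$window_kb))
  invisible(x)
}

#' Score samples with a PRS model
#'
#' `score_j = sum_i weight_i * dosage_ij` after aligning each model entry's
#' effect allele to the matrix (dosage flipped to `2 - dosage` when the
#' model's effect allele is the matrix's other allele). Missing dosages are
#' imputed as twice the effect-allele frequency of the aligned allele.
#'
#' @param g A [geno_matrix()].
#' @param model A [prs_model()] (or tibble with its columns).
#' @param max_missing_frac Hard-error threshold on the fraction of model
#'   variants absent from the matrix (default 0.2).
#' @return Tibble `sample_id`, `score`, `n_imputed`; absent model variants
#'   are listed in the `missing_variants` attribute.
#' @export
compute_prs <- function(g, model, max_missing_frac = 0.2) {
  model <- as_tibble(model)
  check_cols(model, c("variant_id", "effect_allele", "weight"), "`model`")
  idx <- match(model$variant_id, g$variants$variant_id)
  absent <- model$variant_id[is.na(idx)]
  if (length(absent) > max_missing_frac * nrow(model)) {
    abort_input(sprintf(
      "%d of %d model variants absent from the genotype matrix",
      length(absent), nrow(model)), class = "onsetprs_missing_variants")
  }
  present <- !is.na(idx)
  score <- rep(0, length(g$samples))
  n_imp <- rep(0L, length(g$samples))
  for (k in which(present)) {
    j <- idx[k]
    dos <- g$dosages[, j]
    mat_ea <- g$variants$effect_allele[j]
    mat_oa <- g$variants$other_allele[j]
    if (model$effect_allele[k] == mat_ea) {
      # orientation matches
    } else if (model$effect_allele[k] == mat_oa) {
      dos <- 2 - dos
    } else {
      absent <- c(absent, model$variant_id[k])
      next
    }
    eaf <- mean(dos, na.rm = TRUE) / 2
    miss <- is.na(dos)
    if (any(miss)) {
      dos[miss] <- 2 * eaf
      n_imp <- n_imp + miss
    }
    score <- score + model$weight[k] * dos
  }
  if (length(absent) > max_missing_frac * nrow(model)) {
    abort_input(sprintf(
      "%d of %d model variants unusable (absent or allele-mismatched)",
      length(absent), nrow(model)), class = "onsetprs_missing_variants")
  }
  out <- tibble(sample_id = g$samples, score = unname(score),
                n_imputed = as.integer(unname(n_imp)))
  attr(out, "missing_variants") <- absent
  out
}

#' Standardize scores and assign reference-based quintiles
#'
#' Z-scores use the reference mean and SD; quintile cut points are the
#' reference 20/40/60/80 percentiles with left-open, right-closed intervals
#' (except the lowest, which is unbounded below): a score equal to the
#' 40th-percentile cut falls in quintile 2.
#'
#' @param scores Numeric scores to classify.
#' @param reference_scores Scores of the reference (general) population.
#' @return Tibble `score`, `z`, `quintile` (integer 1-5).
#' @export
standardize_and_quintile <- function(scores, reference_scores) {
  if (length(reference_scores) == 0L) {
    abort_input("reference scores are empty")
  }
  s <- sd(reference_scores)
  if (is.na(s) || s == 0) {
    abort_input("reference scores have zero variance",
                class = "onsetprs_degenerate_reference")
  }
  cuts <- quantile(reference_scores, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  tibble(score = scores,
         z = (scores - mean(reference_scores)) / s,
         quintile = as.integer(1L + rowSums(outer(scores, cuts, ">"))))
}

#' Merge a reported PRS with scan-derived hits
#'
#' The merged model is the union of the reported entries (weights are the
#' log of the reported odds ratios, i.e. the weights already in `reported`)
#' and those GWAS hits whose r-squared with every reported variant (same
#' chromosome, computed in `g`) is below `r2_replace`. Hits at or above the
#' threshold are dropped — replaced by the reported variant tagging them —
#' and the absorbing reported entries are marked `merged-replaced`.
#'
#' @param reported A [prs_model()] of established variants.
#' @param gwas_hits Tibble of scan hits with `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`.
#' @param g A [geno_matrix()] containing both variant sets (the LD
#'   reference).
#' @param r2_replace Replacement threshold in (0, 1], default 0.8.
#' @return A [prs_model()]; the `replaced` attribute maps each dropped hit
#'   to the reported variant that absorbed it.
#' @export
merge_prs <- function(reported, gwas_hits, g, r2_replace = 0.8) {
  if (!(r2_replace > 0 && r2_replace <= 1)) {
    abort_config("`r2_replace` must lie in (0, 1]", field = "r2_replace")
  }
  reported <- as_tibble(reported)
  check_cols(reported, c("variant_id", "effect_allele", "weight"),
             "`reported`")
  check_cols(gwas_hits, c("variant_id", "chr", "pos", "effect_allele",
                          "beta"), "`gwas_hits`")
  gwas_hits <- filter(gwas_hits,
                      !(.data$variant_id %in% reported$variant_id))
  rep_meta <- left_join(reported["variant_id"],
                        g$variants[, c("variant_id", "chr", "pos")],
                        by = "variant_id")
  d <- g$dosages
  replaced <- tibble(gwas_variant = character(0),
                     reported_variant = character(0), r2 = numeric(0))
  keep <- rep(TRUE, nrow(gwas_hits))
  for (k in seq_len(nrow(gwas_hits))) {
    jg <- match(gwas_hits$variant_id[k], g$variants$variant_id)
    if (is.na(jg)) next
    same_chr <- which(!is.na(rep_meta$chr) &
                        rep_meta$chr == gwas_hits$chr[k])
    if (length(same_chr) == 0L) next
    jr <- match(rep_meta$variant_id[same_chr], g$variants$variant_id)
    ok <- !is.na(jr)
    if (!any(ok)) next
    r2 <- r2_vector(d, jg, jr[ok])
    hit <- which(r2 >= r2_replace)
    if (length(hit)) {
      best <- hit[which.max(r2[hit])]
      keep[k] <- FALSE
      replaced <- bind_rows(replaced, tibble(
        gwas_variant = gwas_hits$variant_id[k],
        reported_variant = rep_meta$variant_id[same_chr][ok][best],
        r2 = r2[best]))
    }
  }
  rep_entries <- mutate(
    reported,
    provenance = ifelse(.data$variant_id %in% replaced$reported_variant,
                        "merged-replaced", "reported"))
  hit_entries <- mutate(
    select(gwas_hits[keep, , drop = FALSE],
           dplyr::any_of(c("variant_id", "chr", "pos", "effect_allele",
                           "other_allele")), weight = "beta"),
    provenance = "gwas")
  out <- prs_model(bind_rows(rep_entries, hit_entries), name = "merged")
  attr(out, "replaced") <- replaced
  out
}
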