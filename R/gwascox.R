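# Variant QC, exit-age population splitting, and per-variant Cox
# proportional-hazards scans on the age timescale (left truncation at entry).

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts by point-probability summation
#' over all heterozygote counts compatible with the observed allele counts
#' (the chi-square approximation misbehaves at the extreme tail where the
#' QC threshold sits).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom-ref, het, hom-alt) among
#'   non-missing calls.
#' @return Exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab
  rare <- min(n_a, 2L * n - n_a)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log point probability of each compatible het count, then normalize
  logp <- vapply(hets, function(h) {
    r_hom <- (rare - h) / 2
    c_hom <- (2L * n - rare - h) / 2
    lgamma(n + 1) - lgamma(r_hom + 1) - lgamma(c_hom + 1) - lgamma(h + 1) +
      h * log(2)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- min(n_ab, rare)
  p_obs <- prob[match(obs, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Removes variants failing any of: minor allele frequency below `maf_min`,
#' exact Hardy-Weinberg p-value below `hwe_p_min`, or call rate not above
#' `call_rate_min`. Criteria are evaluated jointly on the input, so the
#' result does not depend on any filtering order.
#'
#' @param g A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (kept when `maf >= maf_min`).
#' @param hwe_p_min Minimum exact HWE p-value (kept when `p >= hwe_p_min`).
#' @param call_rate_min Call-rate threshold (kept when strictly above).
#' @return The filtered `geno_matrix`, with a tibble attribute `qc_report`
#'   (`variant_id`, `maf`, `call_rate`, `hwe_p`, `removed`, `reason`).
#' @export
variant_qc <- function(g, maf_min = 0.01, hwe_p_min = 1e-6,
                       call_rate_min = 0.95) {
  if (ncol(g$dosages) == 0L || nrow(g$dosages) == 0L) {
    abort_input("empty genotype matrix", class = "onsetprs_empty_input")
  }
  check_prob(maf_min, "maf_min"); check_prob(hwe_p_min, "hwe_p_min")
  check_prob(call_rate_min, "call_rate_min")
  fr <- variant_freq(g)
  d <- g$dosages
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  report <- mutate(
    fr,
    hwe_p = hwe,
    fail_maf = is.na(.data$maf) | .data$maf < maf_min,
    fail_hwe = is.na(hwe) | hwe < hwe_p_min,
    fail_call = .data$call_rate <= call_rate_min
  )
  report <- mutate(
    report,
    removed = .data$fail_maf | .data$fail_hwe | .data$fail_call,
    reason = purrr::pmap_chr(
      list(.data$fail_maf, .data$fail_hwe, .data$fail_call),
      function(m, h, c) paste(c(if (m) "maf", if (h) "hwe",
                                if (c) "call_rate"), collapse = ";"))
  )
  report <- select(report, "variant_id", "maf", "call_rate", "hwe_p",
                   "removed", "reason")
  out <- subset_variants(g, which(!report$removed))
  attr(out, "qc_report") <- report
  out
}

#' Split a follow-up cohort by exit age
#'
#' Early-onset (EO) subjects have `exit_age <= age_cut` (closed boundary),
#' late-onset (LO) subjects `exit_age > age_cut`; the partition is
#' exhaustive and disjoint.
#'
#' @param cohort Tibble with at least `exit_age`.
#' @param age_cut Split age in years (default 55).
#' @return Named list of tibbles `eo` and `lo`, each with a
#'   `population_label` column.
#' @export
split_population <- function(cohort, age_cut = 55) {
  if (!is.numeric(age_cut) || age_cut <= 0) {
    abort_config("`age_cut` must be positive", field = "age_cut")
  }
  check_cols(cohort, "exit_age", "`cohort`")
  is_eo <- cohort$exit_age <= age_cut
  list(eo = mutate(cohort[is_eo, , drop = FALSE], population_label = "EO"),
       lo = mutate(cohort[!is_eo, , drop = FALSE], population_label = "LO"))
}

#' Assign arbitrary exit-age bins
#'
#' Supports piecewise age-group analyses: subjects fall in left-open,
#' right-closed intervals between consecutive breaks (the same convention
#' as [split_population()]).
#'
#' @param cohort Tibble with `exit_age`.
#' @param breaks Increasing numeric break ages.
#' @return The cohort with an `age_group` factor column.
#' @export
bin_population <- function(cohort, breaks) {
  check_cols(cohort, "exit_age", "`cohort`")
  mutate(cohort, age_group = cut(.data$exit_age,
                                 breaks = c(-Inf, sort(breaks), Inf),
                                 right = TRUE))
}

#' Split a case-control table by reference age
#'
#' Reference age is the age at diagnosis for cases and at censoring for
#' controls; grouping uses the same closed-at-the-cut convention as
#' [split_population()]. The General group is the whole table.
#'
#' @param cc Tibble with a `reference_age` column.
#' @param age_cut Split age in years (default 55).
#' @return Named list of tibbles `general`, `eo`, `lo`.
#' @export
split_case_control <- function(cc, age_cut = 55) {
  check_cols(cc, "reference_age", "`cc`")
  if (anyNA(cc$reference_age)) {
    bad <- which(is.na(cc$reference_age))
    abort_input(sprintf("`reference_age` missing in row(s) %s",
                        paste(head(bad, 5L), collapse = ", ")),
                class = "onsetprs_row_validation_error")
  }
  is_eo <- cc$reference_age <= age_cut
  list(general = mutate(cc, population_label = "General"),
       eo = mutate(cc[is_eo, , drop = FALSE], population_label = "EO"),
       lo = mutate(cc[!is_eo, , drop = FALSE], population_label = "LO"))
}

# single Cox fit; returns beta/se/p/converged for the first coefficient
fit_cox_one <- function(df, covariate_names, weights = NULL,
                        iter_max = 25L) {
  covs <- if (length(covariate_names)) {
    paste("+", paste(covariate_names, collapse = " + "))
  } else ""
  f <- stats::as.formula(paste(
    "survival::Surv(entry_age, exit_age, event) ~ x", covs))
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  df$.id <- seq_len(nrow(df))  # robust sandwich needs per-subject clusters
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      if (is.null(weights)) {
        survival::coxph(f, data = df, weights = .w, ties = "efron",
                        control = survival::coxph.control(
                          iter.max = iter_max, eps = 1e-9))
      } else {
        survival::coxph(f, data = df, weights = .w, ties = "efron",
                        robust = TRUE, cluster = .id,
                        control = survival::coxph.control(
                          iter.max = iter_max, eps = 1e-9))
      },
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge|infinite|loglik", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || is.na(coef(fit)[1])) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE, fit = NULL))
  }
  s <- summary(fit)$coefficients
  se_col <- if ("robust se" %in% colnames(s)) "robust se" else "se(coef)"
  beta <- unname(coef(fit)[1])
  se <- unname(s[1, se_col])
  list(beta = beta, se = se,
       p = 2 * pnorm(-abs(beta / se)),
       converged = converged, fit = fit)
}

#' Genome-wide Cox proportional-hazards scan
#'
#' Fits, per variant, a Cox model for `event ~ dosage + covariates` on the
#' age timescale `(entry_age, exit_age]` (Efron tie handling; with
#' per-sample `weights`, the weighted partial likelihood with a robust
#' sandwich SE). Samples with a missing dosage are dropped for that variant
#' only; rows with missing covariates are dropped globally and counted.
#'
#' @param g A [geno_matrix()].
#' @param cohort Tibble with `sample_id`, `entry_age`, `exit_age`, `event`
#'   and any covariate columns; sample ids must match `g`.
#' @param covariate_names Character vector of covariate columns (may be
#'   empty).
#' @param weights Optional per-sample weights aligned with `cohort`.
#' @return Tibble of per-variant summary statistics (`variant_id`, `chr`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`,
#'   `converged`); monomorphic variants are flagged rows with missing
#'   `beta`. Attribute `n_dropped_covariates` counts globally dropped rows.
#' @export
cox_scan <- function(g, cohort, covariate_names = character(),
                     weights = NULL) {
  check_cols(cohort, c("sample_id", "entry_age", "exit_age", "event"),
             "`cohort`")
  check_cols(cohort, covariate_names, "`cohort`")
  if (!setequal(cohort$sample_id, g$samples)) {
    abort_input("cohort and genotype samples do not match")
  }
  g <- subset_samples(g, match(cohort$sample_id, g$samples))
  keep <- stats::complete.cases(cohort[, c("entry_age", "exit_age", "event",
                                           covariate_names), drop = FALSE])
  n_dropped <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(keep))
    weights <- weights[keep]
  }
  g <- subset_samples(g, which(keep))
  if (sum(cohort$event) == 0L) {
    abort_input("cohort contains no events", class = "onsetprs_no_events")
  }
  base <- cohort[, c("entry_age", "exit_age", "event", covariate_names),
                 drop = FALSE]
  res <- purrr::map(seq_len(ncol(g$dosages)), function(j) {
    x <- g$dosages[, j]
    ok <- !is.na(x)
    eaf_j <- mean(x[ok]) / 2
    if (!any(ok) || var(x[ok]) == 0) {
      return(tibble(eaf = ifelse(any(ok), eaf_j, NA_real_),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = as.integer(sum(ok)), converged = FALSE))
    }
    df <- base[ok, , drop = FALSE]
    df$x <- x[ok]
    w <- if (is.null(weights)) NULL else weights[ok]
    f <- fit_cox_one(df, covariate_names, w)
    tibble(eaf = eaf_j, beta = f$beta, se = f$se, p = f$p,
           n = as.integer(sum(ok)), converged = f$converged)
  })
  out <- dplyr::bind_cols(
    g$variants[, c("variant_id", "chr", "pos", "effect_allele",
                   "other_allele")],
    bind_rows(res)
  )
  attr(out, "n_dropped_covariates") <- n_dropped
  out
}
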