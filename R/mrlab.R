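# Two-sample MR: instrument selection by strict clumping, allele
# harmonization, IVW / weighted-median / MR-Egger estimation, Cochran's Q
# over Wald ratios, and the high-confidence trait filter.

#' Select MR instruments by strict clumping
#'
#' Greedy clumping of the exposure summary statistics (reusing [clump()])
#' at genome-wide significance with a near-zero LD ceiling: index variants
#' with `p < p_max`, window `window_kb`, and members absorbed at
#' `r2 >= r2_max`. The retained index variants are the instruments.
#'
#' @param exposure_stats Tibble with `variant_id`, `chr`, `pos`, `p`.
#' @param reference A [geno_matrix()] LD reference panel covering the
#'   exposure variants.
#' @param p_max Instrument p-value ceiling (default 5e-8).
#' @param r2_max LD ceiling (default 0.001).
#' @param window_kb Clumping window (default 10,000 kb = 10 Mb).
#' @return Character vector of instrument variant ids (possibly empty).
#' @export
select_instruments <- function(exposure_stats, reference, p_max = 5e-8,
                               r2_max = 0.001, window_kb = 10000) {
  clump(exposure_stats, reference, p_index = p_max, r2_max = r2_max,
        window_kb = window_kb)$index_variants
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on `variant_id` and aligns the outcome effect to
#' the exposure's effect allele: matching alleles are kept as-is; swapped
#' alleles flip the outcome beta (and `eaf -> 1 - eaf`); strand flips are
#' resolved by complementing and re-checking. Palindromic (A/T, C/G)
#' variants, for which swap and strand flip are indistinguishable, are
#' aligned by allele frequency and dropped as ambiguous when
#' `min(eaf, 1 - eaf) > ambiguous_eaf` on either side. Irreconcilable
#' alleles are dropped with a reason.
#'
#' @param exposure,outcome Summary-statistic tibbles with `variant_id`,
#'   `ea`, `oa`, `eaf`, `beta`, `se`, `p`.
#' @param ambiguous_eaf Palindromic ambiguity threshold on EAF
#'   (default 0.42).
#' @return List of class `mr_dataset`: `instruments` (tibble with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `palindromic`, `action`)
#'   and `dropped` (tibble with reasons).
#' @export
harmonize <- function(exposure, outcome, ambiguous_eaf = 0.42) {
  for (df in list(exposure, outcome)) {
    check_cols(df, c("variant_id", "ea", "oa", "eaf", "beta", "se"),
               "summary statistics")
  }
  j <- dplyr::inner_join(
    rename(exposure, ea_exp = "ea", oa_exp = "oa", eaf_exp = "eaf",
           beta_exp = "beta", se_exp = "se"),
    rename(select(outcome, dplyr::any_of(c("variant_id", "ea", "oa", "eaf",
                                           "beta", "se"))),
           ea_out = "ea", oa_out = "oa", eaf_out = "eaf",
           beta_out = "beta", se_out = "se"),
    by = "variant_id")
  rows <- purrr::pmap(j, function(variant_id, ea_exp, oa_exp, eaf_exp,
                                  beta_exp, se_exp, ea_out, oa_out, eaf_out,
                                  beta_out, se_out, ...) {
    palin <- is_palindromic(ea_exp, oa_exp)
    flip <- NA  # NA = unresolved
    action <- NULL
    if (palin) {
      if (!setequal(c(ea_out, oa_out), c(ea_exp, oa_exp))) {
        return(list(drop = "irreconcilable alleles"))
      }
      if (min(eaf_exp, 1 - eaf_exp) > ambiguous_eaf ||
          min(eaf_out, 1 - eaf_out) > ambiguous_eaf) {
        return(list(drop = "palindromic ambiguous"))
      }
      # align by frequency: effect alleles agree iff eafs sit on the same
      # side of 0.5
      same_letter <- ea_out == ea_exp
      eaf_out_oriented <- if (same_letter || ea_out == COMPLEMENT[ea_exp]) {
        eaf_out
      } else {
        1 - eaf_out
      }
      flip <- (eaf_exp - 0.5) * (eaf_out_oriented - 0.5) < 0
      action <- if (flip) "palindromic-flipped" else "palindromic-kept"
    } else {
      if (ea_out == ea_exp && oa_out == oa_exp) {
        flip <- FALSE; action <- "kept"
      } else if (ea_out == oa_exp && oa_out == ea_exp) {
        flip <- TRUE; action <- "flipped"
      } else {
        ea_c <- unname(COMPLEMENT[ea_out]); oa_c <- unname(COMPLEMENT[oa_out])
        if (identical(ea_c, ea_exp) && identical(oa_c, oa_exp)) {
          flip <- FALSE; action <- "strand-resolved"
        } else if (identical(ea_c, oa_exp) && identical(oa_c, ea_exp)) {
          flip <- TRUE; action <- "strand-resolved-flipped"
        } else {
          return(list(drop = "irreconcilable alleles"))
        }
      }
    }
    list(row = tibble(
      variant_id = variant_id, ea = ea_exp, oa = oa_exp,
      eaf_exp = eaf_exp,
      eaf_out = if (flip) 1 - eaf_out else eaf_out,
      beta_exp = beta_exp, se_exp = se_exp,
      beta_out = if (flip) -beta_out else beta_out, se_out = se_out,
      palindromic = palin, action = action))
  })
  dropped <- tibble(
    variant_id = j$variant_id[vapply(rows, function(r) !is.null(r$drop),
                                     logical(1))],
    reason = unlist(lapply(rows, `[[`, "drop")))
  kept <- bind_rows(lapply(rows, `[[`, "row"))
  structure(list(instruments = kept, dropped = dropped),
            class = "mr_dataset")
}

as_mr_instruments <- function(d) {
  if (inherits(d, "mr_dataset")) d <- d$instruments
  d <- as_tibble(d)
  check_cols(d, c("beta_exp", "se_exp", "beta_out", "se_out"),
             "MR instruments")
  d
}

# Wald ratios with first-order SE; instruments with a zero exposure effect
# are dropped with a warning
wald_ratios <- function(d) {
  zero <- d$beta_exp == 0
  if (any(zero)) {
    rlang::warn(sprintf("dropping %d instrument(s) with zero exposure effect",
                        sum(zero)))
    d <- d[!zero, , drop = FALSE]
  }
  mutate(d, ratio = .data$beta_out / .data$beta_exp,
         ratio_se = .data$se_out / abs(.data$beta_exp))
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW over per-instrument Wald ratios
#' (`ratio = beta_out / beta_exp`, first-order SE
#' `se_out / |beta_exp|`): the inverse-variance-weighted mean, equivalently
#' weighted least squares through the origin. The multiplicative
#' random-error variant inflates the SE by `sqrt(max(1, Q/df))`.
#'
#' @param d An `mr_dataset` from [harmonize()] or a tibble with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`.
#' @param model `"fixed"` (default) or `"mre"`.
#' @return List `estimate`, `se`, `p`, `n_iv`, plus `ratios` (per-IV
#'   tibble).
#' @export
mr_ivw <- function(d, model = c("fixed", "mre")) {
  model <- match.arg(model)
  d <- wald_ratios(as_mr_instruments(d))
  if (nrow(d) < 1L) {
    abort_input("IVW needs at least 1 instrument",
                class = "onsetprs_insufficient_instruments")
  }
  w <- 1 / d$ratio_se^2
  est <- sum(w * d$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (model == "mre" && nrow(d) >= 2L) {
    q <- sum(w * (d$ratio - est)^2)
    se <- se * sqrt(max(1, q / (nrow(d) - 1L)))
  }
  list(estimate = est, se = se, p = 2 * pnorm(-abs(est / se)),
       n_iv = nrow(d), ratios = d)
}

#' Weighted-median MR estimate
#'
#' Orders the Wald ratios and takes the value at which the normalized
#' cumulative inverse-variance weight crosses one half (linear
#' interpolation between bracketing ratios); consistent when at least half
#' the weight comes from valid instruments. The SE is a seeded parametric
#' bootstrap (instrument effects resampled from their normal errors).
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List `estimate`, `se`, `p`, `n_iv`.
#' @export
mr_weighted_median <- function(d, n_boot = 1000, seed = 1L) {
  d <- as_mr_instruments(d)
  if (nrow(d) < 3L) {
    abort_input("weighted median needs at least 3 instruments",
                class = "onsetprs_insufficient_instruments")
  }
  point <- weighted_median_point(d)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      db <- mutate(d,
                   beta_exp = .data$beta_exp + rnorm(dplyr::n()) * .data$se_exp,
                   beta_out = .data$beta_out + rnorm(dplyr::n()) * .data$se_out)
      weighted_median_point(db)
    }, numeric(1))
  })
  se <- sd(boot)
  list(estimate = point, se = se,
       p = 2 * pnorm(-abs(point / se)), n_iv = nrow(d))
}

weighted_median_point <- function(d) {
  r <- wald_ratios(d)
  ord <- order(r$ratio)
  ratio <- r$ratio[ord]
  w <- (1 / r$ratio_se^2)[ord]
  cum <- (cumsum(w) - w / 2) / sum(w)
  if (cum[1] >= 0.5) return(ratio[1])
  if (cum[length(cum)] <= 0.5) return(ratio[length(ratio)])
  approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

#' MR-Egger regression
#'
#' Weighted least squares of the sign-oriented outcome effects
#' (`beta_out * sign(beta_exp)`) on `|beta_exp|` with an intercept, weights
#' `1/se_out^2`. A non-zero intercept indexes directional pleiotropy; its
#' test is a two-sided t at `n_iv - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return List `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`, `n_iv`.
#' @export
mr_egger <- function(d) {
  d <- as_mr_instruments(d)
  if (nrow(d) < 3L) {
    abort_input("MR-Egger needs at least 3 instruments",
                class = "onsetprs_insufficient_instruments")
  }
  x <- abs(d$beta_exp)
  y <- d$beta_out * sign(d$beta_exp)
  fit <- lm(y ~ x, weights = 1 / d$se_out^2)
  s <- summary(fit)$coefficients
  df <- nrow(d) - 2L
  list(slope = s["x", "Estimate"], slope_se = s["x", "Std. Error"],
       slope_p = 2 * pt(-abs(s["x", "t value"]), df),
       intercept = s["(Intercept)", "Estimate"],
       intercept_se = s["(Intercept)", "Std. Error"],
       intercept_p = 2 * pt(-abs(s["(Intercept)", "t value"]), df),
       n_iv = nrow(d))
}

#' Cochran's Q over Wald ratios
#'
#' Heterogeneity of the per-instrument ratios about the IVW estimate, with
#' IVW weights; a chi-square test at `n_iv - 1` degrees of freedom. Large Q
#' flags instruments acting through divergent pathways.
#'
#' @inheritParams mr_ivw
#' @return List `Q`, `df`, `p`.
#' @export
mr_heterogeneity_q <- function(d) {
  d <- as_mr_instruments(d)
  if (nrow(d) < 2L) {
    abort_input("heterogeneity needs at least 2 instruments",
                class = "onsetprs_insufficient_instruments")
  }
  ivw <- mr_ivw(d)
  r <- ivw$ratios
  w <- 1 / r$ratio_se^2
  q <- sum(w * (r$ratio - ivw$estimate)^2)
  df <- nrow(r) - 1L
  list(Q = q, df = df, p = pchisq(q, df, lower.tail = FALSE))
}

#' Full MR analysis of one exposure-outcome pair
#'
#' Runs IVW, weighted median, MR-Egger and Cochran's Q on a harmonized
#' dataset and applies the high-confidence filter.
#'
#' @inheritParams mr_weighted_median
#' @param exposure_id,outcome_id Labels stored on the result.
#' @return Object of class `mr_result` with elements `ivw`,
#'   `weighted_median`, `egger`, `q`, `n_iv`, `high_confidence`, `reasons`.
#' @export
mr_analyze <- function(d, exposure_id = "exposure", outcome_id = "outcome",
                       n_boot = 1000, seed = 1L) {
  d <- as_mr_instruments(d)
  res <- structure(list(
    exposure_id = exposure_id, outcome_id = outcome_id,
    ivw = mr_ivw(d),
    weighted_median = mr_weighted_median(d, n_boot = n_boot, seed = seed),
    egger = mr_egger(d),
    q = mr_heterogeneity_q(d),
    n_iv = nrow(d)
  ), class = "mr_result")
  hc <- high_confidence_filter(res)
  res$high_confidence <- hc$high_confidence
  res$reasons <- hc$reasons
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> %s -> %s (%d IVs): IVW %.3f (p=%.3g), WM %.3f (p=%.3g), Egger intercept p=%.3g, Q p=%.3g; high-confidence: %s\n",
    x$exposure_id, x$outcome_id, x$n_iv,
    x$ivw$estimate, x$ivw$p,
    x$weighted_median$estimate, x$weighted_median$p,
    x$egger$intercept_p, x$q$p,
    ifelse(isTRUE(x$high_confidence), "yes",
           paste0("no (", paste(x$reasons, collapse = "; "), ")"))))
  invisible(x)
}

#' High-confidence MR filter
#'
#' A result is high-confidence iff (1) the IVW and weighted-median
#' estimates are directionally concordant and both have p < 0.05, and
#' (2) the heterogeneity and MR-Egger intercept p-values are both >= 0.05.
#' Boundaries are exact: p = 0.05 fails the effect tests and passes the
#' nuisance tests.
#'
#' @param r An `mr_result`, or a list with components `ivw` (`estimate`,
#'   `p`), `weighted_median` (`estimate`, `p`), `egger` (`intercept_p`) and
#'   `q` (`p`).
#' @return List `high_confidence` (logical) and `reasons` (character,
#'   empty when the flag is true).
#' @export
high_confidence_filter <- function(r) {
  need <- list(c("ivw", "estimate"), c("ivw", "p"),
               c("weighted_median", "estimate"), c("weighted_median", "p"),
               c("egger", "intercept_p"), c("q", "p"))
  for (path in need) {
    v <- r[[path[1]]][[path[2]]]
    if (is.null(v) || is.na(v)) {
      abort_input(sprintf("missing component `%s$%s`", path[1], path[2]))
    }
  }
  reasons <- character(0)
  if (sign(r$ivw$estimate) != sign(r$weighted_median$estimate)) {
    reasons <- c(reasons, "directional discordance")
  }
  if (r$ivw$p >= 0.05) reasons <- c(reasons, "ivw not significant")
  if (r$weighted_median$p >= 0.05) {
    reasons <- c(reasons, "weighted median not significant")
  }
  if (r$q$p < 0.05) reasons <- c(reasons, "heterogeneity")
  if (r$egger$intercept_p < 0.05) {
    reasons <- c(reasons, "pleiotropy")
  }
  list(high_confidence = length(reasons) == 0L, reasons = reasons)
}
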