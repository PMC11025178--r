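# Incidence-based sampling weights and effect estimation for PRS exposures:
# weighted Cox (cases weight 1, non-cases 1/inc_t) with sandwich variance,
# logistic re-analysis, CI<->SE conversion and EO-vs-LO heterogeneity.

new_effect_estimate <- function(beta, se, p, n, n_events, model_tag,
                                population_tag = NA_character_,
                                flags = character(0), fit = NULL) {
  structure(list(
    beta = beta, se = se, hr_or = exp(beta),
    ci_low = exp(beta - qnorm(0.975) * se),
    ci_high = exp(beta + qnorm(0.975) * se),
    p = p, n = n, n_events = n_events,
    model_tag = model_tag, population_tag = population_tag,
    flags = flags, fit = fit
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "<effect_estimate:%s%s> %s = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d (%d events)%s\n",
    x$model_tag,
    if (!is.na(x$population_tag)) paste0("/", x$population_tag) else "",
    if (x$model_tag == "logistic") "OR" else "HR",
    x$hr_or, x$ci_low, x$ci_high, x$p, x$n, x$n_events,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Interpolate banded incidence rates to per-year rates
#'
#' Each band's rate is anchored at an age within the band (its midpoint by
#' default, the least-surprising reading of per-band rates; band-start
#' anchoring is available behind the `anchor` switch) and per-year rates
#' follow by linear interpolation between adjacent anchors, with flat
#' extrapolation outside the outermost anchors.
#'
#' @param bands Tibble with `age_start`, `age_end`, `rate_per_100k`
#'   (non-overlapping ascending bands).
#' @param anchor `"midpoint"` (default) or `"band_start"`.
#' @param ages Integer ages the per-year table covers (default 32-87).
#' @return List of class `incidence_schedule`: `bands`, `per_year` (tibble
#'   `age`, `rate_per_100k`) and `rate_at(age)`, a function of continuous
#'   age.
#' @export
interpolate_incidence <- function(bands, anchor = c("midpoint", "band_start"),
                                  ages = 32:87) {
  anchor <- match.arg(anchor)
  bands <- arrange(as_tibble(bands), .data$age_start)
  check_cols(bands, c("age_start", "age_end", "rate_per_100k"), "`bands`")
  if (nrow(bands) < 2L) abort_input("need at least 2 incidence bands")
  if (any(bands$rate_per_100k < 0)) {
    abort_input("incidence rates must be non-negative")
  }
  if (any(head(bands$age_end, -1) > tail(bands$age_start, -1))) {
    abort_input("incidence bands must be non-overlapping and ascending")
  }
  anchors <- if (anchor == "midpoint") {
    (bands$age_start + bands$age_end) / 2
  } else {
    bands$age_start
  }
  rate_at <- function(age) {
    approx(anchors, bands$rate_per_100k, xout = age, rule = 2)$y
  }
  structure(list(
    bands = bands, anchor = anchor,
    per_year = tibble(age = as.integer(ages), rate_per_100k = rate_at(ages)),
    rate_at = rate_at
  ), class = "incidence_schedule")
}

#' @export
print.incidence_schedule <- function(x, ...) {
  cat(sprintf(
    "<incidence_schedule> %d bands, %s-anchored, per-year ages %d-%d\n",
    nrow(x$bands), x$anchor, min(x$per_year$age), max(x$per_year$age)))
  invisible(x)
}

#' Incidence-based sampling weights
#'
#' Cases get weight 1; non-cases get `1/inc_t`, where `inc_t` is the
#' per-year incidence expressed as a proportion (rate per 100,000 divided
#' by 100,000) at the integer part of the subject's exit age, clamped to
#' the schedule's age range. Optionally the non-case weights are rescaled
#' to mean 1 (point estimates are invariant to any positive rescaling of
#' the weights; only the absolute scale changes).
#'
#' @param cohort Tibble with `exit_age` and `event`.
#' @param sched An [interpolate_incidence()] schedule.
#' @param normalize Rescale non-case weights to mean 1 (default `FALSE`).
#' @return Numeric weight vector aligned with `cohort`.
#' @export
make_weights <- function(cohort, sched, normalize = FALSE) {
  check_cols(cohort, c("exit_age", "event"), "`cohort`")
  stopifnot(inherits(sched, "incidence_schedule"))
  age <- pmin(pmax(age_year(cohort$exit_age), min(sched$per_year$age)),
              max(sched$per_year$age))
  rate <- sched$per_year$rate_per_100k[match(age, sched$per_year$age)]
  inc_t <- rate / 1e5
  noncase <- cohort$event == 0L
  if (any(noncase & inc_t == 0)) {
    abort_input("zero incidence at an age needed for a non-case weight",
                class = "onsetprs_zero_incidence")
  }
  w <- ifelse(noncase, 1 / inc_t, 1)
  if (normalize && any(noncase)) {
    w[noncase] <- w[noncase] / mean(w[noncase])
  }
  w
}

#' Incidence-weighted Cox fit for a PRS exposure
#'
#' Maximizes the weighted Cox partial likelihood (Efron ties) of
#' `event ~ exposure + covariates` on the age timescale, with a robust
#' sandwich variance (the sampling weights make the fit a pseudo-likelihood,
#' so a model-based variance would be anti-conservative). When
#' `reference_scores` is supplied the exposure is standardized against it,
#' so the estimate is per reference-population SD.
#'
#' @param cohort Tibble with `entry_age`, `exit_age`, `event` and the
#'   covariate columns.
#' @param exposure Per-sample numeric score aligned with `cohort`.
#' @param covariate_names Covariate columns to adjust for.
#' @param weights Per-sample weights (e.g. from [make_weights()]); `NULL`
#'   for an unweighted fit.
#' @param reference_scores Optional scores defining the standardization.
#' @param population_tag Label stored on the estimate.
#' @return An `effect_estimate` (see [tidy.effect_estimate()]).
#' @export
weighted_cox_fit <- function(cohort, exposure,
                             covariate_names = character(),
                             weights = NULL, reference_scores = NULL,
                             population_tag = NA_character_) {
  check_cols(cohort, c("entry_age", "exit_age", "event"), "`cohort`")
  check_cols(cohort, covariate_names, "`cohort`")
  stopifnot(length(exposure) == nrow(cohort))
  if (sum(cohort$event) < 1L) {
    abort_input("cohort contains no events", class = "onsetprs_no_events")
  }
  x <- if (!is.null(reference_scores)) {
    standardize_and_quintile(exposure, reference_scores)$z
  } else {
    exposure
  }
  df <- cohort[, c("entry_age", "exit_age", "event", covariate_names),
               drop = FALSE]
  df$x <- x
  ok <- stats::complete.cases(df)
  df <- df[ok, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[ok]
  f <- fit_cox_one(df, covariate_names, w)
  if (is.null(f$fit)) {
    abort_input("weighted Cox fit failed to produce an estimate",
                class = "onsetprs_nonconvergence")
  }
  flags <- character(0)
  if (!f$converged) flags <- c(flags, "nonconvergence")
  if (abs(f$beta) > 15) flags <- c(flags, "separation-like")
  new_effect_estimate(f$beta, f$se, f$p, n = nrow(df),
                      n_events = sum(df$event), model_tag = "wcox",
                      population_tag = population_tag, flags = flags,
                      fit = f$fit)
}

#' Logistic re-analysis for a case-control table
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of case status
#' on the exposure and covariates; odds ratio per exposure unit with a Wald
#' CI. Perfect separation yields a flagged result with no estimate rather
#' than a misleading one.
#'
#' @param cc Tibble with a binary `case` column and covariates.
#' @param exposure Numeric exposure aligned with `cc` (standardize first if
#'   a per-SD OR is wanted).
#' @param covariate_names Covariate columns.
#' @param population_tag Label stored on the estimate.
#' @return An `effect_estimate` with `model_tag = "logistic"`.
#' @export
logistic_fit <- function(cc, exposure, covariate_names = character(),
                         population_tag = NA_character_) {
  check_cols(cc, c("case", covariate_names), "`cc`")
  stopifnot(length(exposure) == nrow(cc))
  if (sd(exposure, na.rm = TRUE) %in% c(0, NA)) {
    abort_input("exposure is constant: no information",
                class = "onsetprs_no_information")
  }
  df <- cc[, c("case", covariate_names), drop = FALSE]
  df$x <- exposure
  df <- df[stats::complete.cases(df), , drop = FALSE]
  covs <- if (length(covariate_names)) {
    paste("+", paste(covariate_names, collapse = " + "))
  } else ""
  f <- stats::as.formula(paste("case ~ x", covs))
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(f, family = binomial(), data = df),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)[["x"]]
  se <- sqrt(diag(vcov(fit)))[["x"]]
  separated <- warned && (abs(beta) > 15 || se > 100)
  if (separated) {
    return(new_effect_estimate(NA_real_, NA_real_, NA_real_,
                               n = nrow(df), n_events = sum(df$case),
                               model_tag = "logistic",
                               population_tag = population_tag,
                               flags = "separation"))
  }
  new_effect_estimate(beta, se, 2 * pnorm(-abs(beta / se)),
                      n = nrow(df), n_events = sum(df$case),
                      model_tag = "logistic",
                      population_tag = population_tag,
                      flags = if (warned) "glm-warning" else character(0),
                      fit = fit)
}

#' Recover (log effect, SE) from a printed ratio and 95% CI
#'
#' Inverts the Wald construction: `beta = log(point)` and
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. This is how printed
#' HR/CI pairs are prepared for heterogeneity analysis.
#'
#' @param point,ci_low,ci_high Ratio-scale point estimate and 95% bounds
#'   (vectorized).
#' @return Tibble with `beta` and `se`.
#' @export
ci_to_se <- function(point, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_low > point) || any(point > ci_high)) {
    abort_input("need 0 < ci_low <= point <= ci_high")
  }
  tibble(beta = log(point),
         se = (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975)))
}

#' Cochran's Q and I-squared across effect estimates
#'
#' Fixed-effect heterogeneity: weights `1/se^2`, pooled mean, `Q` the
#' weighted sum of squared deviations, `I2 = max(0, (Q - df)/Q) * 100`, and
#' `p_het` from the upper chi-square tail at `k - 1` degrees of freedom.
#'
#' @param estimates Tibble (or data frame) with `beta` and `se` columns —
#'   e.g. the output of [ci_to_se()] on printed HR/CI pairs — or a list of
#'   `effect_estimate` objects.
#' @return List of class `het_result`: `Q`, `df`, `I2`, `p_het`, `inputs`.
#' @export
cochran_q <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "effect_estimate"))) {
    estimates <- tibble(
      beta = vapply(estimates, `[[`, numeric(1), "beta"),
      se = vapply(estimates, `[[`, numeric(1), "se"))
  }
  check_cols(estimates, c("beta", "se"), "`estimates`")
  k <- nrow(estimates)
  if (k < 2L) abort_input("heterogeneity needs at least 2 estimates")
  if (any(estimates$se <= 0)) {
    abort_input("all standard errors must be positive",
                class = "onsetprs_infinite_weight")
  }
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$beta) / sum(w)
  q <- sum(w * (estimates$beta - pooled)^2)
  df <- k - 1L
  structure(list(
    Q = q, df = df,
    I2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
    p_het = pchisq(q, df, lower.tail = FALSE),
    pooled = pooled,
    inputs = as_tibble(estimates[, c("beta", "se")])
  ), class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("<het_result> Q = %.3f (df %d), I2 = %.1f%%, p_het = %.3g\n",
              x$Q, x$df, x$I2, x$p_het))
  invisible(x)
}
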