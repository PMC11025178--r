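# broom-style tidiers so fitted objects drop into dplyr chains.

#' Tidy an effect estimate
#'
#' @param x An `effect_estimate` from [weighted_cox_fit()] or
#'   [logistic_fit()].
#' @param ... Unused.
#' @return One-row tibble: `population`, `model`, `estimate` (log scale),
#'   `std.error`, `hr_or`, `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble(population = x$population_tag, model = x$model_tag,
         estimate = x$beta, std.error = x$se, hr_or = x$hr_or,
         conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p)
}

#' @rdname tidy.effect_estimate
#' @export
glance.effect_estimate <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, model = x$model_tag,
         converged = !("nonconvergence" %in% x$flags),
         flags = paste(x$flags, collapse = ";"))
}

#' Tidy a heterogeneity result
#'
#' @param x A `het_result` from [cochran_q()].
#' @param ... Unused.
#' @return One-row tibble with `Q`, `df`, `I2`, `p_het`.
#' @export
tidy.het_result <- function(x, ...) {
  tibble(Q = x$Q, df = x$df, I2 = x$I2, p_het = x$p_het)
}

#' Tidy an MR result
#'
#' @param x An `mr_result` from [mr_analyze()].
#' @param ... Unused.
#' @return One row per method (`ivw`, `weighted_median`, `egger_slope`,
#'   `egger_intercept`) with `estimate`, `std.error`, `p.value`.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(
    method = c("ivw", "weighted_median", "egger_slope", "egger_intercept"),
    estimate = c(x$ivw$estimate, x$weighted_median$estimate,
                 x$egger$slope, x$egger$intercept),
    std.error = c(x$ivw$se, x$weighted_median$se,
                  x$egger$slope_se, x$egger$intercept_se),
    p.value = c(x$ivw$p, x$weighted_median$p,
                x$egger$slope_p, x$egger$intercept_p))
}

#' @rdname tidy.mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(exposure = x$exposure_id, outcome = x$outcome_id, n_iv = x$n_iv,
         Q = x$q$Q, q_p = x$q$p, egger_intercept_p = x$egger$intercept_p,
         high_confidence = x$high_confidence,
         reasons = paste(x$reasons, collapse = "; "))
}

#' Tidy a time-dependent ROC
#'
#' @param x A `td_roc` from [td_roc_km()].
#' @param ... Unused.
#' @return The cutpoint-level curve tibble (`tidy`) or a one-row summary
#'   with the AUC (`glance`).
#' @export
tidy.td_roc <- function(x, ...) x$curve

#' @rdname tidy.td_roc
#' @export
glance.td_roc <- function(x, ...) {
  tibble(predict_time = x$predict_time, auc = x$auc, n_used = x$n_used,
         n_excluded = x$n_excluded_by_landmark, n_clipped = x$n_clipped)
}
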