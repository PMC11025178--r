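# ggplot2 graphics for the main result types.

#' Plot a time-dependent ROC curve
#'
#' @param object A `td_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.td_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Time-dependent ROC at age %g (AUC = %.3f)",
                      object$predict_time, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an incidence schedule
#'
#' Bands as horizontal segments, the per-year interpolation as a line.
#'
#' @param object An `incidence_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.incidence_schedule <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = object$bands,
      ggplot2::aes(x = .data$age_start, xend = .data$age_end,
                   y = .data$rate_per_100k, yend = .data$rate_per_100k),
      colour = "grey55") +
    ggplot2::geom_line(
      data = object$per_year,
      ggplot2::aes(x = .data$age, y = .data$rate_per_100k),
      colour = "steelblue") +
    ggplot2::labs(x = "Age (years)", y = "Incidence per 100,000",
                  title = sprintf("Incidence interpolation (%s-anchored)",
                                  object$anchor)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an MR analysis
#'
#' Instrument effects with the IVW (through the origin) and MR-Egger
#' (free intercept) fits; instruments are sign-oriented so exposure
#' effects are positive.
#'
#' @param object An `mr_dataset` from [harmonize()] (or a tibble with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_dataset <- function(object, ...) {
  d <- as_mr_instruments(object)
  d <- mutate(d, bx = abs(.data$beta_exp),
              by = .data$beta_out * sign(.data$beta_exp))
  ivw <- mr_ivw(d)
  eg <- mr_egger(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - .data$se_out,
                   ymax = .data$by + .data$se_out),
      width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$bx - .data$se_exp,
                   xmax = .data$bx + .data$se_exp),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = ivw$estimate, intercept = 0,
                         colour = "steelblue") +
    ggplot2::geom_abline(slope = eg$slope, intercept = eg$intercept,
                         colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "Exposure effect", y = "Outcome effect",
                  title = "MR instruments (solid: IVW, dashed: MR-Egger)") +
    ggplot2::theme_minimal()
}

#' Forest plot of effect estimates
#'
#' @param estimates Tibble as produced by row-binding
#'   [tidy.effect_estimate()] outputs, optionally with a `label` column.
#' @param log_scale Plot the ratio axis on the log scale (default `TRUE`).
#' @return A ggplot.
#' @export
plot_forest <- function(estimates, log_scale = TRUE) {
  check_cols(estimates, c("hr_or", "conf.low", "conf.high"), "`estimates`")
  if (!"label" %in% names(estimates)) {
    estimates$label <- paste(estimates$population, estimates$model)
  }
  p <- ggplot2::ggplot(
    estimates,
    ggplot2::aes(x = .data$hr_or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Hazard / odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_x_log10()
  p
}
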