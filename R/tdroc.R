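# Landmark filtering and cumulative/dynamic time-dependent ROC with the
# Kaplan-Meier plug-in, on the age timescale (birth as follow-up origin).

#' Landmark filtering for time-dependent ROC validation
#'
#' Implements the landmark case-removal rules: at a given prediction age,
#' cases diagnosed at or below `case_exclusion_age` are removed (e.g.
#' evaluating at 70 after removing cases diagnosed at 55 or younger);
#' controls are always retained.
#'
#' @param cohort Tibble with `exit_age` and `event`.
#' @param predict_time Prediction age in years (stored on the result).
#' @param case_exclusion_age Remove cases with event age at or below this;
#'   `NULL` removes none.
#' @return The filtered cohort; attribute `n_excluded` counts removed cases.
#' @export
landmark_filter <- function(cohort, predict_time,
                            case_exclusion_age = NULL) {
  check_cols(cohort, c("exit_age", "event"), "`cohort`")
  if (predict_time <= 0) abort_config("`predict_time` must be positive",
                                      field = "predict_time")
  drop <- if (is.null(case_exclusion_age)) {
    rep(FALSE, nrow(cohort))
  } else {
    cohort$event == 1L & cohort$exit_age <= case_exclusion_age
  }
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "predict_time") <- predict_time
  out
}

# Kaplan-Meier survival at time t for the subset `mask`, given subjects
# pre-sorted by (time, events first). `risk` is the within-mask risk count
# at each sorted position.
km_at <- function(t, time_s, event_s, mask) {
  m <- mask & event_s & time_s <= t
  if (!any(m)) return(1)
  risk <- rev(cumsum(rev(mask)))
  prod((risk[m] - 1) / risk[m])
}

#' Cumulative/dynamic time-dependent ROC via the Kaplan-Meier plug-in
#'
#' At prediction age `t`, cases are subjects with an event by `t` and
#' controls those event-free at `t`; censoring is handled by plugging
#' Kaplan-Meier estimates into the joint risk-time distribution: for each
#' cutpoint `c`, `sens = (1 - S(t | X > c)) P(X > c) / (1 - S(t))` and
#' `spec = S(t | X > c) P(X > c) / S(t)`, with the overall and
#' high-score-stratum survival both estimated by Kaplan-Meier. The
#' unsmoothed plug-in can leave `[0, 1]` or be locally non-monotone; raw
#' values are reported, and the curve used for the AUC is clipped to
#' `[0, 1]` and made monotone by a cumulative maximum. The AUC is the
#' trapezoidal integral of TPR over FPR. Entry-age left truncation is
#' deliberately ignored: follow-up is taken from birth, mirroring the
#' validation construction this estimator is used for.
#'
#' @param scores Risk scores (higher = higher risk).
#' @param exit_ages Event or censoring ages.
#' @param events Event indicators in \{0, 1\}.
#' @param predict_time Prediction age `t`.
#' @return Object of class `td_roc`: `curve` (tibble `cutpoint`, `tpr_raw`,
#'   `fpr_raw`, `tpr`, `fpr`), `auc`, `predict_time`, `n_used`,
#'   `n_clipped`, `n_excluded_by_landmark`.
#' @export
td_roc_km <- function(scores, exit_ages, events, predict_time) {
  stopifnot(length(scores) == length(exit_ages),
            length(events) == length(exit_ages))
  ok <- !is.na(scores) & !is.na(exit_ages) & !is.na(events)
  scores <- scores[ok]; exit_ages <- exit_ages[ok]; events <- events[ok]
  if (!any(events == 1L & exit_ages <= predict_time)) {
    abort_input("no events at or before `predict_time`: sensitivity undefined",
                class = "onsetprs_no_events")
  }
  ord <- order(exit_ages, -events)
  time_s <- exit_ages[ord]
  event_s <- events[ord] == 1L
  score_s <- scores[ord]
  n <- length(score_s)
  s_all <- km_at(predict_time, time_s, event_s, rep(TRUE, n))
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr_raw <- fpr_raw <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    mask <- score_s > cuts[i]
    p_c <- mean(mask)
    if (p_c == 0) {
      tpr_raw[i] <- 0; fpr_raw[i] <- 0
      next
    }
    s_c <- km_at(predict_time, time_s, event_s, mask)
    tpr_raw[i] <- (1 - s_c) * p_c / (1 - s_all)
    fpr_raw[i] <- s_c * p_c / s_all
  }
  tpr <- pmin(pmax(tpr_raw, 0), 1)
  fpr <- pmin(pmax(fpr_raw, 0), 1)
  n_clipped <- sum(tpr != tpr_raw) + sum(fpr != fpr_raw)
  tpr <- cummax(tpr)
  fpr <- cummax(fpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(
    curve = tibble(cutpoint = cuts, tpr_raw = tpr_raw, fpr_raw = fpr_raw,
                   tpr = tpr, fpr = fpr),
    auc = auc, predict_time = predict_time, n_used = n,
    n_clipped = n_clipped, n_excluded_by_landmark = NA_integer_
  ), class = "td_roc")
}

#' Landmark ROC for a cohort
#'
#' Convenience wrapper: applies [landmark_filter()] then [td_roc_km()].
#'
#' @inheritParams landmark_filter
#' @param scores Risk scores aligned with `cohort`.
#' @return A `td_roc` with `n_excluded_by_landmark` filled in.
#' @export
landmark_roc <- function(cohort, scores, predict_time,
                         case_exclusion_age = NULL) {
  stopifnot(length(scores) == nrow(cohort))
  cohort$.score <- scores
  lm <- landmark_filter(cohort, predict_time, case_exclusion_age)
  roc <- td_roc_km(lm$.score, lm$exit_age, lm$event, predict_time)
  roc$n_excluded_by_landmark <- attr(lm, "n_excluded")
  roc
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf(
    "<td_roc> AUC = %.3f at age %g (n = %d, %d excluded, %d clipped)\n",
    x$auc, x$predict_time, x$n_used,
    ifelse(is.na(x$n_excluded_by_landmark), 0, x$n_excluded_by_landmark),
    x$n_clipped))
  invisible(x)
}
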