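# Incidence interpolation, weights, weighted Cox / logistic estimation,
# CI<->SE inversion and Cochran's Q / I-squared.

test_that("incidence interpolation anchors at midpoints and extrapolates flat", {
  bands <- tibble::tibble(age_start = c(50, 55), age_end = c(55, 60),
                          rate_per_100k = c(100, 200))
  sched <- interpolate_incidence(bands, ages = 45:65)
  # midpoints 52.5 and 57.5; halfway between them the rate is 150
  expect_equal(sched$rate_at(55), 150)
  expect_equal(sched$rate_at(53.75), 125)
  # flat outside the outermost anchors
  expect_equal(sched$rate_at(45), 100)
  expect_equal(sched$rate_at(65), 200)
  # band-start anchoring is the documented alternative
  sched2 <- interpolate_incidence(bands, anchor = "band_start", ages = 50:60)
  expect_equal(sched2$rate_at(52.5), 150)
  # constant bands interpolate to a constant
  const <- interpolate_incidence(
    tibble::tibble(age_start = c(40, 45, 50), age_end = c(45, 50, 55),
                   rate_per_100k = 10), ages = 40:55)
  expect_true(all(const$per_year$rate_per_100k == 10))
  # monotone band rates give monotone per-year rates
  mono <- interpolate_incidence(
    tibble::tibble(age_start = seq(40, 70, 5), age_end = seq(45, 75, 5),
                   rate_per_100k = c(10, 30, 60, 100, 150, 210, 280)))
  expect_true(!is.unsorted(mono$per_year$rate_per_100k))
  expect_error(interpolate_incidence(
    tibble::tibble(age_start = 40, age_end = 45, rate_per_100k = 10)))
  expect_error(interpolate_incidence(
    dplyr::mutate(bands, rate_per_100k = c(-5, 10))))
})

test_that("weights are 1 for cases and 1/inc_t for non-cases", {
  bands <- tibble::tibble(age_start = c(50, 55, 60),
                          age_end = c(55, 60, 65),
                          rate_per_100k = c(1000, 1000, 1000))
  sched <- interpolate_incidence(bands, ages = 50:65)
  co <- toy_cohort(entry = c(40, 40, 40), exit = c(56, 57.9, 60),
                   event = c(1, 0, 0))
  w <- make_weights(co, sched)
  expect_equal(w[1], 1)
  expect_equal(w[2], 1 / 0.01)  # rate 1000/100k as a proportion
  expect_equal(w[3], 1 / 0.01)
  # all-case cohort: all weights one
  co2 <- toy_cohort(entry = 40, exit = c(56, 58), event = c(1, 1))
  expect_equal(make_weights(co2, sched), c(1, 1))
  # zero incidence at a needed non-case age is an error
  bands0 <- dplyr::mutate(bands, rate_per_100k = c(0, 1000, 1000))
  sched0 <- interpolate_incidence(bands0, anchor = "band_start",
                                  ages = 50:65)
  co3 <- toy_cohort(entry = 40, exit = 50.2, event = 0)
  expect_error(make_weights(co3, sched0),
               class = "onsetprs_zero_incidence")
  # normalization rescales non-case weights to mean one
  wn <- make_weights(co, sched, normalize = TRUE)
  expect_equal(mean(wn[co$event == 0]), 1)
})

test_that("weighted partial likelihood matches the grid-search oracle", {
  df <- toy_cohort(entry = c(40, 40, 41, 42, 43, 44, 40, 41),
                   exit = c(50, 55, 60, 52, 58, 65, 49, 61),
                   event = c(1, 0, 1, 1, 0, 1, 0, 1))
  x <- c(0.3, -1.2, 0.8, 1.5, -0.4, 0.9, -0.8, 0.1)
  w <- c(1, 30, 1, 1, 25, 1, 40, 1)
  est <- weighted_cox_fit(df, x, weights = w)
  ll <- function(b) {
    d2 <- df; d2$x <- x
    oracle_cox_loglik(b, d2, "x", weights = w)
  }
  best <- oracle_grid_max(ll, p = 1)
  expect_equal(est$beta, best[1], tolerance = 1e-4)
})

test_that("weight rescaling leaves the weighted Cox beta unchanged", {
  cfg <- sim_config(800, 3, seed = 19, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  co <- simulate_onset(g, cfg)
  sched <- interpolate_incidence(sim_incidence_bands(cfg), ages = 30:90)
  w <- make_weights(co, sched)
  x <- g$dosages[, 1]
  f1 <- weighted_cox_fit(co, x, weights = w)
  f2 <- weighted_cox_fit(co, x, weights = 7.3 * w)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  # unit weights equal the unweighted estimate
  f3 <- weighted_cox_fit(co, x, weights = rep(1, nrow(co)))
  f4 <- weighted_cox_fit(co, x)
  expect_equal(f3$beta, f4$beta, tolerance = 1e-10)
})

test_that("standardization against a reference gives per-SD estimates", {
  cfg <- sim_config(1000, 2, seed = 23, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  co <- simulate_onset(g, cfg)
  x <- rnorm(nrow(co), sd = 4)
  f_raw <- weighted_cox_fit(co, (x - mean(x)) / sd(x))
  f_std <- weighted_cox_fit(co, x, reference_scores = x)
  expect_equal(f_std$beta, f_raw$beta, tolerance = 1e-10)
  expect_equal(f_std$ci_low, exp(f_std$beta - qnorm(0.975) * f_std$se))
  expect_true(f_std$ci_low <= f_std$hr_or && f_std$hr_or <= f_std$ci_high)
})

test_that("logistic fit recovers the closed-form 2x2 odds ratio", {
  cc <- tibble::tibble(case = c(rep(1, 20), rep(0, 80),
                                rep(1, 10), rep(0, 90)))
  x <- c(rep(1, 100), rep(0, 100))
  est <- logistic_fit(cc, x)
  expect_equal(est$hr_or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_error(logistic_fit(cc, rep(2, 200)),
               class = "onsetprs_no_information")
  # perfect separation is flagged, not estimated
  cc2 <- tibble::tibble(case = c(rep(1, 20), rep(0, 20)))
  x2 <- c(rnorm(20, 10), rnorm(20, -10))
  est2 <- logistic_fit(cc2, x2)
  expect_true("separation" %in% est2$flags)
  expect_true(is.na(est2$beta))
})

test_that("ci_to_se inverts the Wald construction", {
  out <- ci_to_se(2.35, 1.99, 2.78)
  expect_equal(out$beta, log(2.35), tolerance = 1e-12)
  expect_equal(out$se, (log(2.78) - log(1.99)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(out$se, 0.0853, tolerance = 1e-3)
  z <- ci_to_se(1, 1, 1)
  expect_equal(z$beta, 0); expect_equal(z$se, 0)
  # round trip through CI construction
  rt <- ci_to_se(exp(0.41), exp(0.41 - qnorm(0.975) * 0.07),
                 exp(0.41 + qnorm(0.975) * 0.07))
  expect_equal(rt$beta, 0.41, tolerance = 1e-12)
  expect_equal(rt$se, 0.07, tolerance = 1e-12)
  expect_error(ci_to_se(2, 2.5, 3))
})

test_that("cochran_q computes fixed-effect heterogeneity invariantly", {
  est <- tibble::tibble(beta = c(0.5, 0.2, 0.9), se = c(0.1, 0.15, 0.3))
  h <- cochran_q(est)
  w <- 1 / est$se^2
  pooled <- sum(w * est$beta) / sum(w)
  expect_equal(h$Q, sum(w * (est$beta - pooled)^2), tolerance = 1e-12)
  expect_equal(h$df, 2L)
  expect_equal(h$p_het, pchisq(h$Q, 2, lower.tail = FALSE))
  # identical estimates: no heterogeneity
  h0 <- cochran_q(tibble::tibble(beta = c(0.3, 0.3), se = c(0.1, 0.1)))
  expect_equal(h0$Q, 0); expect_equal(h0$I2, 0); expect_equal(h0$p_het, 1)
  # permutation and scale invariance
  h_perm <- cochran_q(est[c(3, 1, 2), ])
  h_scaled <- cochran_q(dplyr::mutate(est, beta = 3 * beta, se = 3 * se))
  expect_equal(h$Q, h_perm$Q); expect_equal(h$Q, h_scaled$Q)
  expect_equal(h$I2, h_scaled$I2); expect_equal(h$p_het, h_scaled$p_het)
  # I2 in [0, 100], zero whenever Q <= df
  h1 <- cochran_q(tibble::tibble(beta = c(0.30, 0.31), se = c(0.3, 0.3)))
  expect_equal(h1$I2, 0)
  expect_error(cochran_q(est[1, ]))
  expect_error(cochran_q(tibble::tibble(beta = c(1, 2), se = c(0, 0.1))),
               class = "onsetprs_infinite_weight")
})

test_that("weighted Cox null simulations keep nominal coverage", {
  covered <- sapply(1:200, function(s) {
    cfg <- sim_config(2000, 1, within_block_rho = 0, maf_range = c(0.2, 0.4),
                      missing_rate = 0, seed = s + 5000)
    g <- simulate_genotypes(cfg)
    co <- simulate_onset(g, cfg)
    sched <- interpolate_incidence(sim_incidence_bands(cfg), ages = 30:90)
    w <- make_weights(co, sched)
    set.seed(s)
    f <- weighted_cox_fit(co, rnorm(nrow(co)), weights = w)
    f$ci_low <= 1 && 1 <= f$ci_high
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
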