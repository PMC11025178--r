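# Two-sample MR: instrument selection, harmonization, estimators, filter.

test_that("instrument selection is strict clumping with index retention", {
  g <- toy_geno(cbind(c(0, 1, 2, 0, 1, 2, 0, 1),
                      c(0, 1, 2, 0, 1, 2, 0, 1),
                      c(2, 0, 1, 1, 0, 2, 1, 0)),
                pos = c(1000L, 2000L, 900000L))
  st <- tibble::tibble(variant_id = c("v1", "v2", "v3"), chr = "1",
                       pos = c(1000L, 2000L, 900000L),
                       p = c(1e-9, 1e-12, 1e-10))
  iv <- select_instruments(st, g, p_max = 5e-8, r2_max = 0.5,
                           window_kb = 10000)
  expect_setequal(iv, c("v2", "v3"))  # v1 absorbed by the lower-p v2
  expect_equal(select_instruments(dplyr::mutate(st, p = 1e-5), g),
               character(0))
  # matches the shared brute-force oracle on a 10-variant panel
  set.seed(13)
  gp <- toy_geno(sapply(1:10, function(j) rbinom(200, 2, 0.3)),
                 pos = as.integer(1:10 * 1e4))
  sp <- tibble::tibble(variant_id = gp$variants$variant_id, chr = "1",
                       pos = gp$variants$pos, p = 10^-runif(10, 7.5, 12))
  want <- vapply(oracle_clump(sp, gp, 5e-8, 0.05, 10000), `[[`,
                 character(1), "index")
  expect_equal(select_instruments(sp, gp, r2_max = 0.05), want)
})

test_that("harmonization aligns, strand-resolves and drops ambiguity", {
  exp_row <- tibble::tibble(variant_id = "x", ea = "A", oa = "G",
                            eaf = 0.3, beta = 0.1, se = 0.01, p = 1e-10)
  out_same <- tibble::tibble(variant_id = "x", ea = "A", oa = "G",
                             eaf = 0.31, beta = 0.05, se = 0.02, p = 0.01)
  h1 <- harmonize(exp_row, out_same)
  expect_equal(h1$instruments$beta_out, 0.05)
  expect_equal(h1$instruments$action, "kept")
  # swapped alleles flip the sign and the frequency
  out_sw <- dplyr::mutate(out_same, ea = "G", oa = "A")
  h2 <- harmonize(exp_row, out_sw)
  expect_equal(h2$instruments$beta_out, -0.05)
  expect_equal(h2$instruments$eaf_out, 1 - 0.31)
  # strand flip resolves via complements (A/G vs T/C)
  out_st <- dplyr::mutate(out_same, ea = "T", oa = "C")
  h3 <- harmonize(exp_row, out_st)
  expect_equal(h3$instruments$beta_out, 0.05)
  expect_equal(h3$instruments$action, "strand-resolved")
  # palindromic at 50% frequency is dropped as ambiguous
  exp_pal <- dplyr::mutate(exp_row, ea = "A", oa = "T", eaf = 0.5)
  out_pal <- dplyr::mutate(out_same, ea = "A", oa = "T", eaf = 0.5)
  h4 <- harmonize(exp_pal, out_pal)
  expect_equal(nrow(h4$instruments), 0L)
  expect_equal(h4$dropped$reason, "palindromic ambiguous")
  # palindromic at clear frequency aligns by frequency
  exp_p2 <- dplyr::mutate(exp_pal, eaf = 0.1)
  out_p2 <- dplyr::mutate(out_pal, eaf = 0.9)
  h5 <- harmonize(exp_p2, out_p2)
  expect_equal(h5$instruments$beta_out, -0.05)
  # irreconcilable alleles are dropped with a reason
  out_bad <- dplyr::mutate(out_same, ea = "A", oa = "C")
  h6 <- harmonize(exp_row, out_bad)
  expect_equal(h6$dropped$reason, "irreconcilable alleles")
})

test_that("IVW equals the closed-form weighted mean of Wald ratios", {
  d <- toy_mr(beta_exp = c(0.10, 0.08, 0.15),
              beta_out = c(0.031, 0.019, 0.046),
              se_out = c(0.010, 0.012, 0.015))
  iv <- mr_ivw(d)
  ratio <- d$beta_out / d$beta_exp
  rse <- d$se_out / abs(d$beta_exp)
  w <- 1 / rse^2
  expect_equal(iv$estimate, sum(w * ratio) / sum(w), tolerance = 1e-12)
  expect_equal(iv$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  # single instrument: the Wald ratio itself
  one <- mr_ivw(d[1, ])
  expect_equal(one$estimate, 0.031 / 0.10, tolerance = 1e-12)
  # shared noiseless ratio: estimate r, Q = 0
  dn <- toy_mr(beta_exp = c(0.1, 0.2, 0.05), beta_out = c(0.1, 0.2, 0.05) * 0.4)
  expect_equal(mr_ivw(dn)$estimate, 0.4, tolerance = 1e-12)
  expect_equal(mr_heterogeneity_q(dn)$Q, 0, tolerance = 1e-20)
  expect_equal(mr_heterogeneity_q(dn)$p, 1)
  # zero exposure effect is dropped with a warning
  dz <- toy_mr(beta_exp = c(0, 0.1, 0.2), beta_out = c(0.1, 0.04, 0.08))
  expect_warning(ivz <- mr_ivw(dz), "zero exposure")
  expect_equal(ivz$n_iv, 2L)
})

test_that("weighted median interpolates the half-weight crossing", {
  # equal weights, odd count: the sample median of the ratios
  d <- toy_mr(beta_exp = rep(0.1, 5),
              beta_out = c(0.01, 0.05, 0.03, 0.07, 0.02),
              se_out = 0.01)
  wm <- mr_weighted_median(d, n_boot = 100, seed = 5)
  expect_equal(wm$estimate, median(d$beta_out / d$beta_exp),
               tolerance = 1e-12)
  # deterministic given the seed
  wm2 <- mr_weighted_median(d, n_boot = 100, seed = 5)
  expect_identical(wm$se, wm2$se)
  expect_error(mr_weighted_median(d[1:2, ]),
               class = "onsetprs_insufficient_instruments")
  # one wildly pleiotropic instrument among nine consistent ones
  est <- sapply(1:10, function(s) {
    ss <- simulate_mr_sumstats(mr_sim_config(
      10, true_causal_effect = 0.3, pleiotropy_intercept = 1.5,
      invalid_fraction = 0.1, exposure_n = 1e6, outcome_n = 1e6, seed = s))
    mr_weighted_median(harmonize(ss$exposure, ss$outcome),
                       n_boot = 100, seed = s)$estimate
  })
  expect_true(all(abs(est - 0.3) < 0.05))  # pilot range 0.295-0.308
})

test_that("MR-Egger matches closed-form weighted regression", {
  d <- toy_mr(beta_exp = c(0.12, -0.08, 0.2, 0.05),
              beta_out = c(0.05, -0.01, 0.09, 0.021),
              se_out = c(0.01, 0.02, 0.012, 0.02))
  eg <- mr_egger(d)
  o <- oracle_wls(abs(d$beta_exp), d$beta_out * sign(d$beta_exp),
                  1 / d$se_out^2)
  expect_equal(eg$intercept, o$coef[1], tolerance = 1e-12)
  expect_equal(eg$slope, o$coef[2], tolerance = 1e-12)
  expect_equal(eg$intercept_se, o$se[1], tolerance = 1e-12)
  expect_equal(eg$slope_se, o$se[2], tolerance = 1e-12)
  # exact line through the origin: zero intercept, exact slope
  dl <- toy_mr(beta_exp = c(0.1, 0.15, 0.2), beta_out = c(0.04, 0.06, 0.08))
  egl <- mr_egger(dl)
  expect_equal(egl$intercept, 0, tolerance = 1e-12)
  expect_equal(egl$slope, 0.4, tolerance = 1e-12)
  # directional pleiotropy is consistently estimated (pilot: 0.1000 +- 0.001)
  ints <- sapply(1:50, function(s) {
    ss <- simulate_mr_sumstats(mr_sim_config(
      20, true_causal_effect = 0.3, pleiotropy_intercept = 0.1,
      invalid_fraction = 1, exposure_n = 1e6, outcome_n = 1e6, seed = s))
    mr_egger(harmonize(ss$exposure, ss$outcome))$intercept
  })
  expect_equal(mean(ints), 0.1, tolerance = 0.01)
})

test_that("heterogeneity Q matches hand arithmetic and the null expectation", {
  d <- toy_mr(beta_exp = c(0.1, 0.2, 0.25),
              beta_out = c(0.03, 0.09, 0.06),
              se_out = c(0.01, 0.02, 0.015))
  q <- mr_heterogeneity_q(d)
  ratio <- d$beta_out / d$beta_exp
  w <- (abs(d$beta_exp) / d$se_out)^2
  ivw <- sum(w * ratio) / sum(w)
  expect_equal(q$Q, sum(w * (ratio - ivw)^2), tolerance = 1e-12)
  expect_equal(q$df, 2L)
  # E[Q] = k - 1 under the null (500 reps; SE of the mean ~0.25)
  qs <- sapply(1:500, function(s) {
    ss <- simulate_mr_sumstats(mr_sim_config(8, true_causal_effect = 0.2,
                                             seed = s + 900))
    mr_heterogeneity_q(harmonize(ss$exposure, ss$outcome))$Q
  })
  expect_equal(mean(qs), 7, tolerance = 0.12)
})

test_that("rescaling exposure effects rescales estimators and preserves tests", {
  d <- toy_mr(beta_exp = c(0.12, 0.08, 0.2, 0.05),
              beta_out = c(0.05, 0.03, 0.09, 0.021),
              se_out = c(0.01, 0.02, 0.012, 0.02))
  c_ <- 3.7
  d2 <- dplyr::mutate(d, beta_exp = c_ * beta_exp, se_exp = c_ * se_exp)
  expect_equal(mr_ivw(d2)$estimate, mr_ivw(d)$estimate / c_,
               tolerance = 1e-12)
  expect_equal(mr_egger(d2)$intercept_p, mr_egger(d)$intercept_p,
               tolerance = 1e-10)
  expect_equal(mr_heterogeneity_q(d2)$Q, mr_heterogeneity_q(d)$Q,
               tolerance = 1e-10)
})

test_that("the high-confidence filter applies the quoted boundaries exactly", {
  base <- list(ivw = list(estimate = 0.3, p = 0.01),
               weighted_median = list(estimate = 0.25, p = 0.03),
               egger = list(intercept_p = 0.5),
               q = list(p = 0.2))
  expect_true(high_confidence_filter(base)$high_confidence)
  # discordant direction
  r <- base; r$weighted_median$estimate <- -0.1
  out <- high_confidence_filter(r)
  expect_false(out$high_confidence)
  expect_true("directional discordance" %in% out$reasons)
  # heterogeneity boundary: 0.049 fails, 0.05 passes
  r <- base; r$q$p <- 0.049
  expect_false(high_confidence_filter(r)$high_confidence)
  r$q$p <- 0.05
  expect_true(high_confidence_filter(r)$high_confidence)
  # effect-test boundary: p = 0.05 is not significant
  r <- base; r$ivw$p <- 0.05
  out2 <- high_confidence_filter(r)
  expect_false(out2$high_confidence)
  expect_true("ivw not significant" %in% out2$reasons)
  # egger boundary
  r <- base; r$egger$intercept_p <- 0.0499
  expect_false(high_confidence_filter(r)$high_confidence)
  # missing component
  r <- base; r$q$p <- NULL
  expect_error(high_confidence_filter(r))
})

test_that("IVW coverage is nominal with all-valid instruments", {
  covered <- sapply(1:200, function(s) {
    ss <- simulate_mr_sumstats(mr_sim_config(15, true_causal_effect = 0.25,
                                             invalid_fraction = 0, seed = s))
    iv <- mr_ivw(harmonize(ss$exposure, ss$outcome))
    abs(iv$estimate - 0.25) <= qnorm(0.975) * iv$se
  })
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
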