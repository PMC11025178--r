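#' Default piecewise-constant baseline hazard
#'
#' Age-banded baseline hazard for the onset simulator, shaped like the
#' age-specific prostate-cancer incidence of White US males (steeply
#' increasing from the fifth decade) and scaled by `multiplier`. The default
#' multiplier of 5 compresses the epidemiology to desk scale: it keeps the
#' age profile while giving cohorts of a few tens of thousands enough
#' early-onset events for stable estimation (see the methods vignette).
#'
#' @param multiplier Positive scale factor applied to the population-like
#'   per-year rates.
#' @return Tibble with `age_start`, `age_end` (years, half-open bands) and
#'   `hazard` (events per person-year).
#' @export
default_baseline_hazard <- function(multiplier = 5) {
  stopifnot(is.numeric(multiplier), multiplier >= 0)
  rates_per_100k <- c(
    `30` = 1, `35` = 3, `40` = 9, `45` = 33, `50` = 101, `55` = 228,
    `60` = 420, `65` = 624, `70` = 772, `75` = 720, `80` = 666, `85` = 566
  )
  starts <- as.numeric(names(rates_per_100k))
  tibble(age_start = starts, age_end = starts + 5,
         hazard = multiplier * unname(rates_per_100k) / 1e5)
}

#' Simulation configuration for synthetic genotype/onset cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator:
#' LD-blocked genotypes, age-dependent causal effects that switch at
#' `age_cut` (early-onset-specific effects act only at ages at or below the
#' cut, late-onset-specific only above it, shared effects always), a
#' piecewise-constant baseline hazard, censoring, and a family-history
#' mechanism tied to causal burden.
#'
#' @param n_samples,n_variants Cohort and panel sizes.
#' @param ld_block_sizes Integer vector of block sizes summing to
#'   `n_variants`; `NULL` packs variants into blocks of 5.
#' @param within_block_rho Latent AR(1) correlation within an LD block,
#'   in `[0, 1)`.
#' @param maf_range Range the per-variant minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param causal_sets List with elements `eo`, `lo`, `shared`, each a list
#'   with integer `idx` (variant indices, disjoint across sets) and numeric
#'   `beta` (per-allele log hazard ratios). `NULL` means no causal variants.
#' @param age_cut Age (years) at which early-onset effects switch off and
#'   late-onset effects switch on. Default 55.
#' @param baseline_hazard Piecewise-constant hazard bands, as returned by
#'   [default_baseline_hazard()].
#' @param entry_age_range Uniform range of ages at enrolment.
#' @param admin_censor_age Administrative censoring age.
#' @param follow_up_years Maximum follow-up after entry (censoring at
#'   `entry + follow_up_years`); this is what creates an early-onset
#'   stratum dominated by young entrants.
#' @param loss_rate Constant per-year hazard of loss to follow-up.
#' @param fh_prevalence Baseline probability of positive family history for
#'   a subject of average causal burden.
#' @param fh_slope Log-odds increase in family-history probability per SD
#'   of causal burden.
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed; every stochastic draw of the module flows from
#'   it, so identical configs reproduce byte-identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_variants,
                       ld_block_sizes = NULL,
                       within_block_rho = 0.4,
                       maf_range = c(0.05, 0.5),
                       causal_sets = NULL,
                       age_cut = 55,
                       baseline_hazard = default_baseline_hazard(),
                       entry_age_range = c(40, 69),
                       admin_censor_age = 87,
                       follow_up_years = 13,
                       loss_rate = 0.005,
                       fh_prevalence = 0.07,
                       fh_slope = 0.8,
                       missing_rate = 0.01,
                       seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_variants <- check_count(n_variants, "n_variants")
  if (is.null(ld_block_sizes)) {
    full <- n_variants %/% 5L
    ld_block_sizes <- c(rep(5L, full), if (n_variants %% 5L) n_variants %% 5L)
  }
  if (sum(ld_block_sizes) != n_variants || any(ld_block_sizes < 1L)) {
    abort_config("`ld_block_sizes` must be positive and sum to `n_variants`",
                 field = "ld_block_sizes")
  }
  if (!is.numeric(within_block_rho) || within_block_rho < 0 ||
      within_block_rho >= 1) {
    abort_config("`within_block_rho` must lie in [0, 1)",
                 field = "within_block_rho")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort_config("`maf_range` must be an increasing pair within (0, 0.5]",
                 field = "maf_range")
  }
  causal_sets <- validate_causal_sets(causal_sets, n_variants)
  if (!is.numeric(age_cut) || age_cut <= 0) {
    abort_config("`age_cut` must be positive", field = "age_cut")
  }
  baseline_hazard <- as_tibble(baseline_hazard)
  check_cols(baseline_hazard, c("age_start", "age_end", "hazard"),
             "`baseline_hazard`")
  if (any(baseline_hazard$hazard < 0)) {
    abort_config("baseline hazard rates must be non-negative",
                 field = "baseline_hazard")
  }
  if (length(entry_age_range) != 2L || entry_age_range[1] > entry_age_range[2]) {
    abort_config("`entry_age_range` must be an increasing pair",
                 field = "entry_age_range")
  }
  check_prob(fh_prevalence, "fh_prevalence")
  check_prob(missing_rate, "missing_rate")
  if (loss_rate < 0) abort_config("`loss_rate` must be >= 0", field = "loss_rate")
  structure(list(
    n_samples = n_samples, n_variants = n_variants,
    ld_block_sizes = as.integer(ld_block_sizes),
    within_block_rho = within_block_rho, maf_range = maf_range,
    causal_sets = causal_sets, age_cut = age_cut,
    baseline_hazard = baseline_hazard, entry_age_range = entry_age_range,
    admin_censor_age = admin_censor_age, follow_up_years = follow_up_years,
    loss_rate = loss_rate, fh_prevalence = fh_prevalence,
    fh_slope = fh_slope, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

validate_causal_sets <- function(causal_sets, n_variants) {
  empty <- list(idx = integer(0), beta = numeric(0))
  if (is.null(causal_sets)) {
    return(list(eo = empty, lo = empty, shared = empty))
  }
  for (nm in c("eo", "lo", "shared")) {
    if (is.null(causal_sets[[nm]])) causal_sets[[nm]] <- empty
    set <- causal_sets[[nm]]
    if (length(set$idx) != length(set$beta)) {
      abort_config(sprintf("causal set `%s` needs one beta per index", nm),
                   field = "causal_sets")
    }
    if (length(set$idx) && (any(set$idx < 1L) || any(set$idx > n_variants))) {
      abort_config(sprintf("causal set `%s` indexes outside the panel", nm),
                   field = "causal_sets")
    }
  }
  all_idx <- c(causal_sets$eo$idx, causal_sets$lo$idx, causal_sets$shared$idx)
  if (anyDuplicated(all_idx)) {
    abort_config("causal sets must be disjoint", field = "causal_sets")
  }
  causal_sets[c("eo", "lo", "shared")]
}

#' Canonical demonstration configuration
#'
#' The study conditions used throughout the package's examples and
#' validation runs: an LD-blocked panel with eight early-onset-specific,
#' eight late-onset-specific and eight shared causal variants, strong
#' early-onset effects (the pattern the age-split analysis is designed to
#' detect), and the default compressed baseline hazard.
#'
#' @param n_samples,n_variants Cohort and panel sizes.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
demo_sim_config <- function(n_samples = 20000, n_variants = 200, seed = 1L,
                            ...) {
  n_variants <- check_count(n_variants, "n_variants")
  pick <- function(k, offset) {
    idx <- seq(1L + offset, by = 24L, length.out = k)
    idx[idx <= n_variants]
  }
  eo <- pick(8L, 0L); lo <- pick(8L, 5L); shared <- pick(8L, 10L)
  sim_config(
    n_samples = n_samples, n_variants = n_variants, seed = seed,
    causal_sets = list(
      eo = list(idx = eo, beta = rep(0.9, length(eo))),
      lo = list(idx = lo, beta = rep(0.35, length(lo))),
      shared = list(idx = shared, beta = rep(0.2, length(shared)))
    ),
    ...
  )
}

#' Configuration for paired MR summary statistics
#'
#' @param n_instruments Number of instruments (>= 1).
#' @param true_causal_effect Exposure-to-outcome slope.
#' @param pleiotropy_intercept Directional pleiotropy added to the outcome
#'   effect of invalid instruments.
#' @param exposure_n,outcome_n GWAS sample sizes controlling the SE scale
#'   (SE about `1/sqrt(n)`).
#' @param invalid_fraction Fraction of instruments receiving the pleiotropy
#'   intercept.
#' @param palindromic_fraction Fraction of instruments assigned A/T or C/G
#'   alleles.
#' @param seed Integer seed.
#' @return A validated list of class `mr_sim_config`.
#' @export
mr_sim_config <- function(n_instruments, true_causal_effect = 0,
                          pleiotropy_intercept = 0,
                          exposure_n = 1e5, outcome_n = 1e5,
                          invalid_fraction = 0,
                          palindromic_fraction = 0.2,
                          seed = 1L) {
  n_instruments <- check_count(n_instruments, "n_instruments")
  check_prob(invalid_fraction, "invalid_fraction")
  check_prob(palindromic_fraction, "palindromic_fraction")
  if (exposure_n <= 0 || outcome_n <= 0) {
    abort_config("sample sizes must be positive", field = "exposure_n")
  }
  structure(list(
    n_instruments = n_instruments, true_causal_effect = true_causal_effect,
    pleiotropy_intercept = pleiotropy_intercept,
    exposure_n = exposure_n, outcome_n = outcome_n,
    invalid_fraction = invalid_fraction,
    palindromic_fraction = palindromic_fraction, seed = as.integer(seed)
  ), class = "mr_sim_config")
}
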