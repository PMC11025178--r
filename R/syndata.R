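# Synthetic-cohort generator: LD-blocked genotypes via a Gaussian copula on
# latent haplotypes, age-of-onset sampling by inversion of the piecewise
# cumulative hazard with a multiplier that switches at age_cut, and paired
# exposure/outcome summary statistics for the MR screen.

# run `code` under a deterministic stream without clobbering the caller's RNG
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Draws two latent haplotypes per sample from a block-diagonal Gaussian
#' copula (AR(1) correlation `within_block_rho` within a block, independence
#' between blocks), thresholds each at the variant's drawn allele frequency,
#' and sums them into effect-allele dosages in \{0, 1, 2\}. Genotypes are
#' set missing at `missing_rate`. Variants are laid out on one chromosome
#' with 20 kb spacing inside a block and 1 Mb gaps between blocks.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] whose `variants` table carries a `true_maf`
#'   column (the frequency each variant was drawn at).
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_config("`config` must be a `sim_config`", field = "config")
  }
  with_local_seed(config$seed, {
    n <- config$n_samples
    sizes <- config$ld_block_sizes
    rho <- config$within_block_rho
    maf <- runif(config$n_variants, config$maf_range[1], config$maf_range[2])
    dos <- matrix(NA_real_, n, config$n_variants)
    col0 <- 0L
    for (m in sizes) {
      cols <- col0 + seq_len(m)
      if (m == 1L || rho == 0) {
        z1 <- matrix(rnorm(n * m), n, m)
        z2 <- matrix(rnorm(n * m), n, m)
      } else {
        sigma <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
        u <- chol(sigma)
        z1 <- matrix(rnorm(n * m), n, m) %*% u
        z2 <- matrix(rnorm(n * m), n, m) %*% u
      }
      thr <- rep(qnorm(maf[cols]), each = n)
      dos[, cols] <- (z1 < thr) + (z2 < thr)
      col0 <- col0 + m
    }
    if (config$missing_rate > 0) {
      dos[runif(length(dos)) < config$missing_rate] <- NA_real_
    }
    block_id <- rep(seq_along(sizes), sizes)
    within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
    pos <- (block_id - 1L) * 1e6L + (within - 1L) * 2e4L + 1e4L
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, config$n_variants, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
    variants <- tibble(
      variant_id = sprintf("rs%06d", seq_len(config$n_variants)),
      chr = "1", pos = as.integer(pos),
      effect_allele = ea, other_allele = unname(oa),
      ld_block = block_id, true_maf = maf
    )
    geno_matrix(dos, variants,
                samples = sprintf("id%05d", seq_len(n)))
  })
}

# per-subject log hazard multipliers before/after the age cut; dosages are
# centered at their mean so the baseline hazard refers to the average
# subject, and missing dosages contribute their expectation
causal_burden <- function(g, config) {
  score_set <- function(set) {
    if (length(set$idx) == 0L) return(rep(0, length(g$samples)))
    d <- g$dosages[, set$idx, drop = FALSE]
    ef <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) {
      d[is.na(d[, j]), j] <- ef[j]
      d[, j] <- d[, j] - ef[j]
    }
    drop(d %*% set$beta)
  }
  list(eo = score_set(config$causal_sets$eo),
       lo = score_set(config$causal_sets$lo),
       shared = score_set(config$causal_sets$shared))
}

#' Simulate an age-of-onset survival cohort
#'
#' Event ages are drawn by inverting the cumulative hazard of a
#' piecewise-constant baseline multiplied per subject by
#' `exp(shared + eo burden)` at ages at or below `age_cut` and
#' `exp(shared + lo burden)` above it. Subjects are censored at the
#' earliest of the administrative age, `entry + follow_up_years`, and an
#' exponential loss time. Family history is Bernoulli with log-odds
#' `qlogis(fh_prevalence) + fh_slope * z`, `z` the standardized total
#' causal burden.
#'
#' @param genotypes A [geno_matrix()] from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A tibble (`sample_id`, `entry_age`, `exit_age`, `event`, `fh`,
#'   `bmi`, `pc1`) — exit age is the event age for cases and the censoring
#'   age otherwise.
#' @export
simulate_onset <- function(genotypes, config) {
  if (!inherits(config, "sim_config")) {
    abort_config("`config` must be a `sim_config`", field = "config")
  }
  if (length(genotypes$samples) != config$n_samples) {
    abort_input("genotype sample count does not match `config`")
  }
  if (all(config$baseline_hazard$hazard == 0)) {
    abort_input("baseline hazard is identically zero: no events can occur",
                class = "onsetprs_degenerate_simulation")
  }
  burden <- causal_burden(genotypes, config)
  with_local_seed(config$seed + 1L, {
    n <- config$n_samples
    entry <- runif(n, config$entry_age_range[1], config$entry_age_range[2])
    m_pre <- exp(burden$shared + burden$eo)
    m_post <- exp(burden$shared + burden$lo)
    t_event <- sample_onset_ages(entry, m_pre, m_post, config)
    loss <- if (config$loss_rate > 0) entry + rexp(n, config$loss_rate) else Inf
    cens <- pmin(config$admin_censor_age, entry + config$follow_up_years, loss)
    cens <- pmax(cens, entry)  # admin censoring below entry censors at entry
    event <- as.integer(t_event <= cens)
    exit_age <- pmin(t_event, cens)
    total <- burden$shared + burden$eo + burden$lo
    z <- if (sd(total) > 0) as.numeric(scale(total)) else rep(0, n)
    fh_p <- stats::plogis(stats::qlogis(config$fh_prevalence) +
                            config$fh_slope * z)
    tibble(
      sample_id = genotypes$samples,
      entry_age = entry, exit_age = exit_age, event = event,
      fh = rbinom(n, 1L, fh_p),
      bmi = rnorm(n, 27.8, 4.2),
      pc1 = rnorm(n)
    )
  })
}

# invert H(entry -> t) = -log(U) segment by segment; multiplier switches at
# age_cut. Returns Inf when the target exceeds the support of the bands.
sample_onset_ages <- function(entry, m_pre, m_post, config) {
  bands <- config$baseline_hazard
  cut <- config$age_cut
  edges <- sort(unique(c(bands$age_start, bands$age_end, cut)))
  seg <- tibble(start = head(edges, -1L), end = tail(edges, -1L))
  seg$h0 <- vapply(seg$start, function(s) {
    hit <- which(bands$age_start <= s & s < bands$age_end)
    if (length(hit)) bands$hazard[hit[1]] else 0
  }, numeric(1))
  n <- length(entry)
  target <- -log(runif(n))
  t_event <- rep(Inf, n)
  for (k in seq_len(nrow(seg))) {
    lo <- pmax(seg$start[k], entry)
    len <- pmax(seg$end[k] - lo, 0)
    m <- if (seg$end[k] <= cut) m_pre else m_post
    rate <- seg$h0[k] * m
    cap <- rate * len
    hit <- is.infinite(t_event) & target <= cap & cap > 0
    t_event[hit] <- lo[hit] + target[hit] / rate[hit]
    left <- is.infinite(t_event)
    target[left] <- target[left] - cap[left]
  }
  t_event
}

#' Incidence table implied by a simulation configuration
#'
#' The generator's own baseline hazard re-expressed as a banded incidence
#' table (rate per 100,000 person-years), i.e. the table whose reciprocal
#' rates are the correct non-case sampling weights for cohorts it produced.
#'
#' @param config A [sim_config()].
#' @return Tibble with `age_start`, `age_end`, `rate_per_100k`.
#' @export
sim_incidence_bands <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_config("`config` must be a `sim_config`", field = "config")
  }
  dplyr::transmute(config$baseline_hazard,
                   age_start = .data$age_start, age_end = .data$age_end,
                   rate_per_100k = .data$hazard * 1e5)
}

#' Simulate paired two-sample MR summary statistics
#'
#' Exposure effects are drawn positive (the effect allele is oriented to
#' increase the exposure) with SE `1/sqrt(exposure_n)`; outcome effects are
#' `true_causal_effect * beta_exposure` plus `pleiotropy_intercept` for the
#' invalid fraction of instruments, observed with SE `1/sqrt(outcome_n)`.
#' A configurable fraction of instruments get palindromic (A/T or C/G)
#' alleles.
#'
#' @param config An [mr_sim_config()].
#' @return List with tibbles `exposure` and `outcome`, each with columns
#'   `variant_id`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`,
#'   plus a logical `invalid` column on the outcome side recording which
#'   instruments carry pleiotropy.
#' @export
simulate_mr_sumstats <- function(config) {
  if (!inherits(config, "mr_sim_config")) {
    abort_config("`config` must be an `mr_sim_config`", field = "config")
  }
  with_local_seed(config$seed, {
    k <- config$n_instruments
    beta_true <- runif(k, 0.05, 0.2)
    se_exp <- rep(1 / sqrt(config$exposure_n), k)
    se_out <- rep(1 / sqrt(config$outcome_n), k)
    n_invalid <- round(config$invalid_fraction * k)
    invalid <- seq_len(k) %in% sample.int(k, n_invalid)
    beta_out_true <- config$true_causal_effect * beta_true +
      config$pleiotropy_intercept * invalid
    beta_exp <- beta_true + rnorm(k) * se_exp
    beta_out <- beta_out_true + rnorm(k) * se_out
    palin <- runif(k) < config$palindromic_fraction
    pairs_pal <- list(c("A", "T"), c("C", "G"))
    pairs_reg <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    al <- lapply(seq_len(k), function(i) {
      p <- if (palin[i]) pairs_pal[[sample.int(2L, 1L)]]
      else pairs_reg[[sample.int(4L, 1L)]]
      if (runif(1) < 0.5) rev(p) else p
    })
    ea <- vapply(al, `[`, character(1), 1L)
    oa <- vapply(al, `[`, character(1), 2L)
    eaf <- runif(k, 0.05, 0.95)
    two_sided <- function(b, s) ifelse(s > 0, 2 * pnorm(-abs(b) / s),
                                       as.numeric(b == 0))
    base <- tibble(
      variant_id = sprintf("iv%04d", seq_len(k)),
      chr = as.character(1L + (seq_len(k) - 1L) %% 22L),
      pos = as.integer(1e6 * seq_len(k)),
      ea = ea, oa = oa, eaf = eaf
    )
    exposure <- mutate(base, beta = beta_exp, se = se_exp,
                       p = two_sided(beta_exp, se_exp),
                       n = config$exposure_n)
    outcome <- mutate(base, beta = beta_out, se = se_out,
                      p = two_sided(beta_out, se_out),
                      n = config$outcome_n, invalid = invalid)
    list(exposure = exposure, outcome = outcome)
  })
}
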