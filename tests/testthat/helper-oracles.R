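# Independent oracles: brute-force or closed-form routes that never touch
# the implementation paths they check.

# log weighted Cox partial likelihood, no ties, left truncation
oracle_cox_loglik <- function(beta, df, xcols, weights = NULL) {
  w <- weights %||% rep(1, nrow(df))
  eta <- as.matrix(df[, xcols, drop = FALSE]) %*% beta
  ll <- 0
  for (i in which(df$event == 1)) {
    t_i <- df$exit_age[i]
    risk <- df$entry_age < t_i & df$exit_age >= t_i
    ll <- ll + w[i] * (eta[i] - log(sum(w[risk] * exp(eta[risk]))))
  }
  ll
}

# Efron log partial likelihood with ties, unweighted
oracle_efron_loglik <- function(beta, df, xcols) {
  eta <- drop(as.matrix(df[, xcols, drop = FALSE]) %*% beta)
  ll <- 0
  for (t_i in sort(unique(df$exit_age[df$event == 1]))) {
    dset <- which(df$event == 1 & df$exit_age == t_i)
    risk <- which(df$entry_age < t_i & df$exit_age >= t_i)
    d <- length(dset)
    sum_d <- sum(exp(eta[dset]))
    sum_r <- sum(exp(eta[risk]))
    ll <- ll + sum(eta[dset]) -
      sum(vapply(seq_len(d) - 1, function(l) log(sum_r - (l / d) * sum_d),
                 numeric(1)))
  }
  ll
}

# maximize a log-likelihood over p parameters by iteratively refined grids
oracle_grid_max <- function(loglik, p, lower = -4, upper = 4,
                            passes = 6, pts = 25) {
  centre <- rep(0, p)
  half <- (upper - lower) / 2
  for (pass in seq_len(passes)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(centre[j] - half, centre[j] + half, length.out = pts)
    })
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, loglik)
    centre <- cand[which.max(vals), ]
    half <- half * 2.2 / (pts - 1)  # keep a margin around the best point
  }
  unname(centre)
}

# exact HWE by direct enumeration of all heterozygote counts
oracle_hwe_enum <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- sapply(hets, function(h) {
    lfactorial(n) - lfactorial((rare - h) / 2) -
      lfactorial((2 * n - rare - h) / 2) - lfactorial(h) + h * log(2)
  })
  prob <- exp(logp - max(logp)); prob <- prob / sum(prob)
  obs <- prob[match(min(n_ab, rare), hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# exhaustive greedy clumping that re-scans every pair each round
oracle_clump <- function(stats, g, p_index, r2_max, window_kb) {
  stats <- stats[!is.na(stats$p) & stats$p < p_index, ]
  stats <- stats[order(stats$p, stats$chr, stats$pos), ]
  assigned <- character(0)
  out <- list()
  repeat {
    rest <- stats[!(stats$variant_id %in% assigned), ]
    if (nrow(rest) == 0) break
    idx <- rest[1, ]
    members <- character(0)
    for (k in seq_len(nrow(rest))[-1]) {
      v <- rest[k, ]
      if (v$chr != idx$chr) next
      if (abs(v$pos - idx$pos) > window_kb * 1000) next
      r2 <- tryCatch(ld_r2(g, idx$variant_id, v$variant_id),
                     error = function(e) 0)
      if (r2 >= r2_max) members <- c(members, v$variant_id)
    }
    out[[length(out) + 1]] <- list(index = idx$variant_id, members = members)
    assigned <- c(assigned, idx$variant_id, members)
  }
  out
}

# closed-form weighted least squares (with intercept) and classical SEs
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  b <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% b
  df <- length(y) - 2
  sigma2 <- sum(w * resid^2) / df
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  list(coef = unname(drop(b)), se = unname(se))
}

# minimal MR instrument table
toy_mr <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.03) {
  k <- length(beta_exp)
  tibble::tibble(variant_id = paste0("iv", seq_len(k)),
                 beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
                 beta_out = beta_out, se_out = rep_len(se_out, k))
}

# small deterministic genotype fixture with explicit dosages
toy_geno <- function(dosages, chr = NULL, pos = NULL, ea = NULL, oa = NULL) {
  m <- ncol(dosages)
  geno_matrix(
    dosages,
    tibble::tibble(
      variant_id = paste0("v", seq_len(m)),
      chr = chr %||% rep("1", m),
      pos = pos %||% as.integer(seq_len(m) * 1000),
      effect_allele = ea %||% rep("A", m),
      other_allele = oa %||% rep("G", m)),
    samples = paste0("s", seq_len(nrow(dosages))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small survival cohort with arbitrary columns
toy_cohort <- function(entry, exit, event, ...) {
  tibble::tibble(sample_id = paste0("s", seq_along(entry)),
                 entry_age = entry, exit_age = exit,
                 event = as.integer(event), ...)
}
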