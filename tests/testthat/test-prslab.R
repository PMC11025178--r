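# LD, clumping, PRS scoring, quintiles, merged PRS.

test_that("ld_r2 equals squared Pearson correlation and rejects degeneracy", {
  g <- toy_geno(cbind(c(0, 1, 2, 0, 1), c(0, 1, 1, 0, 2)))
  hand <- cor(c(0, 1, 2, 0, 1), c(0, 1, 1, 0, 2))^2
  expect_equal(ld_r2(g, "v1", "v2"), hand, tolerance = 1e-12)
  g2 <- toy_geno(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(ld_r2(g2, "v1", "v2"), 1.0)
  g3 <- toy_geno(cbind(c(0, 1, 2), c(1, 1, 1)))
  expect_error(ld_r2(g3, "v1", "v2"),
               class = "onsetprs_insufficient_variation")
  g4 <- toy_geno(cbind(c(0, NA, NA), c(NA, 1, NA)))
  expect_error(ld_r2(g4, "v1", "v2"), class = "onsetprs_insufficient_data")
})

make_ld_panel <- function() {
  # 10 variants: planted blocks {v1,v2,v3} and {v6,v7}, rest independent
  set.seed(7)
  n <- 400
  base1 <- rbinom(n, 2, 0.4)
  base2 <- rbinom(n, 2, 0.3)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- rbinom(k, 2, 0.4); x }
  d <- cbind(base1, flip(base1, 20), flip(base1, 40),
             rbinom(n, 2, 0.25), rbinom(n, 2, 0.45),
             base2, flip(base2, 15),
             rbinom(n, 2, 0.35), rbinom(n, 2, 0.2), rbinom(n, 2, 0.5))
  toy_geno(d, pos = as.integer(c(1:5, 1:5) * 5e4),
           chr = rep(c("1", "2"), each = 5))
}

test_that("clump matches the exhaustive re-scanning oracle on a toy panel", {
  g <- make_ld_panel()
  set.seed(21)
  stats <- tibble::tibble(variant_id = g$variants$variant_id,
                          chr = g$variants$chr, pos = g$variants$pos,
                          p = 10^-runif(10, 4, 9))
  for (r2m in c(0.3, 0.8)) {
    got <- clump(stats, g, p_index = 1e-3, r2_max = r2m, window_kb = 500)
    want <- oracle_clump(stats, g, 1e-3, r2m, 500)
    expect_equal(got$clumps$index_variant,
                 vapply(want, `[[`, character(1), "index"))
    expect_equal(got$clumps$members,
                 lapply(want, `[[`, "members"), ignore_attr = TRUE)
  }
})

test_that("clump respects dominance, thresholds and input order", {
  g <- toy_geno(cbind(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)),
                pos = c(1000L, 2000L))
  stats <- tibble::tibble(variant_id = c("v1", "v2"), chr = "1",
                          pos = c(1000L, 2000L), p = c(1e-6, 1e-8))
  cl <- clump(stats, g, p_index = 1e-5, r2_max = 0.8, window_kb = 10)
  expect_equal(cl$clumps$index_variant, "v2")   # lower p wins
  expect_equal(cl$clumps$members[[1]], "v1")
  # empty result below threshold, not an error
  cl0 <- clump(dplyr::mutate(stats, p = 0.5), g, p_index = 1e-5,
               r2_max = 0.8, window_kb = 10)
  expect_equal(nrow(cl0$clumps), 0L)
  # single variant clumps with itself as index
  cl1 <- clump(stats[2, ], g, p_index = 1e-5, r2_max = 0.8, window_kb = 10)
  expect_equal(cl1$index_variants, "v2")
  # row order never matters
  g2 <- make_ld_panel()
  set.seed(33)
  st <- tibble::tibble(variant_id = g2$variants$variant_id,
                       chr = g2$variants$chr, pos = g2$variants$pos,
                       p = 10^-runif(10, 4, 9))
  a <- clump(st, g2, 1e-3, 0.3, 500)
  b <- clump(st[sample(10), ], g2, 1e-3, 0.3, 500)
  expect_identical(a$clumps, b$clumps)
})

test_that("compute_prs does aligned, imputed, linear scoring", {
  # 3 variants: one aligned, one allele-flipped, one with a missing call
  d <- rbind(c(2, 0, 1), c(1, 2, NA), c(0, 1, 2))
  g <- toy_geno(d, ea = c("A", "A", "A"), oa = c("G", "G", "G"))
  model <- prs_model(tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    effect_allele = c("A", "G", "A"),   # v2 weight applies to the G allele
    weight = c(0.5, 1.0, -2.0)))
  out <- compute_prs(g, model)
  eaf3 <- mean(c(1, 2), na.rm = TRUE) / 2  # observed freq used for imputation
  hand <- c(0.5 * 2 + 1.0 * (2 - 0) + (-2.0) * 1,
            0.5 * 1 + 1.0 * (2 - 2) + (-2.0) * (2 * eaf3),
            0.5 * 0 + 1.0 * (2 - 1) + (-2.0) * 2)
  expect_equal(out$score, hand, tolerance = 1e-12)
  expect_equal(out$n_imputed, c(0L, 1L, 0L))
  # single-term arithmetic and the zero model
  g1 <- toy_geno(matrix(c(2, 0), ncol = 1))
  m1 <- prs_model(tibble::tibble(variant_id = "v1", effect_allele = "A",
                                 weight = log(2)))
  expect_equal(compute_prs(g1, m1)$score, c(2 * log(2), 0))
  m0 <- prs_model(tibble::tibble(variant_id = "v1", effect_allele = "A",
                                 weight = 0))
  expect_equal(compute_prs(g1, m0)$score, c(0, 0))
  # linearity in the weights
  m2 <- dplyr::mutate(model, weight = 2 * weight)
  expect_equal(compute_prs(g, m2)$score, 2 * out$score, tolerance = 1e-12)
})

test_that("allele flip with negated weight shifts scores by exactly 2*beta", {
  d <- matrix(c(0, 1, 2, 1, 0), ncol = 1)
  g <- toy_geno(d, ea = "A", oa = "G")
  m_a <- prs_model(tibble::tibble(variant_id = "v1", effect_allele = "A",
                                  weight = 0.7))
  m_g <- prs_model(tibble::tibble(variant_id = "v1", effect_allele = "G",
                                  weight = -0.7))
  s_a <- compute_prs(g, m_a)$score
  s_g <- compute_prs(g, m_g)$score
  expect_equal(s_g - s_a, rep(-2 * 0.7, 5), tolerance = 1e-12)
})

test_that("absent model variants are reported, many absent is fatal", {
  g <- toy_geno(matrix(c(0, 1, 2), ncol = 1))
  model <- prs_model(tibble::tibble(
    variant_id = c("v1", "zz1"), effect_allele = c("A", "A"),
    weight = c(1, 1)))
  out <- compute_prs(g, model, max_missing_frac = 0.6)
  expect_equal(attr(out, "missing_variants"), "zz1")
  expect_error(compute_prs(g, model, max_missing_frac = 0.2),
               class = "onsetprs_missing_variants")
})

test_that("quintiles follow the reference right-closed convention", {
  ref <- as.numeric(1:100)
  q <- standardize_and_quintile(ref, ref)
  expect_equal(unname(table(q$quintile)), rep(20L, 5), ignore_attr = TRUE)
  cuts <- quantile(ref, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  at_cut <- standardize_and_quintile(cuts[2], ref)
  expect_equal(at_cut$quintile, 2L)            # equal to the 40% cut -> Q2
  expect_equal(standardize_and_quintile(min(ref) - 5, ref)$quintile, 1L)
  expect_equal(standardize_and_quintile(max(ref) + 5, ref)$quintile, 5L)
  # monotone in score
  sc <- sort(rnorm(50))
  expect_true(!is.unsorted(standardize_and_quintile(sc, rnorm(200))$quintile))
  expect_error(standardize_and_quintile(1:3, rep(2, 10)),
               class = "onsetprs_degenerate_reference")
})

test_that("merge_prs follows the replacement rule on a hand-traced toy", {
  # reported r1..r5 at chr1 positions, gwas hits g1..g4; g1 tags r1 (same
  # dosimetry), g2 tags r3; g3, g4 independent
  set.seed(5)
  n <- 300
  r1 <- rbinom(n, 2, 0.4); r3 <- rbinom(n, 2, 0.3)
  d <- cbind(r1, rbinom(n, 2, 0.3), r3, rbinom(n, 2, 0.2),
             rbinom(n, 2, 0.45),
             r1, r3, rbinom(n, 2, 0.35), rbinom(n, 2, 0.25))
  g <- toy_geno(d, pos = as.integer(c(1:5, 1:4) * 1e4),
                chr = rep("1", 9))
  reported <- prs_model(tibble::tibble(
    variant_id = paste0("v", 1:5), effect_allele = "A",
    weight = log(c(1.2, 1.1, 1.3, 0.9, 1.05)), provenance = "reported"))
  hits <- tibble::tibble(variant_id = paste0("v", 6:9), chr = "1",
                         pos = g$variants$pos[6:9], effect_allele = "A",
                         other_allele = "G", beta = c(0.2, 0.3, 0.1, -0.1))
  merged <- merge_prs(reported, hits, g, r2_replace = 0.8)
  expect_equal(nrow(merged), 7L)  # 5 reported + 2 surviving hits
  expect_setequal(merged$variant_id[merged$provenance == "gwas"],
                  c("v8", "v9"))
  expect_setequal(merged$variant_id[merged$provenance == "merged-replaced"],
                  c("v1", "v3"))
  repl <- attr(merged, "replaced")
  expect_setequal(repl$gwas_variant, c("v6", "v7"))
  # no LD at all: disjoint union
  m2 <- merge_prs(reported, hits[3:4, ], g)
  expect_equal(nrow(m2), 7L)
  # perfect LD everywhere: reported model unchanged in content
  m3 <- merge_prs(reported, hits[1:2, ], g)
  expect_equal(nrow(m3), 5L)
  expect_setequal(m3$variant_id, paste0("v", 1:5))
})
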