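---
title: "Age-of-onset-specific PRS analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-of-onset-specific PRS analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetprs)
```

`onsetprs` studies how polygenic risk for prostate cancer differs between
early-onset disease (exit age ≤ 55 years — the age at diagnosis, or at
censoring for unaffected subjects) and late-onset disease. This vignette
is the package's account of the statistical machinery: what each stage
assumes, which knobs matter, how the synthetic cohorts are built, and
where the design was genuinely open.

## The estimation chain

**Per-variant scans.** `cox_scan()` fits, per variant, a proportional-
hazards model for the event on the *age* timescale with left truncation
at the entry age, so a subject contributes to risk sets only between
enrolment and exit. Ties are handled by the Efron approximation; Newton
iterations are capped at 25 with a tolerance of 1e-9 on the partial
likelihood, and non-convergence is recorded per variant rather than
raised. The proportional-hazards assumption is deliberately applied
*within* each exit-age stratum: the whole point of the age split is that
a variant's hazard ratio need not be constant across ages, and fitting
separate early- and late-onset scans is the piecewise answer to exactly
that violation.

**Quality control.** Variants are kept when MAF ≥ 0.01, call rate > 95%
and the exact Hardy–Weinberg p-value is ≥ 1e-6. The HWE test sums point
probabilities over all heterozygote counts compatible with the observed
allele counts; a chi-square approximation is unusable at a 1e-6
threshold, which lives deep in the tail. The three criteria are evaluated
jointly, so filtering is order-independent.

**Clumping and scoring.** `clump()` is greedy: the lowest-p variant below
the index threshold seeds a clump and absorbs unassigned same-chromosome
variants within the window whose dosage r² reaches the ceiling. Ties on p
are broken by smaller (chr, pos), which makes the result invariant to the
input row order. r² is computed from dosages (composite LD) —
no phasing is available or needed at this scale. For PRS building the
clump *members are discarded* and indices retained; the `ClumpResult`
keeps the membership for inspection. `compute_prs()` aligns each weight
to the matrix's effect allele (flipping dosage to `2 − dosage` on an
allele swap), imputes missing dosages as twice the observed effect-allele
frequency, and errors when more than 20% of the model cannot be scored.
Quintiles use the *reference* population's 20/40/60/80 percentiles with
left-open, right-closed intervals (lowest unbounded): a score equal to
the 40th-percentile cut is quintile 2. The convention is arbitrary but
fixed and tested.

**Incidence weighting.** The weighted Cox stage assigns weight 1 to cases
and `1/inc_t` to non-cases, `inc_t` being the age-specific incidence as a
proportion (rate per 100,000 over 1e5) at the integer part of the exit
age. Banded rates are anchored at band midpoints and interpolated
linearly, flat outside the outermost midpoints; band-*start* anchoring is
available behind the `anchor` switch because the least-surprising reading
of a banded table was genuinely debatable. Any positive rescaling of the
weights leaves the point estimate unchanged (it cancels in the partial
likelihood), so the optional mean-1 normalization of non-case weights is
cosmetic; this is tested to 1e-8. Because the weights make the fit a
pseudo-likelihood, the variance is always the robust sandwich — a
model-based variance would be anti-conservative.

**Heterogeneity.** `cochran_q()` is fixed-effect: inverse-variance
weights, pooled mean, `Q`, `df = k − 1`, `I² = max(0, (Q − df)/Q)·100`,
and an upper chi-square tail for `p_het`. When reproducing printed
results the inputs are exactly the published HR (95% CI) pairs inverted
through `ci_to_se()`. Those CIs carry 2–3 significant digits, and near
`Q ≈ 0` the p-value is sensitive to that rounding; the package's checks
therefore allow a small absolute band plus ten percent relative slack on
p, while I² reproduces within about one point.

**Time-dependent ROC.** `td_roc_km()` implements the cumulative-case /
dynamic-control estimator with Kaplan–Meier plug-ins, taking birth as the
follow-up origin (entry-age truncation is deliberately ignored here, to
mirror the validation construction; the cost is a mild optimism when
scores correlate with entry age — a documented limitation). The cutpoint
grid is the unique observed scores plus ±∞ sentinels, so the curve always
reaches (0,0) and (1,1). The unsmoothed plug-in can leave [0,1] or be
locally non-monotone; raw values are reported, and the AUC integrates the
clipped, cumulative-maximum curve (the clip count is part of the result).
Two exact properties pin the estimator down: with no censoring before the
horizon it equals the empirical ROC, hence the Mann–Whitney statistic,
to numerical precision; and it is invariant under strictly monotone score
transforms. Score *negation* maps AUC to 1 − AUC exactly only without
censoring — negating scores complements the `X > c` stratum, and subgroup
KM estimates do not decompose exactly under censoring — so that property
is checked exactly on uncensored data and loosely otherwise.

**Mendelian randomization.** Instruments are selected by the same greedy
clumping at P < 5e-8, r² < 0.001, 10 Mb. Harmonization keeps matching
alleles, flips swapped ones, resolves strand by complementation, aligns
palindromic variants by allele frequency and drops them as ambiguous when
min(EAF, 1−EAF) > 0.42 on either side — conventional defaults, all
config-overridable. Wald ratios use the first-order SE
(`se_out/|beta_exp|`); IVW is fixed-effect by default with a
multiplicative random-error variant behind a flag. The weighted median
interpolates the 0.5-crossing of the normalized cumulative weights and
gets its SE from a seeded parametric bootstrap (1000 resamples). MR-Egger
regresses sign-oriented outcome effects on |exposure effects| with
weights `1/se_out²` and tests the intercept at `n − 2` df; the classical
WLS SEs are used as-is. The high-confidence filter applies the stated
boundaries exactly: effect tests need p < 0.05, nuisance tests pass at
p ≥ 0.05.

## The synthetic cohorts

The generator exists so that every stage is testable without any
access-controlled data. It emulates:

- **LD structure** via a Gaussian copula: within a block, two latent
  AR(1) haplotypes per subject are thresholded at the variant's drawn
  MAF; blocks are independent. This gives controllable dosage r² without
  a reference panel. The realized r² between two variants depends on
  both the latent correlation and the MAF difference (the phi coefficient
  is bounded by the marginals), which is why LD tests pin MAFs to a
  narrow band.
- **Age-dependent effects**: onset ages invert the cumulative hazard of a
  piecewise-constant baseline multiplied by `exp(burden)`, with the
  burden switching at the age cut — early-onset-specific effects act only
  at ages ≤ 55, late-onset-specific only above, shared always. Causal
  dosages are centered, so the baseline describes the average subject.
- **The cohort frame**: uniform entry at 40–69, censoring at the earliest
  of age 87, entry + 13 years of follow-up, and an exponential loss time
  (0.005/yr). The follow-up cap is what creates an early-onset stratum
  dominated by young entrants, as in the real enrolment design.
- **Family history** as Bernoulli with log-odds
  `qlogis(0.07) + 0.8·z(burden)` — there is no published generative
  mechanism linking PRS and family history, so the slope is a free
  parameter chosen to give roughly two-to-threefold enrichment in
  early-onset cases over non-cases.
- **MR summary statistics** with positive exposure effects (the effect
  allele oriented to increase the exposure), SEs scaling as `1/sqrt(n)`,
  a configurable invalid fraction receiving a pleiotropy intercept, and a
  configurable palindromic fraction.

The default baseline hazard is five times a White-US-male-like
age-banded incidence curve. At desk scale (2×10⁴ subjects, the size used
by the validation runs) the population rates themselves would leave only
about ten early-onset events — unusable for any scan — whereas the 5×
compression preserves the steeply increasing age shape and yields
absolute stratum event counts (roughly 700 early-onset, 4,300 late-onset
at n = 20,000) on the order of the motivating cohort's. The cost is that
*proportional* incidence is several-fold too high; rate-calibrated
realism and desk-scale information content could not both be kept, and
the package keeps the information.

What passing tests do **not** show about real data: the generator has no
population structure, relatedness, imputation uncertainty, genotyping
batch effects, or realistic human LD maps, and its covariates are
independent noise. Parameter recovery here demonstrates that the
*estimators* are correct, not that any real cohort satisfies their
assumptions.

A note on one emergent behaviour: in the default architecture the
general-population PRS tracks the late-onset stratum more strongly than
the early one, because general-scan hits are dominated by the far more
numerous late-onset events. The motivating analyses observed the
opposite gradient for their reported-variant score; reproducing that
would require an architecture calibrated to their (unpublished)
per-stratum effect spectrum, which the generator does not claim.

## Problem sizes and seeds

Validation runs use n = 20,000 subjects × 200 variants for
planted-effect recovery (10 seeds), 200 replicates at n = 2,000 for
type-I-error and coverage checks, 100 seeds at n = 2,000 for the null
AUC, and 500 replicates for the null expectation of Cochran's Q — sizes
chosen so each check has clear resolution while the whole suite stays
interactive. Every stochastic routine takes an explicit integer seed and
restores the caller's RNG state; identical (config, seed) pairs reproduce
byte-identical outputs, which the pipeline's checksummed manifest makes
testable end-to-end.

## Known limitations

- The weighted fits implement per-subject sampling weights with a robust
  variance, not full design-based survey estimation (no strata, clusters
  or finite-population corrections).
- Early/late sub-population weighting reuses the all-ages incidence
  schedule, clamped to the sub-population's age span; sub-range-specific
  schedules would be a defensible alternative.
- The MR stage does not model weak-instrument bias (no F-statistics) and
  offers no MR-PRESSO-style outlier removal or multivariable MR.
- Genome-wide shrinkage scores (LDpred-style) are out of scope; the
  pipeline is clumping + thresholding by design.
- X-chromosome variants, mixed models and relatedness adjustment are not
  handled.
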