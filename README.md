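# onsetprs

Age-of-onset-specific polygenic risk scores (PRS) for prostate cancer, with
incidence-weighted Cox estimation, heterogeneity statistics, time-dependent
ROC validation and a two-sample Mendelian-randomization (MR) screen.

## The problem

Prostate cancer diagnosed at 55 or younger (early-onset, EOPC) carries a
genetic architecture that a genome-wide scan of all ages largely averages
away: variants acting only at young ages are diluted by the far more
numerous late-onset (LOPC) cases. `onsetprs` implements the full analysis
needed to study that contrast in a follow-up cohort:

- **Age-split association scans.** Subjects are partitioned by *exit age*
  (age at diagnosis, or at censoring otherwise) at a cut of 55 years, and
  each variant is tested with a Cox proportional-hazards model on the age
  timescale, `event ~ dosage + covariates`, with left truncation at entry
  (Efron ties). QC keeps variants with MAF ≥ 0.01, exact Hardy–Weinberg
  P ≥ 1e-6 and call rate > 95%.
- **PRS construction.** Suggestive hits (P < 1e-5) are greedily clumped
  (r² < 0.8, 10 Mb window) and scored as `PRS_j = Σ_i β_i · SNP_ij` over
  effect-allele dosages, standardized and quintiled against the general
  population. A *merged* PRS unites a reported variant list with scan hits
  not in LD (r² < 0.8) with any reported variant.
- **Incidence-weighted Cox (WCoxPH).** Hazard ratios per PRS SD use
  sampling weights of 1 for cases and `1/inc_t` for non-cases, where
  `inc_t` is the age-specific incidence linearly interpolated from 5-year
  bands, with a robust sandwich variance.
- **Heterogeneity.** Early- vs late-onset estimates are compared by
  fixed-effect Cochran's Q, `I² = max(0, (Q − df)/Q)·100`, with
  `ci_to_se()` recovering (β, SE) from printed HR/CI pairs.
- **Validation.** Cumulative/dynamic time-dependent ROC curves with the
  Kaplan–Meier plug-in, from birth, at landmark ages 65, 70 (cases ≤ 55
  removed) and 85 (cases ≤ 70 removed).
- **MR screen.** Instruments at P < 5e-8 / r² < 0.001 / 10 Mb, allele
  harmonization, IVW and weighted-median estimates, MR-Egger intercept,
  Cochran's Q over Wald ratios, and the high-confidence filter
  (concordant, both P < 0.05; heterogeneity and Egger P ≥ 0.05).

Real age-of-onset cohorts of this kind are access-controlled, so the
package ships a first-class synthetic-data module: LD-blocked genotypes
(Gaussian-copula haplotypes), onset ages from a piecewise-constant hazard
whose per-subject multiplier switches at the age cut (so early-onset,
late-onset and shared effects can be planted separately), censoring,
burden-linked family history, and paired exposure/outcome summary
statistics for MR.

## Worked example

Heterogeneity between an early-onset and a late-onset hazard ratio, given
only printed HR (95% CI) pairs:

```r
library(onsetprs)
est <- dplyr::bind_rows(
  ci_to_se(2.35, 1.99, 2.78),   # HR per PRS SD, early-onset stratum
  ci_to_se(1.95, 1.89, 2.01))   # late-onset stratum
cochran_q(est)
#> <het_result> Q = 4.629 (df 1), I2 = 78.4%, p_het = 0.0314
```

The early-onset association is genuinely stronger: about 78% of the
between-stratum variation exceeds chance (P ≈ 0.03).

The full synthetic analysis runs in one call and writes versioned TSVs and
a checksummed JSON manifest:

```r
res <- run_pipeline(pipeline_config("run1", seed = 1,
                                    n_samples = 20000, n_variants = 200))
dplyr::filter(res$estimates, prs == "eo", population != "General")
#> EO population: HR = 5.952 (95% CI 4.763-7.436), p = 1.6e-55 (714 events)
#> LO population: HR = 0.995 (95% CI 0.960-1.032), p = 0.79  (4276 events)
dplyr::filter(res$heterogeneity, prs == "eo")
#> Q = 241.4 (df 1), I2 = 99.6%, p_het = 2.0e-54
```

The planted early-onset-specific burden is recovered exactly where it
should be — a strong hazard ratio below the age cut, a null one above it —
which is the qualitative signature the age-split design exists to detect.

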