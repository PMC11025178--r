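# End-to-end orchestration of the synthetic analysis: simulate -> QC ->
# split -> age-specific scans -> clump -> PRS construction/merging ->
# incidence-weighted fits + heterogeneity -> landmark ROC -> MR screen,
# with versioned text outputs and a checksummed JSON manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: QC at
#' MAF >= 0.01, HWE p >= 1e-6, call rate > 95%; scans at the suggestive
#' threshold p < 1e-5 and clumping at r-squared < 0.8 within 10 Mb; merging
#' at r-squared >= 0.8; landmark ROC ages 65, 70 (cases <= 55 removed) and
#' 85 (cases <= 70 removed).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param n_samples,n_variants Synthetic cohort dimensions.
#' @param sim Named list of [sim_config()] overrides applied on top of
#'   [demo_sim_config()].
#' @param covariates Covariate columns used in every fit.
#' @param age_cut Early/late-onset split age.
#' @param qc Named list with `maf_min`, `hwe_p_min`, `call_rate_min`.
#' @param scan_p_index Suggestive threshold for clump index variants.
#' @param clump_r2,clump_window_kb Clumping parameters for PRS building.
#' @param merge_r2 Replacement threshold for [merge_prs()].
#' @param normalize_weights Passed to [make_weights()].
#' @param landmarks Tibble with `predict_time` and `case_exclusion_age`
#'   (NA for none).
#' @param mr Named list of [mr_sim_config()] overrides for the MR stage.
#' @param simulate Generate inputs (default) or load them from
#'   `genotype_file` / `cohort_file`.
#' @param genotype_file,cohort_file,incidence_file Input paths used when
#'   `simulate = FALSE` (the incidence table may also be supplied alongside
#'   simulated data).
#' @param write_vcf Also write genotypes as VCF (default `FALSE`; the TSV
#'   dosage matrix is always written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_samples = 5000, n_variants = 200,
                            sim = list(),
                            covariates = c("bmi", "pc1"),
                            age_cut = 55,
                            qc = list(maf_min = 0.01, hwe_p_min = 1e-6,
                                      call_rate_min = 0.95),
                            scan_p_index = 1e-5,
                            clump_r2 = 0.8, clump_window_kb = 10000,
                            merge_r2 = 0.8,
                            normalize_weights = FALSE,
                            landmarks = tibble(
                              predict_time = c(65, 70, 85),
                              case_exclusion_age = c(NA, 55, 70)),
                            mr = list(n_instruments = 30,
                                      true_causal_effect = 0.2,
                                      invalid_fraction = 0),
                            simulate = TRUE,
                            genotype_file = NULL, cohort_file = NULL,
                            incidence_file = NULL,
                            write_vcf = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

preflight <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- character(0)
  if (!config$simulate) {
    for (f in c("genotype_file", "cohort_file")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        problems <- c(problems, sprintf("`%s` missing or nonexistent", f))
      }
    }
    if (is.null(config$incidence_file) ||
        !file.exists(config$incidence_file)) {
      problems <- c(problems,
                    "`incidence_file` required when not simulating (weighting needs an incidence table)")
    }
  } else if (!is.null(config$incidence_file) &&
             !file.exists(config$incidence_file)) {
    problems <- c(problems, "`incidence_file` does not exist")
  }
  if (!all(c("predict_time") %in% names(config$landmarks))) {
    problems <- c(problems, "`landmarks` needs a `predict_time` column")
  }
  if (length(problems)) {
    rlang::abort(paste0("pre-flight validation failed:\n",
                        paste("-", problems, collapse = "\n")),
                 class = "onsetprs_preflight_error")
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                         conditionMessage(e)),
                 class = "onsetprs_stage_error", stage = name, parent = e)
  })
}

#' Run the end-to-end synthetic analysis
#'
#' Executes every stage in order, writes versioned TSV/JSON outputs under
#' `config$out_dir`, and returns the results plus a manifest holding the
#' parameters, per-stage row counts and MD5 checksums of every written
#' file. Identical configurations (including the seed) reproduce identical
#' manifests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest`, `estimates`, `heterogeneity`,
#'   `roc`, `mr`, `models`, and `paths`.
#' @export
run_pipeline <- function(config) {
  preflight(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(x, name, writer = readr::write_tsv) {
    p <- file.path(config$out_dir, name)
    writer(x, p)
    paths[[name]] <<- p
    p
  }

  # --- simulate or load -----------------------------------------------
  if (config$simulate) {
    sc <- run_stage("simulate", {
      do.call(demo_sim_config, c(
        list(n_samples = config$n_samples, n_variants = config$n_variants,
             seed = config$seed, age_cut = config$age_cut),
        config$sim))
    })
    g <- run_stage("simulate", simulate_genotypes(sc))
    cohort <- run_stage("simulate", simulate_onset(g, sc))
    bands <- if (!is.null(config$incidence_file)) {
      read_incidence_tsv(config$incidence_file)
    } else {
      sim_incidence_bands(sc)
    }
    emit(cohort, "cohort.tsv")
    emit(bands, "incidence.tsv")
    run_stage("simulate", write_dosage_tsv(g, file.path(config$out_dir,
                                                        "dosages.tsv")))
    paths[["dosages.tsv"]] <- file.path(config$out_dir, "dosages.tsv")
    if (config$write_vcf) {
      run_stage("simulate", write_vcf(g, file.path(config$out_dir,
                                                   "genotypes.vcf")))
      paths[["genotypes.vcf"]] <- file.path(config$out_dir, "genotypes.vcf")
    }
    true_sets <- sc$causal_sets
  } else {
    g <- run_stage("load", read_dosage_tsv(config$genotype_file))
    cohort <- run_stage("load", read_cohort_tsv(config$cohort_file))
    bands <- run_stage("load", read_incidence_tsv(config$incidence_file))
    true_sets <- NULL
  }

  # --- qc ---------------------------------------------------------------
  g_qc <- run_stage("qc", do.call(variant_qc, c(list(g), config$qc)))
  qc_report <- attr(g_qc, "qc_report")
  emit(qc_report, "qc_report.tsv")

  # --- split ------------------------------------------------------------
  pops <- run_stage("split", split_population(cohort, config$age_cut))
  pops <- c(list(general = mutate(cohort, population_label = "General")),
            pops)

  # --- scans ------------------------------------------------------------
  scans <- run_stage("scan", purrr::imap(pops, function(pop, nm) {
    subset_g <- subset_samples(g_qc, match(pop$sample_id, g_qc$samples))
    cox_scan(subset_g, pop, covariate_names = config$covariates)
  }))
  for (nm in names(scans)) {
    emit(scans[[nm]], sprintf("scan_%s.tsv", nm))
  }

  # --- clump + PRS models ----------------------------------------------
  models <- run_stage("clump", purrr::imap(scans, function(sc_tbl, nm) {
    cl <- clump(sc_tbl, g_qc, p_index = config$scan_p_index,
                r2_max = config$clump_r2,
                window_kb = config$clump_window_kb)
    hits <- filter(sc_tbl, .data$variant_id %in% cl$index_variants)
    if (nrow(hits) == 0L) return(NULL)
    prs_model(dplyr::transmute(
      hits, variant_id = .data$variant_id, chr = .data$chr,
      pos = .data$pos, effect_allele = .data$effect_allele,
      other_allele = .data$other_allele, weight = .data$beta,
      provenance = "gwas"), name = nm)
  }))
  models <- models[!vapply(models, is.null, logical(1))]

  reported <- NULL
  if (!is.null(true_sets)) {
    idx <- c(true_sets$eo$idx, true_sets$lo$idx, true_sets$shared$idx)
    beta <- c(true_sets$eo$beta, true_sets$lo$beta, true_sets$shared$beta)
    keep <- g$variants$variant_id[idx] %in% g_qc$variants$variant_id
    if (any(keep)) {
      reported <- prs_model(tibble(
        variant_id = g$variants$variant_id[idx][keep],
        chr = g$variants$chr[idx][keep], pos = g$variants$pos[idx][keep],
        effect_allele = g$variants$effect_allele[idx][keep],
        other_allele = g$variants$other_allele[idx][keep],
        weight = beta[keep], provenance = "reported"), name = "reported")
      models$reported <- reported
    }
  }
  if (!is.null(reported)) {
    for (nm in intersect(c("general", "eo", "lo"), names(models))) {
      gw <- rename(as_tibble(models[[nm]]), beta = "weight")
      merged <- run_stage("merge", merge_prs(reported, gw, g_qc,
                                             r2_replace = config$merge_r2))
      attr(merged, "name") <- paste0("merged_", nm)
      models[[paste0("merged_", nm)]] <- merged
    }
  }
  for (nm in names(models)) {
    emit(as_tibble(models[[nm]]), sprintf("prs_model_%s.tsv", nm))
  }

  # --- scores -----------------------------------------------------------
  scores <- run_stage("prs", purrr::map(models, function(m) {
    sc_tbl <- compute_prs(g_qc, m)
    std <- standardize_and_quintile(sc_tbl$score, sc_tbl$score)
    mutate(sc_tbl, z = std$z, quintile = std$quintile)
  }))
  for (nm in names(scores)) {
    emit(scores[[nm]], sprintf("scores_%s.tsv", nm))
  }

  # --- weighted fits + heterogeneity -----------------------------------
  sched <- run_stage("weights", interpolate_incidence(
    bands, ages = seq(ceiling(min(bands$age_start)),
                      floor(max(bands$age_end)))))
  w_all <- run_stage("weights", make_weights(cohort, sched,
                                             normalize = config$normalize_weights))
  names(w_all) <- cohort$sample_id
  fits <- list(); het <- list()
  for (nm in names(models)) {
    z_all <- setNames(scores[[nm]]$z, scores[[nm]]$sample_id)
    ests <- purrr::imap(pops, function(pop, pnm) {
      if (sum(pop$event) == 0L) return(NULL)
      run_stage("wcox", weighted_cox_fit(
        pop, z_all[pop$sample_id],
        covariate_names = config$covariates,
        weights = w_all[pop$sample_id],
        population_tag = pop$population_label[1] %||% pnm))
    })
    ests <- ests[!vapply(ests, is.null, logical(1))]
    fits[[nm]] <- ests
    if (all(c("eo", "lo") %in% names(ests))) {
      het[[nm]] <- run_stage("het", cochran_q(list(ests$eo, ests$lo)))
    }
  }
  estimates <- purrr::imap(fits, function(ests, nm) {
    mutate(bind_rows(purrr::map(ests, tidy)), prs = nm, .before = 1)
  }) |> bind_rows()
  emit(estimates, "estimates.tsv")
  het_tbl <- purrr::imap(het, function(h, nm) {
    mutate(tidy(h), prs = nm, .before = 1)
  }) |> bind_rows()
  if (nrow(het_tbl)) emit(het_tbl, "heterogeneity.tsv")

  # --- landmark ROC -----------------------------------------------------
  roc <- list()
  for (nm in names(models)) {
    z_all <- setNames(scores[[nm]]$z, scores[[nm]]$sample_id)
    for (i in seq_len(nrow(config$landmarks))) {
      pt <- config$landmarks$predict_time[i]
      ex <- config$landmarks$case_exclusion_age[i]
      r <- run_stage("tdroc", tryCatch(
        landmark_roc(cohort, z_all[cohort$sample_id], pt,
                     case_exclusion_age = if (is.na(ex)) NULL else ex),
        onsetprs_no_events = function(e) NULL))
      if (!is.null(r)) {
        roc[[sprintf("%s_t%g", nm, pt)]] <- r
      }
    }
  }
  roc_tbl <- purrr::imap(roc, function(r, nm) {
    mutate(glance(r), label = nm, .before = 1)
  }) |> bind_rows()
  if (nrow(roc_tbl)) emit(roc_tbl, "tdroc.tsv")

  # --- MR screen --------------------------------------------------------
  mr_cfg <- run_stage("mr", do.call(mr_sim_config, c(
    list(seed = config$seed + 2L), config$mr)))
  ss <- run_stage("mr", simulate_mr_sumstats(mr_cfg))
  emit(ss$exposure, "mr_exposure.tsv")
  emit(select(ss$outcome, -"invalid"), "mr_outcome.tsv")
  keep <- ss$exposure$p < 5e-8
  mr_res <- NULL
  if (sum(keep) >= 3L) {
    harm <- run_stage("mr", harmonize(ss$exposure[keep, ],
                                      ss$outcome[keep, ]))
    mr_res <- run_stage("mr", mr_analyze(harm, exposure_id = "sim_exposure",
                                         outcome_id = "sim_outcome",
                                         seed = config$seed + 3L))
    emit(bind_rows(tidy(mr_res)), "mr_estimates.tsv")
    emit(glance(mr_res), "mr_summary.tsv")
  }

  # --- manifest ---------------------------------------------------------
  n_qc_removed <- sum(qc_report$removed)
  manifest <- list(
    seed = config$seed,
    parameters = list(
      n_samples = nrow(cohort), n_variants = ncol(g$dosages),
      age_cut = config$age_cut, qc = config$qc,
      scan_p_index = config$scan_p_index, clump_r2 = config$clump_r2,
      clump_window_kb = config$clump_window_kb,
      merge_r2 = config$merge_r2),
    counts = list(
      variants_in = ncol(g$dosages),
      variants_removed_qc = n_qc_removed,
      variants_scanned = ncol(g_qc$dosages),
      samples_in = nrow(cohort),
      samples_eo = nrow(pops$eo), samples_lo = nrow(pops$lo),
      events = sum(cohort$event),
      models = names(models)),
    checksums = as.list(tools::md5sum(unlist(paths)))
  )
  names(manifest$checksums) <- names(paths)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths[["manifest.json"]] <- manifest_path

  invisible(list(manifest = manifest, estimates = estimates,
                 heterogeneity = het_tbl, roc = roc_tbl, mr = mr_res,
                 models = models, paths = paths))
}
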