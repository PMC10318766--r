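#' Assemble the analysis cohort (study-flow exclusions)
#'
#' Applies the eight cohort-flow exclusions in their fixed order:
#' (1) history of hepatitis; (2) heavy drinkers (>= 30 g alcohol/day men,
#' >= 20 g/day women); (3) insufficient baseline data for the liver fat
#' score; (4) NAFLD at baseline; (5) no follow-up during the exposure
#' period; (6) NAFLD developing during the exposure period; (7) no
#' follow-up during the event-accrual period; (8) no genotype data. The
#' order changes per-step counts but not the final set.
#'
#' @param derived Visit table after [derive_covariates()].
#' @param genotypes A `genotype_matrix` (or NULL to skip filter 8).
#' @param n_exposure_visits Number of exposure-period visits (default 4).
#' @return List: `analysis_ids` (participants passing all filters),
#'   `flow_report` (step, reason, n_removed, n_remaining).
#' @export
assemble_cohort <- function(derived, genotypes = NULL,
                            n_exposure_visits = 4L) {
  base <- derived[derived$visit_index == 0L, ]
  ids <- base$participant_id
  if (anyDuplicated(ids)) stop("duplicate baseline records")
  n0 <- length(ids)

  expo <- derived[derived$visit_index > 0L &
                    derived$visit_index < n_exposure_visits, ]
  accr <- derived[derived$visit_index >= n_exposure_visits, ]
  has_expo <- unique(expo$participant_id[!is.na(expo$non_hdl)])
  expo_nafld <- unique(expo$participant_id[!is.na(expo$nafld) & expo$nafld])
  has_accr <- unique(accr$participant_id)

  hep <- if ("hepatitis" %in% names(base))
    !is.na(base$hepatitis) & base$hepatitis else rep(FALSE, n0)
  heavy <- !is.na(base$heavy_drinker_excluded) & base$heavy_drinker_excluded
  no_lfs <- is.na(base$nafld_lfs)
  base_nafld <- !is.na(base$nafld) & base$nafld

  filters <- list(
    hepatitis_history = hep,
    heavy_drinker = heavy,
    insufficient_lfs_data = no_lfs,
    baseline_nafld = base_nafld,
    no_exposure_followup = !(ids %in% has_expo),
    exposure_period_nafld = ids %in% expo_nafld,
    no_event_accrual_followup = !(ids %in% has_accr),
    no_genotype = if (is.null(genotypes)) rep(FALSE, n0)
                  else !(ids %in% genotypes$sample_ids))

  remaining <- rep(TRUE, n0)
  rows <- vector("list", length(filters))
  for (i in seq_along(filters)) {
    hit <- remaining & filters[[i]]
    remaining <- remaining & !hit
    rows[[i]] <- data.frame(step = i, reason = names(filters)[i],
                            n_removed = sum(hit),
                            n_remaining = sum(remaining),
                            stringsAsFactors = FALSE)
  }
  report <- rbind(data.frame(step = 0L, reason = "initial",
                             n_removed = 0L, n_remaining = n0,
                             stringsAsFactors = FALSE),
                  do.call(rbind, rows))
  if (!any(remaining)) stop("empty analysis set after cohort-flow filters")
  list(analysis_ids = ids[remaining], flow_report = report)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: simulate (or accept) a cohort, derive
#' phenotypes, assemble the analysis set, fit the non-HDL trajectory
#' model and name the groups, run the survival analyses (person-years,
#' per-visit incidence, Kaplan-Meier/log-rank, Cox models 0-4), perform
#' genotype QC, genotype PCs and stratified association scans for the
#' requested adjustment models, and build the interaction PRS with the
#' control / stable / increasing comparison. All randomness derives from
#' `config$seed`, so reruns with the same configuration are reproducible.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory for TSV/JSON artifacts (created if
#'   needed); NULL skips writing.
#' @param cohort Optional pre-built [simulate_cohort()] object (must match
#'   `config`).
#' @param models Scan adjustment models to run (subset of 1:4).
#' @param K Trajectory classes: an integer, or "auto" for BIC selection
#'   up to `K_max`.
#' @param K_max Upper bound for BIC selection when `K = "auto"`.
#' @param degree Polynomial degree of the trajectory curves.
#' @param n_starts EM restarts.
#' @param ties Cox ties method.
#' @param maf_diff_cut PRS minor-allele-frequency-difference exclusion.
#' @param n_pcs Genotype PCs used as scan covariates.
#' @param n_perm Permutation replicates in the PRS group comparison.
#' @param write_genotype_files Also emit VCF and dosage-text genotype
#'   files (off by default; they dominate output size).
#' @param verbose Log stage progress via `message()`.
#' @return List with every stage result: `cohort`, `derived`, `flow`,
#'   `trajectory` (model, groups), `survival` (records, person_years,
#'   incidence, km, cox), `gwas` (per model: sumstats, lambda), `prs`
#'   (per model: weights, scores, comparison), `config`.
#' @export
run_all <- function(config = cohort_config(), out_dir = NULL,
                    cohort = NULL, models = 1L, K = 2L, K_max = 4L,
                    degree = 1L, n_starts = 10L,
                    ties = c("efron", "breslow"), maf_diff_cut = 0.20,
                    n_pcs = 10L, n_perm = 0L,
                    write_genotype_files = FALSE, verbose = TRUE) {
  ties <- match.arg(ties)
  stopifnot(all(models %in% 1:4))
  say <- function(...) if (verbose) message("[nafldtraj] ", ...)
  t0 <- Sys.time()

  if (is.null(cohort)) {
    say("simulating cohort (seed ", config$seed, ")")
    cohort <- simulate_cohort(config)
  }
  nvE <- config$n_exposure_visits

  say("deriving phenotypes")
  derived <- derive_covariates(cohort$cohort_table)

  say("assembling analysis cohort")
  asm <- assemble_cohort(derived, cohort$genotypes, nvE)
  ids <- asm$analysis_ids

  say("fitting trajectory model (", length(ids), " participants)")
  expo <- derived[derived$participant_id %in% ids &
                    derived$visit_index < nvE &
                    !is.na(derived$non_hdl), ]
  series <- data.frame(participant_id = expo$participant_id,
                       years = expo$visit_index * config$visit_spacing_years,
                       non_hdl = expo$non_hdl)
  K_used <- K
  bic <- NULL
  if (identical(K, "auto")) {
    K_used <- select_num_classes(series, K_max = K_max, degree = degree,
                                 seed = config$seed, n_starts = n_starts)
    bic <- attr(K_used, "bic")
    say("BIC selected K = ", K_used)
  }
  model <- fit_trajectory_model(series, K = as.integer(K_used),
                                degree = degree, n_starts = n_starts,
                                seed = config$seed)
  groups <- assign_groups(model)

  say("survival analysis")
  rec <- build_survival_records(derived, groups, nvE,
                                config$visit_spacing_years)
  py <- person_years(rec)
  inc_tab <- incidence_by_visit(derived, groups, nvE,
                                config$visit_spacing_years)
  rates <- data.frame(
    group = c("stable", "increasing"),
    n = as.integer(table(rec$group)),
    cases = as.integer(tapply(rec$event, rec$group, sum)),
    person_years = as.numeric(py[c("stable", "increasing")]))
  rates$rate_per_1000py <- incidence_rate_per_1000py(rates$cases,
                                                     rates$person_years)
  km <- km_logrank(rec)
  cox <- lapply(stats::setNames(0:4, paste0("model", 0:4)),
                function(mid) cox_fit(rec, mid, ties = ties))

  say("genotype QC and principal components")
  g_set <- subset_genotypes(cohort$genotypes,
                            samples = rec$participant_id)
  g_qc <- snp_qc(g_set)
  g_qc <- sample_qc(g_qc)
  g_qc <- snp_qc(g_qc)
  pcs <- compute_pcs(g_qc, n_components = n_pcs,
                     seed = substream_seed(config$seed, "genotypes"))

  scan_ids <- g_qc$sample_ids
  rec_idx <- match(scan_ids, rec$participant_id)
  pheno <- rec$event[rec_idx]
  covars <- cbind(rec[rec_idx, c("age", "sex", "bmi", "energy_intake",
                                 "smoking", "current_drinker",
                                 "pa_category", "htn", "dm", "crp",
                                 "alt")],
                  as.data.frame(pcs$scores))
  strata <- as.character(rec$group[rec_idx])

  gwas <- list()
  prs <- list()
  # control pool: genotyped participants outside the analysis set with no
  # observed NAFLD at any attended visit
  pool <- setdiff(cohort$genotypes$sample_ids, ids)
  hist_tab <- tapply(!is.na(derived$nafld) & derived$nafld,
                     derived$participant_id, any)
  controls <- select_control_group(pool, length(ids), hist_tab,
                                   seed = substream_seed(config$seed,
                                                         "control"))
  score_ids <- c(controls, ids)
  g_score <- subset_genotypes(cohort$genotypes, samples = score_ids)
  group_all <- c(stats::setNames(rep("control", length(controls)),
                                 controls),
                 stats::setNames(unname(groups[ids]), ids))

  for (mid in models) {
    say("association scan, model ", mid)
    scans <- lapply(c(increasing = "increasing", stable = "stable"),
                    function(s) {
      sel <- strata == s
      association_scan(pheno[sel],
                       subset_genotypes(g_qc, samples = which(sel)),
                       covars[sel, , drop = FALSE],
                       model_id = mid, stratum = s, n_pcs = n_pcs)
    })
    sums <- rbind(scans$increasing, scans$stable)
    infl <- lapply(scans, genomic_inflation)
    gwas[[paste0("model", mid)]] <-
      list(sumstats = sums,
           lambda = vapply(infl, `[[`, numeric(1), "lambda"),
           qq = lapply(infl, `[[`, "qq"))

    say("interaction PRS, model ", mid)
    w <- compute_diff_weights(scans$increasing, scans$stable,
                              maf_diff_cut = maf_diff_cut)
    sc <- interaction_prs(w, subset_genotypes(g_score,
                                              variants = w$snp[w$included]))
    pr <- prs_result(sc, group_all, model_id = mid)
    cmp <- compare_groups(pr, n_perm = n_perm,
                          seed = substream_seed(config$seed, "control"))
    prs[[paste0("model", mid)]] <- list(weights = w, scores = pr,
                                        comparison = cmp)
  }

  res <- list(cohort = cohort, derived = derived, flow = asm$flow_report,
              trajectory = list(model = model, groups = groups,
                                K = as.integer(K_used), bic = bic,
                                curves = trajectory_curves(model)),
              survival = list(records = rec, person_years = py,
                              rates = rates, incidence = inc_tab,
                              km = km, cox = cox),
              gwas = gwas, prs = prs,
              qc = list(snp = attr(g_qc, "qc_report"),
                        pcs_explained = pcs$explained),
              controls = controls,
              config = config)

  if (!is.null(out_dir)) {
    say("writing outputs to ", out_dir)
    write_pipeline_outputs(res, out_dir, write_genotype_files)
  }
  say("done in ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir, write_genotype_files) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  cfg <- res$config
  jsonlite::write_json(unclass(cfg), fp("config.json"), auto_unbox = TRUE,
                       digits = NA)

  write_cohort(res$cohort$cohort_table, fp("cohort.tsv"))
  if (write_genotype_files) {
    write_genotypes_vcf(res$cohort$genotypes, fp("genotypes.vcf"))
    write_genotypes_dosage(res$cohort$genotypes, fp("genotypes_dosage.tsv"))
  }
  write_tsv_out(res$flow, fp("cohort_flow.tsv"))

  grp <- res$trajectory$groups
  write_tsv_out(data.frame(participant_id = names(grp),
                           group = unname(grp)),
                fp("trajectory_labels.tsv"))
  tm <- res$trajectory$model
  jsonlite::write_json(
    list(K = tm$K, degree = tm$degree,
         coefficients = tm$coefficients,
         residual_sd = tm$residual_sd,
         class_weights = tm$class_weights,
         log_likelihood = tm$log_likelihood),
    fp("trajectory_model.json"), auto_unbox = TRUE, digits = NA)
  write_tsv_out(res$trajectory$curves, fp("trajectory_curves.tsv"))

  write_tsv_out(res$survival$rates, fp("incidence_rates.tsv"))
  write_tsv_out(res$survival$incidence, fp("incidence_by_visit.tsv"))
  write_tsv_out(res$survival$km$km, fp("km_curves.tsv"))
  jsonlite::write_json(list(chisq = res$survival$km$chisq,
                            p = res$survival$km$p),
                       fp("logrank.json"), auto_unbox = TRUE, digits = NA)
  cox_tab <- do.call(rbind, lapply(res$survival$cox, function(cf) {
    i <- grep("^group", names(cf$hr))[1]
    data.frame(model = cf$model_id, hr = cf$hr[i],
               ci_lower = cf$ci95[i, 1], ci_upper = cf$ci95[i, 2],
               p = cf$p[i], n_events = cf$n_events)
  }))
  write_tsv_out(cox_tab, fp("cox_models.tsv"))

  for (nm in names(res$gwas)) {
    write_tsv_out(res$gwas[[nm]]$sumstats, fp(paste0("sumstats_", nm, ".tsv")))
    jsonlite::write_json(as.list(res$gwas[[nm]]$lambda),
                         fp(paste0("lambda_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_tsv_out(res$gwas[[nm]]$qq$increasing,
                  fp(paste0("qq_increasing_", nm, ".tsv")))
    write_tsv_out(res$gwas[[nm]]$qq$stable,
                  fp(paste0("qq_stable_", nm, ".tsv")))
  }
  for (nm in names(res$prs)) {
    write_tsv_out(res$prs[[nm]]$weights, fp(paste0("prs_weights_", nm, ".tsv")))
    write_tsv_out(res$prs[[nm]]$scores, fp(paste0("prs_scores_", nm, ".tsv")))
    write_tsv_out(res$prs[[nm]]$comparison$table,
                  fp(paste0("prs_forest_", nm, ".tsv")))
    write_tsv_out(res$prs[[nm]]$comparison$pairwise,
                  fp(paste0("prs_pairwise_", nm, ".tsv")))
  }
  invisible(out_dir)
}
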