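#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the scale of the motivating cohort design: 9 biennial
#' visits (4 exposure-period visits used for trajectory fitting, 5
#' event-accrual visits), trajectory group sizes 1269 (stable) / 934
#' (increasing), a per-interval discrete-time event hazard tuned so that
#' cumulative incidence over the accrual period is about 30% with a
#' group odds ratio of 1.5, and baseline non-HDL cholesterol of 129
#' (stable) vs 154 mg/dL (increasing, rising 8 mg/dL per visit).
#'
#' @param n_stable,n_increasing Trajectory group sizes.
#' @param n_control_pool Participants outside the trajectory analysis set,
#'   available as the control pool for PRS comparisons.
#' @param n_snps Number of simulated independent SNPs.
#' @param n_causal_shared SNPs with a liability effect in both groups.
#' @param n_causal_increasing_only SNPs whose liability effect acts only in
#'   the increasing group; these same SNPs carry the genetic component of
#'   trajectory-group membership (see [simulate_cohort()]).
#' @param maf_range Minor allele frequency range, within (0, 0.5].
#' @param visit_spacing_years Years between visits (default 2).
#' @param n_exposure_visits,n_event_visits Visits in the exposure and
#'   event-accrual windows.
#' @param stable_nonhdl_mean,increasing_nonhdl_start Baseline non-HDL
#'   cholesterol means, mg/dL.
#' @param increasing_slope Non-HDL rise per visit in the increasing group,
#'   mg/dL.
#' @param nonhdl_noise_sd Visit-level measurement noise SD, mg/dL.
#' @param lipid_intercept_sd Between-participant intercept SD, mg/dL.
#' @param baseline_hazard_logit Logit of the per-interval event
#'   probability in the stable group at zero genetic liability.
#' @param group_log_hr Log odds ratio of the per-interval event
#'   probability, increasing vs stable.
#' @param causal_effect_size Per-allele liability effect (log-odds).
#' @param dropout_prob_per_visit Probability a non-baseline visit is
#'   missed (independent across visits; baseline always attended).
#' @param geno_missing_prob Per-genotype missingness probability.
#' @param group_genetic_weight Weight of the standardized genetic score in
#'   the trajectory-membership liability (noise SD fixed at 1).
#' @param control_history_prob Fraction of the control pool carrying
#'   baseline NAFLD (excluded when controls are selected).
#' @param seed Integer master seed; expanded into independent per-stage
#'   substreams.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_stable = 1269L,
                          n_increasing = 934L,
                          n_control_pool = 3000L,
                          n_snps = 1000L,
                          n_causal_shared = 10L,
                          n_causal_increasing_only = 20L,
                          maf_range = c(0.05, 0.5),
                          visit_spacing_years = 2,
                          n_exposure_visits = 4L,
                          n_event_visits = 5L,
                          stable_nonhdl_mean = 129,
                          increasing_nonhdl_start = 154,
                          increasing_slope = 8,
                          nonhdl_noise_sd = 10,
                          lipid_intercept_sd = 6,
                          baseline_hazard_logit = -2.79,
                          group_log_hr = log(1.5),
                          causal_effect_size = 0.2,
                          dropout_prob_per_visit = 0.07,
                          geno_missing_prob = 0.005,
                          group_genetic_weight = 1,
                          control_history_prob = 0.15,
                          seed = 1L) {
  cfg <- list(
    n_stable = as.integer(n_stable), n_increasing = as.integer(n_increasing),
    n_control_pool = as.integer(n_control_pool), n_snps = as.integer(n_snps),
    n_causal_shared = as.integer(n_causal_shared),
    n_causal_increasing_only = as.integer(n_causal_increasing_only),
    maf_range = as.numeric(maf_range),
    visit_spacing_years = visit_spacing_years,
    n_exposure_visits = as.integer(n_exposure_visits),
    n_event_visits = as.integer(n_event_visits),
    stable_nonhdl_mean = stable_nonhdl_mean,
    increasing_nonhdl_start = increasing_nonhdl_start,
    increasing_slope = increasing_slope,
    nonhdl_noise_sd = nonhdl_noise_sd,
    lipid_intercept_sd = lipid_intercept_sd,
    baseline_hazard_logit = baseline_hazard_logit,
    group_log_hr = group_log_hr,
    causal_effect_size = causal_effect_size,
    dropout_prob_per_visit = dropout_prob_per_visit,
    geno_missing_prob = geno_missing_prob,
    group_genetic_weight = group_genetic_weight,
    control_history_prob = control_history_prob,
    seed = as.integer(seed))

  counts <- c("n_stable", "n_increasing", "n_control_pool", "n_snps",
              "n_exposure_visits", "n_event_visits")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop("configuration error: ", nm, " must be >= 1")
  if (cfg$n_causal_shared < 0L || cfg$n_causal_increasing_only < 0L)
    stop("configuration error: causal SNP counts must be >= 0")
  if (cfg$n_causal_shared + cfg$n_causal_increasing_only > cfg$n_snps)
    stop("configuration error: more causal SNPs than SNPs")
  if (length(cfg$maf_range) != 2L || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("configuration error: maf_range must lie within (0, 0.5]")
  if (cfg$dropout_prob_per_visit < 0 || cfg$dropout_prob_per_visit >= 1)
    stop("configuration error: dropout_prob_per_visit must be in [0, 1)")
  if (cfg$geno_missing_prob < 0 || cfg$geno_missing_prob >= 1)
    stop("configuration error: geno_missing_prob must be in [0, 1)")
  class(cfg) <- "cohort_config"
  cfg
}

# Independent per-stage RNG substreams from one master seed.
substream_seed <- function(seed, stage) {
  offs <- c(genotypes = 1L, labels = 2L, lipids = 3L, outcomes = 4L,
            components = 5L, covariates = 6L, missing = 7L, control = 8L)
  if (!stage %in% names(offs)) stop("unknown RNG stage: ", stage)
  as.integer((as.double(seed) * 7919 + 104729 * offs[[stage]]) %%
               .Machine$integer.max)
}

#' Simulate independent Hardy-Weinberg genotypes
#'
#' Each SNP draws its allele frequency from `Uniform(maf_range)` and each
#' individual's dosage from `Binomial(2, maf)` independently, so
#' Hardy-Weinberg proportions hold by construction and loci are unlinked.
#'
#' @param n Individuals.
#' @param m SNPs.
#' @param maf_range Allele-frequency range within (0, 0.5].
#' @param seed Integer seed.
#' @param missing_prob Per-genotype missingness probability (default 0).
#' @return A `genotype_matrix`: list with integer `dosages` (n x m, NA =
#'   missing), `sample_ids`, and a `variants` data frame (id, chrom, pos,
#'   ref, alt, maf_true).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1L,
                               missing_prob = 0) {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("configuration error: maf_range must lie within (0, 0.5]")
  set.seed(seed)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  if (missing_prob > 0) {
    dos[stats::runif(n * m) < missing_prob] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(m) - 1L) %% 4L + 1L]
  alt <- bases[seq_len(m) %% 4L + 1L]
  g <- list(
    dosages = dos,
    sample_ids = sprintf("P%05d", seq_len(n)),
    variants = data.frame(
      id = sprintf("snp%05d", seq_len(m)),
      chrom = as.character((seq_len(m) - 1L) %% 22L + 1L),
      pos = 1e4L + 37L * seq_len(m),
      ref = ref, alt = alt,
      maf_true = maf,
      stringsAsFactors = FALSE))
  rownames(g$dosages) <- g$sample_ids
  colnames(g$dosages) <- g$variants$id
  class(g) <- "genotype_matrix"
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}

#' Simulate exposure-period non-HDL cholesterol series
#'
#' Stable and control participants follow a flat mean; increasing
#' participants rise linearly per visit. Every participant carries a
#' Gaussian random intercept and visit-level measurement noise. Visits
#' after baseline are missed independently with the dropout probability;
#' baseline is never missing.
#'
#' @param labels Character vector in {"stable","increasing","control"},
#'   optionally named by participant id.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Long data frame: `participant_id`, `label`, `visit_index`
#'   (0-based), `years`, `non_hdl`. Only observed visits appear.
#' @export
simulate_lipid_series <- function(labels, config, seed = config$seed) {
  if (!all(labels %in% c("stable", "increasing", "control")))
    stop("unknown group label")
  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("P%05d", seq_len(n))
  nv <- config$n_exposure_visits
  set.seed(substream_seed(seed, "lipids"))
  intercept <- stats::rnorm(n, 0, config$lipid_intercept_sd)
  visit <- rep(seq_len(nv) - 1L, each = n)
  base <- ifelse(labels == "increasing", config$increasing_nonhdl_start,
                 config$stable_nonhdl_mean)
  slope <- ifelse(labels == "increasing", config$increasing_slope, 0)
  mu <- rep(base, nv) + rep(slope, nv) * visit + rep(intercept, nv)
  y <- mu + stats::rnorm(n * nv, 0, config$nonhdl_noise_sd)
  attended <- c(rep(TRUE, n),
                stats::runif(n * (nv - 1L)) >= config$dropout_prob_per_visit)
  out <- data.frame(
    participant_id = rep(ids, nv),
    label = rep(unname(labels), nv),
    visit_index = visit,
    years = visit * config$visit_spacing_years,
    non_hdl = y,
    stringsAsFactors = FALSE)[attended, ]
  rownames(out) <- NULL
  attr(out, "intercepts") <- stats::setNames(intercept, ids)
  out
}

# Liver-fat-score components consistent with a target NAFLD status.
# Components are drawn from case / non-case distributions and fasting
# insulin is solved from a target score, so applying the liver fat score
# to the emitted columns reproduces the intended status exactly (a
# simulation convenience making phenotype derivation invertible).
sim_lfs_components <- function(n, case) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  if (n == 0L)
    return(data.frame(mets_flag = integer(), dm_flag = integer(),
                      ast = numeric(), alt = numeric(),
                      insulin = numeric()))
  if (case) {
    mets <- stats::rbinom(n, 1L, 0.5)
    dm <- stats::rbinom(n, 1L, 0.05)
    ast <- clip(stats::rnorm(n, 30, 7), 15, 60)
    alt <- clip(stats::rnorm(n, 28, 7), 12, 70)
    target <- stats::runif(n, -0.5, 0.8)
  } else {
    mets <- integer(n)
    # low background diabetes prevalence; the component bounds keep even a
    # clamped-insulin diabetic non-case below the NAFLD threshold
    dm <- stats::rbinom(n, 1L, 0.017)
    ast <- clip(stats::rnorm(n, 24, 5), 12, 45)
    alt <- clip(stats::rnorm(n, 25, 6), 12, 60)
    target <- stats::runif(n, -2.5, -0.9)
  }
  insulin <- (target + 2.89 - 1.18 * mets - 0.9 * dm - 0.04 * ast +
                0.94 * ast / alt) / 0.15
  # Clamping can only raise the score; bounds on the component ranges keep
  # a clamped non-case below the threshold and a clamped case above it.
  insulin <- pmax(insulin, 0.5)
  data.frame(mets_flag = mets, dm_flag = dm, ast = ast, alt = alt,
             insulin = insulin)
}

#' Simulate interval-detected NAFLD outcomes
#'
#' Applies a discrete-time hazard at each event-accrual visit:
#' `expit(baseline_hazard_logit + group_log_hr * I[increasing] + genetic
#' liability)`, where the genetic liability sums the centered dosages of
#' the causal SNPs times their (possibly group-specific) effects. Onset is
#' the first Bernoulli success; the event is detected at the first
#' attended visit at or after onset, otherwise the participant is censored
#' at the last attended accrual visit. Control-pool participants accrue no
#' events.
#'
#' @param draft List with `labels`, `genotypes` ([simulate_genotypes()]
#'   output covering all participants in `labels` order) and
#'   `truth_weights` (per-SNP `shared_effect`, `increasing_effect`).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List: `true_event_visit` (named integer, NA = censored),
#'   `attend` (n x visits logical attendance matrix over all 9 visits),
#'   `event_prob` (named per-interval event probability, the truth used by
#'   oracle tests), `onset_interval`.
#' @export
simulate_outcomes <- function(draft, config, seed = config$seed) {
  labels <- draft$labels
  n <- length(labels)
  ids <- names(labels)
  nvE <- config$n_exposure_visits
  nvA <- config$n_event_visits
  n_visits <- nvE + nvA

  tw <- draft$truth_weights
  causal <- which(tw$shared_effect != 0 | tw$increasing_effect != 0)
  eta <- rep(config$baseline_hazard_logit, n) +
    config$group_log_hr * (labels == "increasing")
  if (length(causal)) {
    G <- draft$genotypes$dosages[, causal, drop = FALSE]
    G[is.na(G)] <- 0
    cen <- sweep(G, 2L, 2 * draft$genotypes$variants$maf_true[causal])
    gl <- drop(cen %*% tw$shared_effect[causal]) +
      drop(cen %*% tw$increasing_effect[causal]) * (labels == "increasing")
    # center the genetic liability within each group: SNPs drive
    # within-group risk variation (and, through the membership selection,
    # group allele-frequency gradients) while group_log_hr remains the
    # marginal group hazard contrast
    gl <- gl - stats::ave(gl, labels)
    eta <- eta + gl
  }
  p <- stats::plogis(eta)

  set.seed(substream_seed(seed, "outcomes"))
  member <- labels != "control"
  # latent onset interval: first success among nvA Bernoulli trials
  trials <- matrix(stats::runif(n * nvA), nrow = n) < p
  trials[!member, ] <- FALSE
  onset <- apply(trials, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })

  attend <- matrix(FALSE, n, n_visits)
  attend[, 1] <- TRUE
  keep <- matrix(stats::runif(n * (n_visits - 1L)) >=
                   config$dropout_prob_per_visit, nrow = n)
  attend[member, 2:n_visits] <- keep[member, ]

  event_visit <- rep(NA_integer_, n)
  has <- which(!is.na(onset))
  for (i in has) {
    onset_visit <- nvE - 1L + onset[i]           # 0-based visit index
    att <- which(attend[i, ]) - 1L
    det <- att[att >= onset_visit]
    if (length(det)) event_visit[i] <- det[1]
  }
  names(event_visit) <- ids
  names(onset) <- ids
  list(true_event_visit = event_visit, attend = attend,
       event_prob = stats::setNames(p, ids), onset_interval = onset)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the generator: (1) HWE genotypes for all participants;
#' (2) trajectory-group membership by ranking a genetic liability built
#' from the increasing-only causal SNPs (weight `group_genetic_weight`)
#' plus standard-normal noise - the top `n_increasing` ranks form the
#' increasing group, the next `n_stable` the stable group, the remainder
#' the control pool, so group allele-frequency gradients arise from
#' selection while marginal genotypes stay exactly HWE; (3) exposure-period
#' non-HDL series per group; (4) discrete-time NAFLD outcomes and
#' liver-fat-score component columns that reproduce the simulated status
#' exactly; (5) demographic and covariate columns at the scale of a
#' middle-aged East Asian cohort. Control-pool participants attend only
#' the baseline visit (a fraction `control_history_prob` carries baseline
#' NAFLD), so cohort-assembly filters reproduce the trajectory analysis
#' set without consulting the truth labels.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: `cohort_table` (long
#'   format, one row per attended participant-visit), `genotypes`,
#'   `true_group_labels`, `true_event_visit`, `truth_weights`,
#'   `true_event_prob`, and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_stable + config$n_increasing + config$n_control_pool
  m <- config$n_snps
  ids <- sprintf("P%05d", seq_len(n))

  geno <- simulate_genotypes(n, m, config$maf_range,
                             seed = substream_seed(config$seed, "genotypes"),
                             missing_prob = config$geno_missing_prob)

  # causal architecture
  n_sh <- config$n_causal_shared
  n_io <- config$n_causal_increasing_only
  tw <- data.frame(snp = geno$variants$id,
                   shared_effect = 0, increasing_effect = 0,
                   stringsAsFactors = FALSE)
  if (n_sh > 0) tw$shared_effect[seq_len(n_sh)] <- config$causal_effect_size
  io_idx <- if (n_io > 0) n_sh + seq_len(n_io) else integer()
  if (n_io > 0) tw$increasing_effect[io_idx] <- config$causal_effect_size

  # group membership: genetic trajectory liability + noise, ranked
  set.seed(substream_seed(config$seed, "labels"))
  if (length(io_idx) && config$group_genetic_weight != 0) {
    G <- geno$dosages[, io_idx, drop = FALSE]
    G[is.na(G)] <- 0
    gs <- drop(scale(rowSums(G)))
    if (any(!is.finite(gs))) gs <- rep(0, n)
  } else gs <- rep(0, n)
  liab <- config$group_genetic_weight * gs + stats::rnorm(n)
  rk <- order(liab, decreasing = TRUE)
  labels <- rep("control", n)
  labels[rk[seq_len(config$n_increasing)]] <- "increasing"
  labels[rk[config$n_increasing + seq_len(config$n_stable)]] <- "stable"
  names(labels) <- ids

  lipids <- simulate_lipid_series(labels, config, seed = config$seed)

  draft <- list(labels = labels, genotypes = geno, truth_weights = tw)
  out <- simulate_outcomes(draft, config, seed = config$seed)

  tab <- build_cohort_table(ids, labels, lipids, out, config)

  res <- list(cohort_table = tab,
              genotypes = geno,
              true_group_labels = labels,
              true_event_visit = out$true_event_visit,
              truth_weights = tw,
              true_event_prob = out$event_prob,
              config = config)
  class(res) <- "synthetic_cohort"
  res
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tb <- table(x$true_group_labels)
  cat("synthetic_cohort:", length(x$true_group_labels), "participants (",
      paste(names(tb), tb, sep = "=", collapse = ", "), "),",
      ncol(x$genotypes$dosages), "SNPs,",
      sum(!is.na(x$true_event_visit)), "incident events\n")
  invisible(x)
}

# Assemble the long visit table: demographics, lifestyle, lipids and
# liver-fat-score components for every attended visit.
build_cohort_table <- function(ids, labels, lipids, out, config) {
  n <- length(ids)
  nvE <- config$n_exposure_visits
  nvA <- config$n_event_visits
  n_visits <- nvE + nvA
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  set.seed(substream_seed(config$seed, "covariates"))
  male <- stats::runif(n) < 0.404
  age0 <- clip(round(stats::rnorm(n, 50.9, 8.5)), 40, 69)
  bmi <- clip(stats::rnorm(n, 23.4, 2.6), 16, 35)
  height <- ifelse(male, stats::rnorm(n, 167, 6), stats::rnorm(n, 155, 6))
  weight <- bmi * (height / 100)^2
  wc <- clip(stats::rnorm(n, 78.5, 7.6), 55, 110)
  sbp <- clip(stats::rnorm(n, 121, 15), 85, 200)
  dbp <- clip(stats::rnorm(n, 75, 10), 45, 130)
  # kept below the diabetes threshold so the DM indicator derived from the
  # table coincides exactly with the emitted liver-fat-score DM component
  fpg <- clip(stats::rnorm(n, 82, 11), 55, 125)
  crp <- exp(stats::rnorm(n, log(0.11), 0.9))
  platelet <- clip(stats::rnorm(n, 262, 60), 80, 500)
  energy <- clip(stats::rnorm(n, 1922, 656), 500, 5000)
  drinker <- stats::runif(n) < 0.45
  alc_amt <- exp(stats::rnorm(n, log(8), 0.7))
  alcohol <- ifelse(drinker, pmin(alc_amt, ifelse(male, 29, 19)), 0)
  smoking <- sample(c("never", "ex", "intermittent", "daily"), n,
                    replace = TRUE, prob = c(0.698, 0.126, 0.015, 0.161))
  met <- exp(stats::rnorm(n, 2.9, 0.7))
  hdl_i <- clip(stats::rnorm(n, 47, 10), 25, 90)
  tg_i <- clip(stats::rnorm(n, 125, 55), 40, 390)
  htn_trt <- stats::runif(n) < 0.12
  lip_trt <- stats::runif(n) < 0.03
  control_case <- labels == "control" &
    stats::runif(n) < config$control_history_prob

  # attended (participant, visit) pairs
  att <- out$attend
  idx <- which(att, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pi <- idx[, 1]
  vi <- idx[, 2] - 1L                     # 0-based visit index
  nr <- length(pi)

  # non-HDL: exposure visits from the simulated series; accrual visits
  # plateau at the end-of-exposure group mean plus intercept and noise
  inter <- attr(lipids, "intercepts")[ids]
  key <- paste(lipids$participant_id, lipids$visit_index)
  nonhdl_map <- stats::setNames(lipids$non_hdl, key)
  set.seed(substream_seed(config$seed, "components"))
  plateau <- ifelse(labels == "increasing",
                    config$increasing_nonhdl_start +
                      config$increasing_slope * (nvE - 1L),
                    config$stable_nonhdl_mean)
  non_hdl <- ifelse(
    vi < nvE,
    nonhdl_map[paste(ids[pi], vi)],
    plateau[pi] + inter[pi] + stats::rnorm(nr, 0, config$nonhdl_noise_sd))
  # control participants attend only baseline, always present in series
  non_hdl[is.na(non_hdl)] <-
    (plateau[pi] + inter[pi])[is.na(non_hdl)]

  # NAFLD status per attended row: case from the detection visit onward;
  # control-pool "history" participants are cases at baseline
  ev <- out$true_event_visit[ids[pi]]
  is_case <- (!is.na(ev) & vi >= ev) | (control_case[pi] & vi == 0L)
  comp <- as.data.frame(matrix(NA_real_, nr, 5))
  names(comp) <- c("mets_flag", "dm_flag", "ast", "alt", "insulin")
  comp[is_case, ] <- sim_lfs_components(sum(is_case), case = TRUE)
  comp[!is_case, ] <- sim_lfs_components(sum(!is_case), case = FALSE)

  hdl <- clip(hdl_i[pi] + stats::rnorm(nr, 0, 3), 20, 95)
  tab <- data.frame(
    participant_id = ids[pi],
    visit_index = vi,
    age = age0[pi] + vi * config$visit_spacing_years,
    sex = ifelse(male[pi], "male", "female"),
    height = round(height[pi], 1),
    weight = round(weight[pi], 1),
    bmi = round(bmi[pi], 2),
    wc = round(wc[pi], 1),
    sbp = round(sbp[pi]),
    dbp = round(dbp[pi]),
    total_chol = non_hdl + hdl,
    hdl_chol = hdl,
    triglyceride = clip(tg_i[pi] + stats::rnorm(nr, 0, 12), 35, 399),
    fpg = fpg[pi],
    insulin = comp$insulin,
    ast = comp$ast,
    alt = comp$alt,
    crp = crp[pi],
    platelet = platelet[pi],
    energy_intake = energy[pi],
    alcohol_g_per_day = alcohol[pi],
    smoking = smoking[pi],
    met_hr_day = met[pi],
    mets_flag = as.integer(comp$mets_flag),
    dm_flag = as.integer(comp$dm_flag),
    dm_treatment = comp$dm_flag == 1L,
    htn_treatment = htn_trt[pi],
    lipid_treatment = lip_trt[pi],
    insulin_therapy = FALSE,
    ogtt_2h_glucose = NA_real_,
    hba1c = NA_real_,
    hepatitis = FALSE,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}
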