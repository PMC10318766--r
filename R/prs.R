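#' Per-SNP difference weights between trajectory strata
#'
#' For every SNP present in both stratified scans, the interaction weight
#' is the difference in log-odds effect size, increasing minus stable,
#' with standard error `sqrt(se_inc^2 + se_stable^2)`. Alleles are
#' harmonized to a common effect allele (the stable-stratum beta flips
#' sign when its effect/other alleles are swapped). SNPs with an absolute
#' between-stratum minor-allele-frequency difference above `maf_diff_cut`
#' are flagged excluded; SNPs unestimated in either stratum are excluded
#' with a reason code.
#'
#' @param inc,stable `assoc_result` data frames for the increasing and
#'   stable strata (same model).
#' @param maf_diff_cut Exclusion threshold on |MAF_inc - MAF_stable|
#'   (default 0.20, i.e. 20 percentage points).
#' @return Data frame of class `interaction_weights`: `snp`,
#'   `effect_allele`, `diff`, `se_diff`, `maf_increasing`, `maf_stable`,
#'   `included`, `reason`, `model`; attribute `N_included`.
#' @export
compute_diff_weights <- function(inc, stable, maf_diff_cut = 0.20) {
  mg <- merge(inc, stable, by = "snp", suffixes = c("_inc", "_sta"))
  if (nrow(mg) == 0L) stop("no overlapping SNPs between strata")

  same <- mg$effect_allele_inc == mg$effect_allele_sta &
    mg$other_allele_inc == mg$other_allele_sta
  swap <- mg$effect_allele_inc == mg$other_allele_sta &
    mg$other_allele_inc == mg$effect_allele_sta
  beta_sta <- ifelse(swap, -mg$beta_sta, mg$beta_sta)

  diff <- mg$beta_inc - beta_sta
  se_diff <- sqrt(mg$se_inc^2 + mg$se_sta^2)
  maf_gap <- abs(mg$maf_inc - mg$maf_sta)

  reason <- rep("", nrow(mg))
  reason[!same & !swap] <- "allele_mismatch"
  reason[is.na(mg$beta_inc) | is.na(beta_sta)] <- "missing_in_stratum"
  reason[reason == "" & maf_gap > maf_diff_cut] <- "maf_diff"
  included <- reason == ""

  out <- data.frame(snp = mg$snp,
                    effect_allele = mg$effect_allele_inc,
                    diff = diff, se_diff = se_diff,
                    maf_increasing = mg$maf_inc,
                    maf_stable = mg$maf_sta,
                    included = included, reason = reason,
                    model = mg$model_inc,
                    stringsAsFactors = FALSE)
  attr(out, "N_included") <- sum(included)
  class(out) <- c("interaction_weights", "data.frame")
  out
}

#' Interaction polygenic risk score
#'
#' Scores each individual as the weighted dosage sum over included SNPs,
#' `sum_i diff_i x dosage_ij`, with dosages oriented to each weight's
#' effect allele. A missing dosage contributes that SNP's mean observed
#' dosage, keeping scores comparable across individuals with different
#' missingness.
#'
#' @param weights `interaction_weights` from [compute_diff_weights()].
#' @param g A `genotype_matrix` covering the individuals to score.
#' @return Data frame `participant_id`, `raw_score`.
#' @export
interaction_prs <- function(weights, g) {
  w <- weights[weights$included, ]
  if (nrow(w) == 0L) stop("no included SNPs to score")
  vi <- match(w$snp, g$variants$id)
  if (anyNA(vi)) stop("weights contain SNPs absent from the genotypes: ",
                      paste(utils::head(w$snp[is.na(vi)]), collapse = ", "))
  D <- g$dosages[, vi, drop = FALSE]
  storage.mode(D) <- "double"
  ok <- w$effect_allele == g$variants$alt[vi] |
    w$effect_allele == g$variants$ref[vi]
  if (!all(ok))
    stop("effect alleles not matching genotype alleles for: ",
         paste(utils::head(w$snp[!ok]), collapse = ", "))
  flip <- w$effect_allele == g$variants$ref[vi]
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  mu <- colMeans(D, na.rm = TRUE)
  na_idx <- which(is.na(D))
  if (length(na_idx)) D[na_idx] <- mu[(na_idx - 1L) %/% nrow(D) + 1L]
  data.frame(participant_id = g$sample_ids,
             raw_score = drop(D %*% w$diff),
             stringsAsFactors = FALSE)
}

#' Standardize PRS values
#'
#' z = (x - mean) / SD over the scored population, sample-SD (n - 1)
#' convention.
#'
#' @param raw_scores Numeric vector (>= 2 distinct values).
#' @return z-scores (mean 0, SD 1).
#' @export
standardize_prs <- function(raw_scores) {
  if (length(raw_scores) < 2L)
    stop("need at least two scores to standardize")
  s <- stats::sd(raw_scores)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot standardize")
  (raw_scores - mean(raw_scores)) / s
}

#' Select the control group from the non-trajectory pool
#'
#' Uniform random sample without replacement from the pool after
#' excluding participants with any history of NAFLD, matching the
#' trajectory-set sample size.
#'
#' @param pool_ids Candidate participant ids.
#' @param n Number of controls to draw.
#' @param nafld_history Named logical by participant id: any observed
#'   NAFLD.
#' @param seed Integer seed.
#' @return Character vector of `n` ids (canonical order when `n` equals
#'   the eligible pool size).
#' @export
select_control_group <- function(pool_ids, n, nafld_history, seed = 1L) {
  hist_ <- nafld_history[pool_ids]
  eligible <- pool_ids[is.na(hist_) | !hist_]
  if (length(eligible) < n)
    stop("control pool too small after NAFLD-history exclusion: ",
         length(eligible), " < ", n)
  if (length(eligible) == n) return(sort(eligible))
  set.seed(seed)
  sort(sample(eligible, n))
}

#' Assemble a PRS result across groups
#'
#' Combines raw scores with group membership and standardizes over the
#' combined control + stable + increasing population.
#'
#' @param scores Data frame from [interaction_prs()].
#' @param groups Named character vector ("control"/"stable"/"increasing")
#'   for every scored participant.
#' @param model_id Adjustment model the weights came from.
#' @return Data frame of class `prs_result`: `participant_id`,
#'   `raw_score`, `z_score`, `group`, `model`.
#' @export
prs_result <- function(scores, groups, model_id = 1L) {
  grp <- groups[scores$participant_id]
  if (anyNA(grp)) stop("every scored participant needs a group label")
  out <- data.frame(participant_id = scores$participant_id,
                    raw_score = scores$raw_score,
                    z_score = standardize_prs(scores$raw_score),
                    group = factor(grp, levels = c("control", "stable",
                                                   "increasing")),
                    model = model_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Compare standardized PRS across groups (forest-plot table)
#'
#' Group means of the standardized interaction PRS with 95% confidence
#' intervals (mean +/- 1.96 SE), plus pairwise Welch two-sample tests
#' and, optionally, permutation p-values for the group-mean differences.
#'
#' @param prs A `prs_result`.
#' @param n_perm Permutation replicates for the permutation p-values
#'   (0 disables).
#' @param seed Seed for the permutation test.
#' @return List: `table` (group, n, mean_z, ci_lower, ci_upper in
#'   control/stable/increasing order) and `pairwise` (group1, group2,
#'   mean_diff, p_welch, p_perm).
#' @export
compare_groups <- function(prs, n_perm = 0L, seed = 1L) {
  z <- prs$z_score
  grp <- droplevels(prs$group)
  sizes <- table(grp)
  if (any(sizes < 2L)) {
    warning("degenerate group(s) excluded: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- grp %in% names(sizes)[sizes >= 2L]
    z <- z[keep]
    grp <- droplevels(grp[keep])
  }
  if (nlevels(grp) < 2L) stop("need >= 2 groups with >= 2 members")

  mu <- tapply(z, grp, mean)
  se <- tapply(z, grp, function(v) stats::sd(v) / sqrt(length(v)))
  tab <- data.frame(group = names(mu), n = as.integer(table(grp)),
                    mean_z = as.numeric(mu),
                    ci_lower = as.numeric(mu - 1.96 * se),
                    ci_upper = as.numeric(mu + 1.96 * se),
                    stringsAsFactors = FALSE)

  combs <- utils::combn(levels(grp), 2L)
  pw <- lapply(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    z1 <- z[grp == g1]; z2 <- z[grp == g2]
    wt <- stats::t.test(z1, z2)
    p_perm <- NA_real_
    if (n_perm > 0L) {
      set.seed(seed + i)
      obs <- mean(z1) - mean(z2)
      pool <- c(z1, z2)
      n1 <- length(z1)
      null_diff <- replicate(n_perm, {
        idx <- sample.int(length(pool), n1)
        mean(pool[idx]) - mean(pool[-idx])
      })
      p_perm <- (1 + sum(abs(null_diff) >= abs(obs))) / (n_perm + 1)
    }
    data.frame(group1 = g1, group2 = g2,
               mean_diff = mean(z1) - mean(z2),
               p_welch = wt$p.value, p_perm = p_perm,
               stringsAsFactors = FALSE)
  })
  list(table = tab, pairwise = do.call(rbind, pw))
}
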