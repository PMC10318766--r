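#' Hardy-Weinberg equilibrium exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions from genotype
#' counts, conditioning on the observed allele counts: the p-value sums
#' the probabilities of all heterozygote counts no more probable than the
#' observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log-probability of each compatible heterozygote count
  hom_r <- (rare - hets) %/% 2L
  hom_c <- n - hets - hom_r
  logp <- lgamma(n + 1) - lgamma(hets + 1) - lgamma(hom_r + 1) -
    lgamma(hom_c + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hets == n_het]
  min(1, sum(prob[prob <= obs * (1 + 1e-10)]))
}

#' Per-variant and per-sample genotype summary statistics
#'
#' @param g A `genotype_matrix`.
#' @return List: `variant` data frame (`id`, `call_rate`, `alt_freq`,
#'   `maf`, `hwe_p`) and `sample` data frame (`id`, `call_rate`).
#' @export
geno_stats <- function(g) {
  dos <- g$dosages
  n <- nrow(dos)
  obs <- !is.na(dos)
  call_rate_v <- colMeans(obs)
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(alt_freq, 1 - alt_freq)
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j)
    hwe_exact_test(n0[j], n1[j], n2[j]), numeric(1))
  list(variant = data.frame(id = g$variants$id, call_rate = call_rate_v,
                            alt_freq = alt_freq, maf = maf, hwe_p = hwe_p,
                            stringsAsFactors = FALSE),
       sample = data.frame(id = g$sample_ids, call_rate = rowMeans(obs),
                           stringsAsFactors = FALSE))
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g A `genotype_matrix`.
#' @param samples Sample ids or logical/integer index (default: all).
#' @param variants Variant ids or logical/integer index (default: all).
#' @return The subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(g$sample_ids)
        else if (is.character(samples)) match(samples, g$sample_ids)
        else samples
  vi <- if (is.null(variants)) seq_len(nrow(g$variants))
        else if (is.character(variants)) match(variants, g$variants$id)
        else variants
  if (anyNA(si)) stop("unknown sample ids")
  if (anyNA(vi)) stop("unknown variant ids")
  out <- list(dosages = g$dosages[si, vi, drop = FALSE],
              sample_ids = g$sample_ids[si],
              variants = g$variants[vi, , drop = FALSE])
  rownames(out$variants) <- NULL
  class(out) <- "genotype_matrix"
  out
}

#' Variant quality control
#'
#' Removes SNPs with minor allele frequency below 0.05 (strict), call
#' rate below 0.95 (strict), or Hardy-Weinberg exact-test p below 1e-6.
#'
#' @param g A `genotype_matrix`.
#' @param maf_min,call_rate_min,hwe_p_min QC thresholds; a variant is
#'   removed when its statistic is strictly below the threshold.
#' @return Filtered `genotype_matrix` with a `qc_report` attribute
#'   counting removals per criterion (a variant failing several criteria
#'   is counted in each).
#' @export
snp_qc <- function(g, maf_min = 0.05, call_rate_min = 0.95,
                   hwe_p_min = 1e-6) {
  st <- geno_stats(g)$variant
  fail_maf <- st$maf < maf_min
  fail_cr <- st$call_rate < call_rate_min
  fail_hwe <- st$hwe_p < hwe_p_min
  drop_ <- fail_maf | fail_cr | fail_hwe
  if (all(drop_)) stop("no variants survive QC")
  out <- subset_genotypes(g, variants = which(!drop_))
  attr(out, "qc_report") <- data.frame(
    criterion = c("maf", "call_rate", "hwe", "total_removed", "retained"),
    count = c(sum(fail_maf), sum(fail_cr), sum(fail_hwe), sum(drop_),
              sum(!drop_)))
  out
}

#' Sample quality control
#'
#' Removes samples with genotype call rate below 0.90 and, when
#' X-chromosome variants are present, samples whose genotype-inferred sex
#' (X heterozygosity below 0.2 implies male) conflicts with reported sex.
#' Without X variants the sex check is skipped with a warning.
#'
#' @param g A `genotype_matrix`.
#' @param reported_sex Optional named vector ("male"/"female") by sample
#'   id.
#' @param call_rate_min Call-rate threshold (exclusion strictly below).
#' @return Filtered `genotype_matrix` with a `qc_report` attribute.
#' @export
sample_qc <- function(g, reported_sex = NULL, call_rate_min = 0.90) {
  st <- geno_stats(g)$sample
  fail_cr <- st$call_rate < call_rate_min
  fail_sex <- rep(FALSE, length(g$sample_ids))
  x_idx <- which(g$variants$chrom %in% c("X", "23", "chrX"))
  if (!is.null(reported_sex)) {
    if (length(x_idx) == 0L) {
      warning("no X-chromosome variants: sex check skipped")
    } else {
      xh <- rowMeans(g$dosages[, x_idx, drop = FALSE] == 1L, na.rm = TRUE)
      inferred <- ifelse(is.nan(xh), NA_character_,
                         ifelse(xh < 0.2, "male", "female"))
      rep_sex <- reported_sex[g$sample_ids]
      fail_sex <- !is.na(inferred) & !is.na(rep_sex) & inferred != rep_sex
    }
  }
  drop_ <- fail_cr | fail_sex
  out <- subset_genotypes(g, samples = which(!drop_))
  attr(out, "qc_report") <- data.frame(
    criterion = c("call_rate", "sex_mismatch", "total_removed", "retained"),
    count = c(sum(fail_cr), sum(fail_sex), sum(drop_), sum(!drop_)))
  out
}

#' Genotype principal components
#'
#' Principal components of the column-standardized dosage matrix (missing
#' dosages mean-imputed for this step only), computed by truncated SVD:
#' exact for small problems, randomized subspace iteration otherwise.
#' Components are ordered by explained variance and each component's sign
#' is fixed by making its largest-magnitude variant loading positive.
#'
#' @param g A post-QC `genotype_matrix`.
#' @param n_components Number of leading components (default 10).
#' @param seed Seed for the randomized range finder.
#' @return List: `scores` (n x k matrix, columns PC1..PCk), `sdev`,
#'   `explained` (proportion of total variance), `loadings` (variants x
#'   k).
#' @export
compute_pcs <- function(g, n_components = 10L, seed = 1L) {
  dos <- g$dosages
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos))
  if (length(idx)) dos[idx] <- mu[(idx - 1L) %/% nrow(dos) + 1L]
  sdv <- apply(dos, 2L, stats::sd)
  keep <- sdv > 0
  X <- scale(dos[, keep, drop = FALSE])
  n <- nrow(X); m <- ncol(X)
  k <- as.integer(n_components)
  if (k > min(n, m))
    stop("n_components exceeds the rank of the dosage matrix")

  if (min(n, m) <= 500L) {
    sv <- svd(X, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    U <- sv$u
    V <- sv$v
  } else {
    set.seed(seed)
    l <- min(k + 10L, min(n, m))
    Q <- qr.Q(qr(X %*% matrix(stats::rnorm(m * l), m, l)))
    for (i in 1:3) Q <- qr.Q(qr(X %*% crossprod(X, Q)))
    B <- crossprod(Q, X)
    sb <- svd(B)
    d <- sb$d[seq_len(k)]
    U <- (Q %*% sb$u)[, seq_len(k), drop = FALSE]
    V <- sb$v[, seq_len(k), drop = FALSE]
  }
  # deterministic orientation: largest |loading| positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(d, k)
  dimnames(scores) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  list(scores = scores,
       sdev = d / sqrt(n - 1),
       explained = d^2 / ((n - 1) * m),
       loadings = V)
}

# Covariate sets of the stratified association scans. Model 4 adds only
# serum ALT (the Cox Model 4 additionally adjusts triglyceride).
scan_model_terms <- function(model_id, n_pcs = 10L) {
  pcs <- if (n_pcs > 0) paste0("PC", seq_len(n_pcs)) else character(0)
  base <- list(
    `1` = c("age", "sex", pcs),
    `2` = c("age", "sex", pcs, "bmi", "energy_intake", "smoking",
            "current_drinker", "pa_category"),
    `3` = c("age", "sex", pcs, "bmi", "energy_intake", "smoking",
            "current_drinker", "pa_category", "htn", "dm", "crp"),
    `4` = c("age", "sex", pcs, "bmi", "energy_intake", "smoking",
            "current_drinker", "pa_category", "htn", "dm", "crp", "alt"))
  key <- as.character(model_id)
  if (!key %in% names(base)) stop("model_id must be 1..4")
  base[[key]]
}

#' Per-SNP covariate-adjusted logistic association scan
#'
#' Logistic regression of incident NAFLD on each SNP's dosage plus the
#' covariate set of the requested model (Model 1: age, sex, 10 genotype
#' PCs; Model 2 adds BMI, energy intake, smoking, drinking, physical
#' activity; Model 3 adds HTN, DM, CRP; Model 4 adds ALT), fit separately
#' within a trajectory stratum. Wald statistics are reported per SNP. A
#' SNP whose fit fails (non-convergence, separation, monomorphic dosage)
#' is flagged missing and the scan continues.
#'
#' @param phenotype Logical/0-1 incident-NAFLD vector aligned to
#'   `g$sample_ids`.
#' @param g Post-QC `genotype_matrix` for the stratum samples.
#' @param covariates Data frame aligned to `g$sample_ids` containing the
#'   scan covariates (including PC columns from [compute_pcs()]).
#' @param model_id 1..4.
#' @param stratum Label recorded in the output (e.g. "increasing").
#' @param n_pcs Number of PC covariates (default 10).
#' @return Data frame of class `assoc_result`: `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`, `beta`, `se`, `p`, `n`,
#'   `stratum`, `model`, `note`.
#' @export
association_scan <- function(phenotype, g, covariates, model_id = 1L,
                             stratum = "all", n_pcs = 10L) {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary")
  n <- length(y)
  if (n != nrow(g$dosages) || n != nrow(covariates))
    stop("phenotype, genotypes and covariates must align")
  terms <- scan_model_terms(model_id, n_pcs)
  missing_cols <- setdiff(terms, names(covariates))
  if (length(missing_cols))
    stop("covariates lack: ", paste(missing_cols, collapse = ", "))
  cov_df <- droplevels(covariates[terms])
  Xbase <- stats::model.matrix(~ ., data = cov_df)
  if (nrow(Xbase) != n)
    stop("missing values in covariates are not allowed in the scan")
  # guard against constant columns (e.g. a covariate level absent from
  # this stratum) that would make every per-SNP fit singular
  keep_col <- c(TRUE, apply(Xbase[, -1, drop = FALSE], 2L,
                            function(cc) stats::var(cc) > 0))
  Xbase <- Xbase[, keep_col, drop = FALSE]

  m <- ncol(g$dosages)
  st <- geno_stats(g)$variant
  beta <- se <- p <- rep(NA_real_, m)
  nn <- integer(m)
  note <- character(m)
  for (j in seq_len(m)) {
    dos <- g$dosages[, j]
    ok <- !is.na(dos)
    nn[j] <- sum(ok)
    dj <- as.numeric(dos[ok])
    if (stats::var(dj) == 0) {
      note[j] <- "monomorphic"
      next
    }
    X <- cbind(Xbase[ok, , drop = FALSE], dosage = dj)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y[ok],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      note[j] <- "nonconvergence"
      next
    }
    w <- fit$weights
    vc <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
    if (is.null(vc)) {
      note[j] <- "singular"
      next
    }
    b <- fit$coefficients[["dosage"]]
    s <- sqrt(vc[ncol(X), ncol(X)])
    if (!is.finite(b) || !is.finite(s) || abs(b) > 15 || s > 10) {
      note[j] <- "separation"
      next
    }
    beta[j] <- b
    se[j] <- s
    p[j] <- 2 * stats::pnorm(-abs(b / s))
  }
  out <- data.frame(snp = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos,
                    effect_allele = g$variants$alt,
                    other_allele = g$variants$ref,
                    maf = st$maf, alt_freq = st$alt_freq,
                    beta = beta, se = se, p = p, n = nn,
                    stratum = stratum, model = model_id, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Genomic inflation factor and QQ coordinates
#'
#' lambda is the median association chi-square divided by the null
#' median (qchisq(0.5, 1) ~ 0.456); values near 1 indicate calibrated
#' tests.
#'
#' @param results An `assoc_result` data frame (>= 100 non-missing
#'   p-values).
#' @return List: `lambda` and `qq` (data frame `expected`, `observed`,
#'   both -log10 p).
#' @export
genomic_inflation <- function(results) {
  p <- results$p[!is.na(results$p)]
  if (length(p) < 100L) stop("need >= 100 SNP tests for lambda")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  p_sorted <- sort(p)
  k <- length(p_sorted)
  qq <- data.frame(expected = -log10((seq_len(k) - 0.5) / k),
                   observed = -log10(p_sorted))
  list(lambda = lambda, qq = qq)
}
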