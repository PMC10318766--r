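# Shared fixtures and independent oracles used across the suite.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small but structurally complete cohort for module tests
small_config <- function(seed = 7L, ...) {
  cohort_config(n_stable = 160L, n_increasing = 130L,
                n_control_pool = 600L, n_snps = 120L,
                n_causal_shared = 4L, n_causal_increasing_only = 8L,
                seed = seed, ...)
}

small_cohort <- function() {
  cache_fixture("small_cohort", function() simulate_cohort(small_config()))
}

default_cohort <- function() {
  cache_fixture("default_cohort",
                function() simulate_cohort(cohort_config(seed = 41L)))
}

# build a genotype_matrix by hand from a dosage matrix
make_geno <- function(dos, chrom = NULL, maf_true = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  g <- list(
    dosages = dos,
    sample_ids = sprintf("S%03d", seq_len(n)),
    variants = data.frame(
      id = sprintf("v%03d", seq_len(m)),
      chrom = if (is.null(chrom)) rep("1", m) else chrom,
      pos = seq_len(m) * 100L,
      ref = rep("A", m), alt = rep("G", m),
      maf_true = if (is.null(maf_true)) rep(NA_real_, m) else maf_true,
      stringsAsFactors = FALSE))
  rownames(g$dosages) <- g$sample_ids
  colnames(g$dosages) <- g$variants$id
  class(g) <- "genotype_matrix"
  g
}

# independent two-group log-rank oracle (observed minus expected, group 1)
logrank_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  U <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    at <- time >= t
    n_t <- sum(at)
    n1 <- sum(at & group == g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g1)
    U <- U + d1 - d * n1 / n_t
    if (n_t > 1)
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  U^2 / V
}

# independent Cox partial log-likelihood for one covariate, no ties
cox_pll_oracle <- function(beta, time, event, x) {
  sum(vapply(which(event), function(i) {
    beta * x[i] - log(sum(exp(beta * x[time >= time[i]])))
  }, numeric(1)))
}

# independent HWE exact p-value via direct choose() enumeration
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2L * n0 + n1        # allele A count
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  prob <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- n - h - a
    choose(n, a) * choose(n - a, h) * 2^h / choose(2 * n, nA)
  }, numeric(1))
  prob <- prob / sum(prob)
  obs <- prob[hets == n1]
  sum(prob[prob <= obs * (1 + 1e-10)])
}
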