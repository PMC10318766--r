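test_that("HWE exact test matches the enumeration oracle", {
  set.seed(4)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    n1 <- sample(0:n, 1)
    n0 <- sample(0:(n - n1), 1)
    n2 <- n - n1 - n0
    expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                 tolerance = 1e-9)
  }
  # a heterozygote-deficient SNP is decisively rejected
  expect_lt(hwe_exact_test(298, 104, 98), 1e-6)
  expect_equal(hwe_exact_test(298, 104, 98), hwe_oracle(298, 104, 98),
               tolerance = 1e-9)
  # perfect HWE proportions are not rejected
  expect_gt(hwe_exact_test(81, 18, 1), 0.05)
})

test_that("variant QC applies the printed thresholds strictly", {
  set.seed(2)
  n <- 200
  dos <- cbind(
    rbinom(n, 2, 0.30),                    # clean
    rbinom(n, 2, 0.05),                    # MAF near the boundary
    rep(0L, n),                            # monomorphic
    rbinom(n, 2, 0.40),                    # low call rate (below)
    rbinom(n, 2, 0.40))                    # call rate exactly at threshold
  # force exact MAF 0.05: 20 alt alleles in 400
  dos[, 2] <- 0L; dos[1:20, 2] <- 1L
  dos[1:11, 4] <- NA                       # call rate 189/200 = 0.945
  dos[1:10, 5] <- NA                       # call rate 190/200 = 0.95
  # heterozygote-free common SNP fails HWE
  dos <- cbind(dos, c(rep(0L, 120), rep(2L, 80)))
  g <- make_geno(dos)
  out <- snp_qc(g)
  kept <- out$variants$id
  expect_true("v001" %in% kept)
  expect_true("v002" %in% kept)            # MAF exactly 0.05 retained
  expect_false("v003" %in% kept)           # monomorphic removed
  expect_false("v004" %in% kept)           # call rate 0.945 removed
  expect_true("v005" %in% kept)            # call rate exactly 0.95 retained
  expect_false("v006" %in% kept)           # HWE failure removed
  rep_ <- attr(out, "qc_report")
  expect_equal(rep_$count[rep_$criterion == "retained"], 3)
  all_bad <- make_geno(matrix(0L, 50, 2))
  expect_error(snp_qc(all_bad), "survive")
})

test_that("sample QC enforces call rate and the X-based sex check", {
  set.seed(3)
  dos <- matrix(rbinom(30 * 100, 2, 0.3), 30, 100)
  dos[1, 1:11] <- NA                       # call rate 0.89 -> removed
  dos[2, 1:10] <- NA                       # call rate 0.90 -> retained
  g <- make_geno(dos)
  sex30 <- setNames(rep("female", 30), g$sample_ids)
  expect_warning(sample_qc(g, reported_sex = sex30), "sex check skipped")
  out <- suppressWarnings(sample_qc(g, reported_sex = sex30))
  expect_false("S001" %in% out$sample_ids)
  expect_true("S002" %in% out$sample_ids)

  # with X variants, an X-homozygous "female" is flagged
  chrom <- c(rep("1", 60), rep("X", 40))
  dos2 <- matrix(rbinom(20 * 100, 2, 0.3), 20, 100)
  dos2[1, 61:100] <- ifelse(dos2[1, 61:100] > 0, 2L, 0L)  # zero X het
  g2 <- make_geno(dos2, chrom = chrom)
  sex <- setNames(rep("female", 20), g2$sample_ids)
  out2 <- sample_qc(g2, reported_sex = sex)
  expect_false("S001" %in% out2$sample_ids)
  expect_true("S002" %in% out2$sample_ids)
})

test_that("principal components separate structured subpopulations", {
  set.seed(9)
  n <- 120; m <- 150
  p1 <- runif(m, 0.1, 0.4)
  p2 <- pmin(p1 + 0.4, 0.9)
  dos <- rbind(
    matrix(rbinom(60 * m, 2, rep(p1, each = 60)), 60, m),
    matrix(rbinom(60 * m, 2, rep(p2, each = 60)), 60, m))
  g <- make_geno(dos)
  pcs <- compute_pcs(g, n_components = 5)
  pc1 <- pcs$scores[, 1]
  expect_true(max(pc1[1:60]) < min(pc1[61:120]) ||
                min(pc1[1:60]) > max(pc1[61:120]))
  # scores are orthogonal
  cp <- crossprod(pcs$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
})

test_that("homogeneous genotypes produce no dominant axis", {
  g <- simulate_genotypes(200, 400, c(0.1, 0.5), seed = 31)
  pcs <- compute_pcs(g, n_components = 5)
  expect_lt(pcs$sdev[1] / pcs$sdev[2], 1.25)
  expect_error(compute_pcs(make_geno(matrix(rbinom(40, 2, .4), 4, 10)),
                           n_components = 8), "rank")
})

test_that("a planted large-effect SNP tops the scan", {
  set.seed(12)
  n <- 1000
  g <- simulate_genotypes(n, 301, c(0.1, 0.5), seed = 77)
  g$variants$maf_true[301] <- 0.3
  g$dosages[, 301] <- rbinom(n, 2, 0.3)
  covars <- data.frame(age = rnorm(n, 50, 8),
                       sex = factor(sample(c("male", "female"), n, TRUE)))
  eta <- -1 + 0.5 * g$dosages[, 301] + 0.01 * (covars$age - 50)
  y <- runif(n) < plogis(eta)
  res <- association_scan(y, g, covars, model_id = 1, stratum = "all",
                          n_pcs = 0)
  expect_equal(which.min(res$p), 301L)
  expect_equal(res$beta[301], 0.5, tolerance = 0.35)
})

test_that("scan betas are invariant to affine covariate rescaling", {
  set.seed(13)
  n <- 400
  g <- simulate_genotypes(n, 8, c(0.2, 0.5), seed = 5)
  covars <- data.frame(age = rnorm(n, 50, 8),
                       sex = factor(sample(c("male", "female"), n, TRUE)))
  y <- runif(n) < 0.3
  r1 <- association_scan(y, g, covars, 1, n_pcs = 0)
  covars2 <- covars
  covars2$age <- covars2$age * 1000 - 777
  r2 <- association_scan(y, g, covars2, 1, n_pcs = 0)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-6)
  expect_equal(r1$se, r2$se, tolerance = 1e-6)
})

test_that("flipping the counted allele negates beta exactly", {
  set.seed(14)
  n <- 500
  g <- simulate_genotypes(n, 5, c(0.2, 0.5), seed = 6)
  covars <- data.frame(age = rnorm(n, 50, 8),
                       sex = factor(sample(c("male", "female"), n, TRUE)))
  y <- runif(n) < plogis(-1 + 0.3 * g$dosages[, 2])
  r1 <- association_scan(y, g, covars, 1, n_pcs = 0)
  gf <- g
  gf$dosages <- 2L - gf$dosages
  r2 <- association_scan(y, gf, covars, 1, n_pcs = 0)
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("failed per-SNP fits are flagged missing, not fatal", {
  set.seed(15)
  n <- 80
  g <- simulate_genotypes(n, 3, c(0.3, 0.5), seed = 7)
  g$dosages[, 2] <- 1L                       # constant dosage
  covars <- data.frame(age = rnorm(n, 50, 8),
                       sex = factor(sample(c("male", "female"), n, TRUE)))
  y <- runif(n) < 0.4
  res <- association_scan(y, g, covars, 1, n_pcs = 0)
  expect_true(is.na(res$beta[2]))
  expect_equal(res$note[2], "monomorphic")
  expect_false(anyNA(res$beta[c(1, 3)]))
})

test_that("genomic inflation is 1 at the null reference", {
  res <- data.frame(p = rep(0.5, 200))
  gi <- genomic_inflation(res)
  expect_equal(gi$lambda, 1, tolerance = 1e-12)
  expect_equal(nrow(gi$qq), 200)
  expect_error(genomic_inflation(data.frame(p = runif(50))), ">= 100")
})

test_that("QC order is fixed and recomputes variant statistics", {
  co <- small_cohort()
  g <- co$genotypes
  q1 <- snp_qc(g)
  q2 <- sample_qc(q1)
  q3 <- snp_qc(q2)
  st <- geno_stats(q3)$variant
  expect_true(all(st$maf >= 0.05))
  expect_true(all(st$call_rate >= 0.95))
  expect_true(all(st$hwe_p >= 1e-6))
})
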