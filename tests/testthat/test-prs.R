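fake_scan <- function(beta, se, maf, stratum, snp = NULL,
                      ea = "G", oa = "A", model = 1L) {
  m <- length(beta)
  structure(data.frame(
    snp = if (is.null(snp)) sprintf("v%03d", seq_len(m)) else snp,
    chrom = "1", pos = seq_len(m),
    effect_allele = rep_len(ea, m), other_allele = rep_len(oa, m),
    maf = maf, alt_freq = maf, beta = beta, se = se,
    p = 2 * pnorm(-abs(beta / se)), n = 500L, stratum = stratum,
    model = model, note = "", stringsAsFactors = FALSE),
    class = c("assoc_result", "data.frame"))
}

test_that("difference weights follow the stated arithmetic exactly", {
  inc <- fake_scan(c(0.5, 0.1), c(0.3, 0.2), c(0.30, 0.10), "increasing")
  sta <- fake_scan(c(0.2, -0.1), c(0.4, 0.1), c(0.28, 0.35), "stable")
  w <- compute_diff_weights(inc, sta)
  expect_equal(w$diff[1], 0.3)
  expect_equal(w$se_diff[1], 0.5)          # sqrt(0.09 + 0.16)
  expect_true(w$included[1])
  # |0.10 - 0.35| = 0.25 > 0.20 -> excluded by the MAF-difference rule
  expect_false(w$included[2])
  expect_equal(w$reason[2], "maf_diff")
  expect_equal(attr(w, "N_included"), 1L)
})

test_that("the se of the difference is exact over random inputs and the
           MAF filter excludes exactly the >20-point gaps", {
  set.seed(6)
  m <- 300
  b1 <- rnorm(m); b2 <- rnorm(m)
  s1 <- runif(m, 0.05, 0.5); s2 <- runif(m, 0.05, 0.5)
  f1 <- runif(m, 0.05, 0.5); f2 <- runif(m, 0.05, 0.5)
  w <- compute_diff_weights(fake_scan(b1, s1, f1, "increasing"),
                            fake_scan(b2, s2, f2, "stable"))
  idx <- match(w$snp, sprintf("v%03d", 1:m))
  expect_equal(w$diff, (b1 - b2)[idx], tolerance = 1e-12)
  expect_equal(w$se_diff, sqrt(s1[idx]^2 + s2[idx]^2), tolerance = 1e-12)
  expect_identical(w$included, abs(f1[idx] - f2[idx]) <= 0.20)
})

test_that("allele harmonization flips the stable beta when swapped", {
  inc <- fake_scan(0.5, 0.1, 0.3, "increasing", ea = "G", oa = "A")
  sta <- fake_scan(0.2, 0.1, 0.3, "stable", ea = "A", oa = "G")
  w <- compute_diff_weights(inc, sta)
  expect_equal(w$diff, 0.5 - (-0.2))
  mis <- fake_scan(0.2, 0.1, 0.3, "stable", ea = "T", oa = "C")
  w2 <- compute_diff_weights(inc, mis)
  expect_false(w2$included)
  expect_equal(w2$reason, "allele_mismatch")
  # a SNP unestimated in one stratum is excluded with a reason
  sta_na <- fake_scan(NA_real_, NA_real_, 0.3, "stable")
  w3 <- compute_diff_weights(inc, sta_na)
  expect_equal(w3$reason, "missing_in_stratum")
})

test_that("the interaction PRS is the weighted dosage sum", {
  dos <- matrix(c(2L, 1L,
                  1L, 0L), 2, 2, byrow = TRUE)
  g <- make_geno(dos)
  w <- compute_diff_weights(
    fake_scan(c(0.3, -0.1), c(0.1, 0.1), c(0.3, 0.3), "increasing"),
    fake_scan(c(0.0, 0.0), c(0.1, 0.1), c(0.3, 0.3), "stable"))
  sc <- interaction_prs(w, g)
  expect_equal(sc$raw_score, c(0.3 * 2 - 0.1 * 1, 0.3 * 1))
  # zero weights give zero scores; doubling weights doubles scores
  w0 <- w; w0$diff <- c(0, 0)
  expect_true(all(interaction_prs(w0, g)$raw_score == 0))
  w2 <- w; w2$diff <- w$diff * 2
  expect_equal(interaction_prs(w2, g)$raw_score, sc$raw_score * 2)
  # no included SNPs is an error
  wx <- w; wx$included <- FALSE
  expect_error(interaction_prs(wx, g), "no included")
})

test_that("missing dosages score at the SNP mean", {
  dos <- matrix(c(2L, NA, 0L, 1L), 4, 1)
  g <- make_geno(dos)
  w <- compute_diff_weights(fake_scan(1, 0.1, 0.3, "increasing"),
                            fake_scan(0, 0.1, 0.3, "stable"))
  sc <- interaction_prs(w, g)
  expect_equal(sc$raw_score[2], 1)         # mean of 2, 0, 1
})

test_that("allele flips shift raw scores by a constant, z unchanged", {
  set.seed(8)
  g <- make_geno(matrix(rbinom(600, 2, 0.35), 60, 10))
  w <- compute_diff_weights(
    fake_scan(rnorm(10), runif(10, .05, .2), runif(10, .1, .5),
              "increasing"),
    fake_scan(rnorm(10), runif(10, .05, .2), runif(10, .1, .5),
              "stable"))
  z1 <- standardize_prs(interaction_prs(w, g)$raw_score)
  gf <- g
  gf$dosages[, 3] <- 2L - gf$dosages[, 3]
  tmp <- gf$variants$ref[3]
  gf$variants$ref[3] <- gf$variants$alt[3]
  gf$variants$alt[3] <- tmp
  z2 <- standardize_prs(interaction_prs(w, gf)$raw_score)
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("standardization follows the sample-SD convention", {
  expect_equal(standardize_prs(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize_prs(rep(2, 5)), "zero variance")
  z <- standardize_prs(rnorm(50, 4, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize_prs(z), z, tolerance = 1e-12)
})

test_that("control selection excludes NAFLD history and is reproducible", {
  pool <- sprintf("P%04d", 1:500)
  hist_ <- setNames(rep(c(TRUE, FALSE), c(100, 400)), pool)
  a <- select_control_group(pool, 200, hist_, seed = 5)
  b <- select_control_group(pool, 200, hist_, seed = 5)
  expect_identical(a, b)
  expect_length(a, 200)
  expect_true(all(!hist_[a]))
  expect_identical(select_control_group(pool, 400, hist_, seed = 1),
                   sort(pool[101:500]))
  expect_error(select_control_group(pool, 401, hist_), "too small")
})

test_that("group comparison returns calibrated nulls under permutation", {
  set.seed(10)
  z <- rnorm(300)
  ids <- sprintf("P%03d", 1:300)
  pvals <- replicate(120, {
    grp <- setNames(sample(rep(c("control", "stable", "increasing"), 100)),
                    ids)
    pr <- prs_result(data.frame(participant_id = ids, raw_score = z),
                     grp)
    cmp <- compare_groups(pr)
    cmp$pairwise$p_welch
  })
  expect_lt(abs(mean(pvals) - 0.5), 0.08)
  expect_lt(abs(mean(pvals < 0.25) - 0.25), 0.08)
})

test_that("a group equal to the whole population has mean z near zero", {
  set.seed(11)
  ids <- sprintf("P%03d", 1:400)
  raw <- rnorm(400)
  grp <- setNames(sample(c("control", "stable"), 400, TRUE,
                         prob = c(.99, .01)), ids)
  pr <- prs_result(data.frame(participant_id = ids, raw_score = raw), grp)
  cmp <- compare_groups(pr)
  big <- cmp$table[cmp$table$group == "control", ]
  expect_lt(abs(big$mean_z), 0.05)
  # permutation p-values are reported when requested
  cmp2 <- compare_groups(pr, n_perm = 99, seed = 3)
  expect_true(all(is.finite(cmp2$pairwise$p_perm)))
})
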