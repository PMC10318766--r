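test_that("configuration invariants are enforced before any sampling", {
  expect_error(simulate_genotypes(4, 1, maf_range = c(0, 0)),
               "configuration error")
  expect_error(cohort_config(maf_range = c(0, 0.5)), "configuration error")
  expect_error(cohort_config(maf_range = c(0.1, 0.6)), "configuration error")
  expect_error(cohort_config(dropout_prob_per_visit = 1), "configuration error")
  expect_error(cohort_config(n_stable = 0), "configuration error")
  expect_error(cohort_config(n_snps = 4, n_causal_shared = 3,
                             n_causal_increasing_only = 3),
               "configuration error")
})

test_that("simulated genotypes match their allele frequency and HWE", {
  g <- simulate_genotypes(2000, 1, maf_range = c(0.3, 0.3), seed = 9)
  af <- mean(g$dosages) / 2
  expect_lt(abs(af - 0.3), 0.03)          # ~4 binomial SDs
  expect_true(all(g$dosages %in% 0:2))

  g2 <- simulate_genotypes(5000, 200, maf_range = c(0.05, 0.5), seed = 10)
  st <- geno_stats(g2)$variant
  expect_lt(mean(st$hwe_p < 0.01), 0.02)  # null calibration
  expect_true(all(abs(st$alt_freq - g2$variants$maf_true) < 0.05))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  a <- simulate_cohort(small_config(seed = 33))
  b <- simulate_cohort(small_config(seed = 33))
  expect_identical(a$cohort_table, b$cohort_table)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$true_event_visit, b$true_event_visit)
  c_ <- simulate_cohort(small_config(seed = 34))
  expect_false(identical(a$cohort_table, c_$cohort_table))
})

test_that("lipid series follow the configured class shapes", {
  cfg0 <- cohort_config(nonhdl_noise_sd = 0, increasing_slope = 0,
                        lipid_intercept_sd = 0,
                        dropout_prob_per_visit = 0)
  labs <- setNames(rep("stable", 20), sprintf("P%05d", 1:20))
  s <- simulate_lipid_series(labs, cfg0, seed = 1)
  expect_equal(nrow(s), 80)
  expect_true(all(s$non_hdl == cfg0$stable_nonhdl_mean))

  # class-mean separation at the last exposure visit
  cfg <- cohort_config()
  labs2 <- setNames(rep(c("stable", "increasing"), each = 400),
                    sprintf("P%05d", 1:800))
  s2 <- simulate_lipid_series(labs2, cfg, seed = 2)
  m3 <- tapply(s2$non_hdl[s2$visit_index == 3], s2$label[s2$visit_index == 3],
               mean)
  expect_gte(m3[["increasing"]] - m3[["stable"]], 20)

  expect_error(simulate_lipid_series(c(a = "weird"), cfg), "unknown")
})

test_that("dropout thins follow-up visits at the configured rate", {
  cfg <- cohort_config(dropout_prob_per_visit = 0.2)
  labs <- setNames(rep("stable", 2500), sprintf("P%05d", 1:2500))
  s <- simulate_lipid_series(labs, cfg, seed = 5)
  obs_per <- nrow(s) / 2500
  expect_lt(abs(obs_per - (1 + 3 * 0.8)), 0.06)
  expect_equal(sum(s$visit_index == 0), 2500)  # baseline never missing
})

test_that("null outcome settings give equal incidence across groups", {
  cfg <- cohort_config(seed = 13, group_log_hr = 0,
                       causal_effect_size = 0, n_stable = 700L,
                       n_increasing = 700L, n_control_pool = 10L,
                       n_snps = 60L)
  co <- simulate_cohort(cfg)
  ev <- !is.na(co$true_event_visit)
  lab <- co$true_group_labels
  p1 <- mean(ev[lab == "stable"]); p2 <- mean(ev[lab == "increasing"])
  se <- sqrt(p1 * (1 - p1) / 700 + p2 * (1 - p2) / 700)
  expect_lt(abs(p1 - p2), 3.5 * se)
})

test_that("an impossible hazard yields zero events", {
  cfg <- small_config(seed = 14, baseline_hazard_logit = -50)
  co <- simulate_cohort(cfg)
  expect_true(all(is.na(co$true_event_visit)))
})

test_that("cohort structure invariants hold", {
  co <- small_cohort()
  tab <- co$cohort_table
  nvE <- co$config$n_exposure_visits
  nv <- nvE + co$config$n_event_visits
  # every participant has a baseline record
  expect_setequal(tab$participant_id[tab$visit_index == 0],
                  names(co$true_group_labels))
  # events only in the accrual window
  ev <- co$true_event_visit[!is.na(co$true_event_visit)]
  expect_true(all(ev >= nvE & ev < nv))
  # dosages within [0, 2] (allowing missing)
  d <- co$genotypes$dosages
  expect_true(all(is.na(d) | (d >= 0 & d <= 2)))
  # events never assigned to control-pool participants
  expect_true(all(is.na(co$true_event_visit[co$true_group_labels ==
                                              "control"])))
})

test_that("phenotype derivation inverts the generator exactly (round trip)", {
  co <- default_cohort()
  d <- derive_covariates(co$cohort_table)
  nvE <- co$config$n_exposure_visits
  acc <- d[d$visit_index >= nvE, ]
  fe <- tapply(ifelse(acc$nafld, acc$visit_index, NA_integer_),
               acc$participant_id, function(v) {
                 v <- v[!is.na(v)]
                 if (length(v)) min(v) else NA_integer_
               })
  members <- names(co$true_group_labels)[co$true_group_labels != "control"]
  truth <- co$true_event_visit[members]
  got <- fe[members]
  match_ <- (is.na(got) & is.na(truth)) |
    (!is.na(got) & !is.na(truth) & got == truth)
  expect_true(all(match_))
  # exposure-period visits of members are NAFLD-free by construction
  expo <- d[d$visit_index < nvE & d$participant_id %in% members, ]
  expect_true(all(!expo$nafld))
})

test_that("trajectory-group selection leaves marginal HWE intact but
           creates the allele-frequency gradient at causal SNPs", {
  co <- default_cohort()
  st <- geno_stats(co$genotypes)$variant
  expect_lt(mean(st$hwe_p < 0.01, na.rm = TRUE), 0.03)
  tw <- co$truth_weights
  io <- which(tw$increasing_effect != 0 & tw$shared_effect == 0)
  lab <- co$true_group_labels
  af <- function(sel) colMeans(co$genotypes$dosages[sel, io, drop = FALSE],
                               na.rm = TRUE) / 2
  af_i <- mean(af(lab == "increasing"))
  af_s <- mean(af(lab == "stable"))
  af_c <- mean(af(lab == "control"))
  expect_gt(af_i, af_s)
  expect_gt(af_s, af_c)
  expect_lt(af_i - af_s, 0.20)   # stays clear of the PRS MAF-difference cut
})
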