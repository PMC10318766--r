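toy_records <- function() {
  data.frame(participant_id = c("a", "b", "c", "d"),
             group = factor(c("stable", "increasing", "stable",
                              "increasing"),
                            levels = c("stable", "increasing")),
             entry_time = 0, exit_time = c(1, 2, 3, 4),
             time = c(1, 2, 3, 4),
             event = c(TRUE, TRUE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

test_that("person-years sum exit minus entry per group", {
  r <- data.frame(group = factor(rep("stable", 3),
                                 levels = c("stable", "increasing")),
                  entry_time = c(0, 0, 0), exit_time = c(2, 2, 2))
  expect_warning(py <- person_years(r), "zero person-years")
  expect_equal(unname(py["stable"]), 6)
  expect_equal(unname(py["increasing"]), 0)
  expect_equal(unname(py["total"]), 6)
  bad <- data.frame(group = "a", entry_time = 2, exit_time = 2)
  expect_error(person_years(bad), "exceed")
})

test_that("incidence arithmetic is exact", {
  expect_equal(incidence_rate_per_1000py(0, 1000), 0)
  expect_equal(incidence_rate_per_1000py(50, 2000), 25)
  expect_error(incidence_rate_per_1000py(1, 0), "positive")
  expect_equal(interval_incidence(0, 500), 0)
  expect_equal(interval_incidence(5, 200), 2.5)
  expect_error(interval_incidence(1, 0), "positive")
})

test_that("log-rank matches the observed-minus-expected hand oracle", {
  r <- toy_records()
  res <- km_logrank(r)
  oracle <- logrank_oracle(r$time, r$event, as.character(r$group))
  expect_equal(res$chisq, oracle, tolerance = 1e-6)
  expect_equal(res$df, 1L)
  expect_equal(res$p, pchisq(oracle, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # larger random data still agrees with the oracle (distinct times)
  set.seed(8)
  n <- 60
  r2 <- data.frame(group = factor(sample(c("stable", "increasing"), n,
                                         TRUE),
                                  levels = c("stable", "increasing")),
                   time = sample(seq(0.5, 60, by = 0.5), n),
                   event = runif(n) < 0.6)
  res2 <- km_logrank(r2)
  expect_equal(res2$chisq,
               logrank_oracle(r2$time, r2$event, as.character(r2$group)),
               tolerance = 1e-6)
})

test_that("Kaplan-Meier curves are proper survival functions", {
  r <- toy_records()
  km <- km_logrank(r)$km
  for (g in unique(km$group)) {
    s <- km$surv[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  none <- toy_records()
  none$event <- FALSE
  expect_error(km_logrank(none), "no events")
  one <- toy_records()
  one$group <- factor("stable", levels = "stable")
  res1 <- km_logrank(one)
  expect_true(is.na(res1$p))
  expect_s3_class(res1$km, "data.frame")
})

test_that("permuted group labels give a null log-rank distribution", {
  set.seed(21)
  n <- 80
  time <- sample(seq(1, 200), n)
  event <- runif(n) < 0.5
  stats <- replicate(150, {
    r <- data.frame(group = factor(sample(rep(c("stable", "increasing"),
                                              n / 2)),
                                   levels = c("stable", "increasing")),
                    time = time, event = event)
    km_logrank(r)$chisq
  })
  expect_lt(abs(mean(stats) - 1), 0.35)   # chi-square(1) has mean 1
  p <- pchisq(stats, 1, lower.tail = FALSE)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.12)
})

test_that("Cox partial likelihood agrees with a brute-force oracle", {
  set.seed(5)
  r <- data.frame(group = factor(c("stable", "increasing", "increasing",
                                   "stable", "increasing"),
                                 levels = c("stable", "increasing")),
                  time = c(1.5, 2.1, 3.7, 4.2, 5.9),
                  event = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  x <- as.numeric(r$group) - 1
  cf <- cox_fit(r, model_id = 0)
  opt <- optimize(function(b) -cox_pll_oracle(b, r$time, r$event, x),
                  c(-5, 5), tol = 1e-10)
  expect_equal(unname(log(cf$hr[1])), opt$minimum, tolerance = 1e-6)
  expect_equal(cox_pll_oracle(log(cf$hr[1]), r$time, r$event, x),
               cf$fit$loglik[2], tolerance = 1e-6)
})

test_that("Cox estimates are centering-invariant and flip under label swap", {
  co <- small_cohort()
  d <- derive_covariates(co$cohort_table)
  memb <- co$true_group_labels[co$true_group_labels != "control"]
  rec <- suppressWarnings(build_survival_records(d, memb))
  f1 <- cox_fit(rec, 1)
  rec2 <- rec
  rec2$age <- rec2$age - 50
  f2 <- cox_fit(rec2, 1)
  expect_equal(f1$hr, f2$hr, tolerance = 1e-8)

  rec3 <- rec
  rec3$group <- factor(ifelse(rec3$group == "stable", "increasing",
                              "stable"),
                       levels = c("stable", "increasing"))
  f3 <- cox_fit(rec3, 0)
  expect_equal(unname(f3$hr[1]), unname(1 / cox_fit(rec, 0)$hr[1]),
               tolerance = 1e-8)
})

test_that("survival records respect the interval-detection convention", {
  co <- small_cohort()
  d <- derive_covariates(co$cohort_table)
  memb <- co$true_group_labels[co$true_group_labels != "control"]
  rec <- suppressWarnings(build_survival_records(d, memb))
  expect_true(all(rec$exit_time > rec$entry_time))
  expect_true(all(rec$entry_time == 6))
  # event exits sit on visit dates and match the simulated truth
  ev <- rec[rec$event, ]
  expect_true(all(ev$exit_time %% 2 == 0))
  truth <- co$true_event_visit[ev$participant_id]
  expect_equal(unname(ev$exit_visit), unname(truth))
})

test_that("person-years match the enumeration oracle of the censoring process", {
  co <- default_cohort()
  d <- derive_covariates(co$cohort_table)
  memb <- co$true_group_labels[co$true_group_labels != "control"]
  rec <- suppressWarnings(build_survival_records(d, memb))
  py_obs <- unname(person_years(rec)["total"])

  # exact expectation: enumerate attendance patterns (5 accrual visits,
  # independent dropout) x latent onset interval, per participant
  q <- co$config$dropout_prob_per_visit
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 5)))
  patterns <- patterns[rowSums(patterns) > 0, ]
  p_att <- apply(patterns, 1, function(a)
    prod(ifelse(a, 1 - q, q))) / (1 - q^5)
  exit_rel <- function(att, T_) {
    a <- which(att)
    det <- a[a >= T_]
    2 * if (length(det)) det[1] else max(a)
  }
  g <- sapply(1:6, function(T_) {   # 6 = no onset
    sum(p_att * apply(patterns, 1, function(a)
      if (T_ == 6) 2 * max(which(a)) else exit_rel(a, T_)))
  })
  p <- co$true_event_prob[rec$participant_id]
  wT <- cbind(sapply(1:5, function(t) (1 - p)^(t - 1) * p), (1 - p)^5)
  py_exp <- sum(wT %*% g)
  expect_lt(abs(py_obs - py_exp) / py_exp, 0.05)
})

test_that("missing covariates for a model are reported", {
  r <- toy_records()
  expect_error(cox_fit(r, 1), "lack covariates")
  expect_error(cox_model_terms <- nafldtraj:::cox_model_terms(7),
               "model_id")
})
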