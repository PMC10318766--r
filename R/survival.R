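#' Build per-participant survival records for the event-accrual period
#'
#' Entry is the last exposure-period visit (start of event accrual); exit
#' is the first attended accrual visit at which NAFLD is detected (event)
#' or the last attended accrual visit (censored). The outcome is
#' interval-detected at biennial visits, so event time is the visit date.
#' Baseline covariates (visit 0) are carried into the record for the Cox
#' models.
#'
#' @param derived Long visit table after [derive_covariates()], containing
#'   `nafld` per attended visit.
#' @param groups Named character vector of trajectory groups
#'   ("stable"/"increasing") for the analysis participants.
#' @param n_exposure_visits,visit_spacing_years Visit layout (defaults 4
#'   biennial exposure visits, accrual from visit 3's date).
#' @return Data frame with `participant_id`, `group`, `entry_time`,
#'   `exit_time`, `time` (= exit - entry, years), `event`, and baseline
#'   covariate columns. Participants with no attended accrual visit are
#'   dropped with a warning (they are excluded upstream in the cohort
#'   flow).
#' @export
build_survival_records <- function(derived, groups,
                                   n_exposure_visits = 4L,
                                   visit_spacing_years = 2) {
  stopifnot(is.data.frame(derived), !is.null(names(groups)))
  ids <- names(groups)
  acc <- derived[derived$participant_id %in% ids &
                   derived$visit_index >= n_exposure_visits, ]
  if (any(is.na(acc$nafld)))
    stop("NAFLD status missing at accrual visits; check liver-fat-score inputs")
  entry <- (n_exposure_visits - 1L) * visit_spacing_years

  first_ev <- tapply(ifelse(acc$nafld, acc$visit_index, NA_integer_),
                     acc$participant_id, function(v) {
                       v <- v[!is.na(v)]
                       if (length(v)) min(v) else NA_integer_
                     })
  last_att <- tapply(acc$visit_index, acc$participant_id, max)
  have <- ids[ids %in% names(last_att)]
  if (length(have) < length(ids))
    warning(length(ids) - length(have),
            " participants without accrual follow-up dropped")
  fe <- first_ev[have]
  rec <- data.frame(participant_id = have,
                    exit_visit = as.integer(ifelse(!is.na(fe), fe,
                                                   last_att[have])),
                    event = !is.na(fe),
                    stringsAsFactors = FALSE)
  rec$group <- factor(groups[rec$participant_id],
                      levels = c("stable", "increasing"))
  rec$entry_time <- entry
  rec$exit_time <- rec$exit_visit * visit_spacing_years
  rec$time <- rec$exit_time - rec$entry_time

  base <- derived[derived$visit_index == 0L, ]
  keep <- c("participant_id", "age", "sex", "bmi", "energy_intake",
            "smoking", "current_drinker", "pa_category", "htn", "dm",
            "crp", "alt", "triglyceride")
  keep <- keep[keep %in% names(base)]
  out <- merge(rec, base[keep], by = "participant_id", sort = TRUE)
  out$sex <- factor(out$sex, levels = c("female", "male"))
  out$smoking <- factor(out$smoking,
                        levels = c("never", "ex", "intermittent", "daily"))
  out
}

#' Person-years of follow-up per group
#'
#' @param records Survival records from [build_survival_records()] (needs
#'   `group`, `entry_time`, `exit_time`).
#' @return Named numeric vector of person-years per group (plus `total`).
#'   Empty groups contribute 0 with a warning.
#' @export
person_years <- function(records) {
  if (any(records$exit_time <= records$entry_time))
    stop("exit_time must exceed entry_time")
  py <- tapply(records$exit_time - records$entry_time, records$group, sum)
  py[is.na(py)] <- 0
  if (any(py == 0)) warning("group with zero person-years")
  c(py, total = sum(py))
}

#' Incidence rate per 1000 person-years
#'
#' @param cases Event count.
#' @param py Person-years (> 0).
#' @return `1000 * cases / py`, reported to 2 decimals.
#' @examples
#' incidence_rate_per_1000py(322, 16958.1)
#' @export
incidence_rate_per_1000py <- function(cases, py) {
  if (any(py <= 0)) stop("person-years must be positive")
  round(1000 * cases / py, 2)
}

#' Interval incidence per 2-year visit interval
#'
#' @param cases Events detected at the visit.
#' @param at_risk Participants at risk (attended, event-free before).
#' @return Percent per interval, `100 * cases / at_risk`, to 2 decimals.
#' @examples
#' interval_incidence(230, 2064)
#' @export
interval_incidence <- function(cases, at_risk) {
  if (any(at_risk <= 0)) stop("at-risk count must be positive")
  round(100 * cases / at_risk, 2)
}

#' Per-visit incidence table over the event-accrual period
#'
#' For each accrual visit: participants at risk (attended that visit with
#' no earlier detected event), events detected, and the 2-year interval
#' incidence.
#'
#' @inheritParams build_survival_records
#' @return Data frame `visit_index`, `at_risk`, `cases`, `rate_per_2y`.
#' @export
incidence_by_visit <- function(derived, groups, n_exposure_visits = 4L,
                               visit_spacing_years = 2) {
  ids <- names(groups)
  acc <- derived[derived$participant_id %in% ids &
                   derived$visit_index >= n_exposure_visits, ]
  first_ev <- tapply(ifelse(acc$nafld, acc$visit_index, NA_integer_),
                     acc$participant_id, function(v) {
                       v <- v[!is.na(v)]
                       if (length(v)) min(v) else NA_integer_
                     })
  visits <- sort(unique(acc$visit_index))
  rows <- lapply(visits, function(v) {
    here <- acc[acc$visit_index == v, ]
    fe <- first_ev[here$participant_id]
    at_risk <- sum(is.na(fe) | fe >= v)
    cases <- sum(!is.na(fe) & fe == v)
    data.frame(visit_index = v, at_risk = at_risk, cases = cases,
               rate_per_2y = if (at_risk > 0)
                 interval_incidence(cases, at_risk) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per trajectory group with the 1-df
#' log-rank chi-square comparing the cumulative incidence of NAFLD
#' between groups.
#'
#' @param records Survival records (needs `time`, `event`, `group`).
#' @return List: `km` (data frame `group`, `time`, `n_risk`, `n_event`,
#'   `surv`), `chisq`, `df`, `p`. With a single group, curves only and
#'   `chisq`/`p` are `NA`.
#' @export
km_logrank <- function(records) {
  if (sum(records$event) < 1L)
    stop("no events: survival is 1 everywhere and the log-rank test is undefined")
  sf <- survival::survfit(survival::Surv(time, event) ~ group,
                          data = records)
  strata_names <- if (is.null(sf$strata)) {
    rep(as.character(records$group[1]), length(sf$time))
  } else {
    rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  km <- data.frame(group = strata_names, time = sf$time,
                   n_risk = sf$n.risk, n_event = sf$n.event,
                   surv = sf$surv)
  ngrp <- length(unique(records$group[!is.na(records$group)]))
  if (ngrp < 2L) {
    return(list(km = km, chisq = NA_real_, df = NA_integer_, p = NA_real_))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records)
  df <- length(sd_$n) - 1L
  list(km = km, chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

# Covariate sets of the four adjustment models for the Cox analysis.
# Model 0 is the unadjusted group effect; Model 4 adds ALT and
# triglyceride (the association-scan Model 4 adds only ALT).
cox_model_terms <- function(model_id) {
  m <- list(
    `0` = "group",
    `1` = c("group", "age", "sex"),
    `2` = c("group", "age", "sex", "bmi", "energy_intake", "smoking",
            "current_drinker", "pa_category"),
    `3` = c("group", "age", "sex", "bmi", "energy_intake", "smoking",
            "current_drinker", "pa_category", "htn", "dm", "crp"),
    `4` = c("group", "age", "sex", "bmi", "energy_intake", "smoking",
            "current_drinker", "pa_category", "htn", "dm", "crp",
            "alt", "triglyceride"))
  key <- as.character(model_id)
  if (!key %in% names(m)) stop("model_id must be 0..4")
  m[[key]]
}

#' Cox proportional-hazards fit for a covariate adjustment model
#'
#' Fits the partial likelihood for incident NAFLD on the trajectory-group
#' indicator plus the covariate set of the requested model: Model 1 age
#' and sex; Model 2 adds BMI, total energy intake, smoking, drinking and
#' physical activity; Model 3 adds hypertension, diabetes and CRP;
#' Model 4 adds ALT and triglyceride. Model 0 is unadjusted.
#'
#' @param records Survival records from [build_survival_records()].
#' @param model_id 0..4.
#' @param ties "efron" (default; visit-based times are heavily tied) or
#'   "breslow".
#' @return Object of class `cox_fit`: `model_id`, `hr`, `ci95` (2-column
#'   matrix), `p`, `beta`, `se`, `n_events`, `ties_method` and the
#'   underlying `survival::coxph` fit.
#' @export
cox_fit <- function(records, model_id = 1L,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  terms <- cox_model_terms(model_id)
  missing_cols <- setdiff(terms, names(records))
  if (length(missing_cols))
    stop("records lack covariates: ", paste(missing_cols, collapse = ", "))
  n_events <- sum(records$event)
  if (n_events < length(terms))
    warning("fewer events than covariates; estimates may be unstable")
  f <- stats::reformulate(terms,
                          response = "survival::Surv(time, event)")
  fit <- survival::coxph(f, data = records, ties = ties)
  beta <- stats::coef(fit)
  if (any(is.na(beta))) {
    warning("aliased covariates dropped: ",
            paste(names(beta)[is.na(beta)], collapse = ", "))
    beta <- beta[!is.na(beta)]
  }
  gi <- grep("^group", names(beta))
  if (length(gi) == 0L || any(!is.finite(beta)))
    stop("Cox fit did not converge: ",
         paste(format(stats::coef(fit)), collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))[names(beta)]
  if (any(se > 100))
    warning("very large standard errors suggest separation")
  z <- beta / se
  out <- list(model_id = model_id,
              hr = exp(beta),
              ci95 = cbind(lower = exp(beta - 1.96 * se),
                           upper = exp(beta + 1.96 * se)),
              p = 2 * stats::pnorm(-abs(z)),
              beta = beta, se = se,
              n_events = n_events,
              ties_method = ties,
              fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit (Model ", x$model_id, ", ties = ", x$ties_method, ", ",
      x$n_events, " events)\n", sep = "")
  tab <- data.frame(HR = round(x$hr, 3),
                    lower95 = round(x$ci95[, 1], 3),
                    upper95 = round(x$ci95[, 2], 3),
                    p = signif(x$p, 3))
  print(tab)
  invisible(x)
}
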