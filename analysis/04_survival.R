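#!/usr/bin/env Rscript
# Stage 4: incidence and survival analysis of interval-detected NAFLD.
#
# Person-years and rates per 1000 person-years by trajectory group,
# per-visit interval incidence, Kaplan-Meier curves with the log-rank
# test, and Cox proportional-hazards models 0-4.

library(nafldtraj)

out <- "results/survival"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

derived <- read_cohort("results/phenotypes/derived.tsv")
lab_tab <- read.delim("results/trajectory/trajectory_labels.tsv")
groups <- setNames(lab_tab$group, lab_tab$participant_id)

rec <- build_survival_records(derived, groups)
py <- person_years(rec)
rates <- data.frame(
  group = c("stable", "increasing"),
  n = as.integer(table(rec$group)),
  cases = as.integer(tapply(rec$event, rec$group, sum)),
  person_years = round(as.numeric(py[c("stable", "increasing")]), 1))
rates$rate_per_1000py <- incidence_rate_per_1000py(rates$cases,
                                                   rates$person_years)
data.table::fwrite(rates, file.path(out, "incidence_rates.tsv"),
                   sep = "\t")
message("incidence by trajectory group:")
print(rates)

inc <- incidence_by_visit(derived, groups)
data.table::fwrite(inc, file.path(out, "incidence_by_visit.tsv"),
                   sep = "\t")

km <- km_logrank(rec)
data.table::fwrite(km$km, file.path(out, "km_curves.tsv"), sep = "\t")
jsonlite::write_json(list(chisq = km$chisq, df = km$df, p = km$p),
                     file.path(out, "logrank.json"), auto_unbox = TRUE,
                     digits = NA)
message("log-rank chi-square = ", round(km$chisq, 2), ", p = ",
        signif(km$p, 3))

cox_rows <- lapply(0:4, function(m) {
  cf <- cox_fit(rec, m)
  data.frame(model = m, hr = round(cf$hr[1], 3),
             ci_lower = round(cf$ci95[1, 1], 3),
             ci_upper = round(cf$ci95[1, 2], 3),
             p = signif(cf$p[1], 3), n_events = cf$n_events)
})
cox_tab <- do.call(rbind, cox_rows)
data.table::fwrite(cox_tab, file.path(out, "cox_models.tsv"), sep = "\t")
message("group hazard ratios (increasing vs stable):")
print(cox_tab)
message("outputs in ", out)
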