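#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emits the long-format visit table (with data dictionary), genotypes as
# VCF and as a dosage-text matrix, and the generator truth tables used
# only for validation, under results/cohort/.

library(nafldtraj)

SEED <- 20260930L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = SEED)
message("simulating cohort: ",
        cfg$n_stable + cfg$n_increasing + cfg$n_control_pool,
        " participants, ", cfg$n_snps, " SNPs")
co <- simulate_cohort(cfg)
print(co)

write_cohort(co$cohort_table, file.path(out, "cohort.tsv"))
write_genotypes_vcf(co$genotypes, file.path(out, "genotypes.vcf"))
write_genotypes_dosage(co$genotypes, file.path(out, "genotypes_dosage.tsv"))

# truth tables (validation only, never inputs to the analysis stages)
truth <- data.frame(participant_id = names(co$true_group_labels),
                    true_group = unname(co$true_group_labels),
                    true_event_visit = unname(
                      co$true_event_visit[names(co$true_group_labels)]))
data.table::fwrite(truth, file.path(out, "truth_labels.tsv"), sep = "\t",
                   na = "NA")
data.table::fwrite(co$truth_weights, file.path(out, "truth_weights.tsv"),
                   sep = "\t")
jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA)

ev <- co$true_event_visit[co$true_group_labels != "control"]
message("members: ", sum(co$true_group_labels != "control"),
        "; incident events: ", sum(!is.na(ev)),
        " (", round(100 * mean(!is.na(ev)), 1), "%)")
message("outputs in ", out)
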