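#!/usr/bin/env Rscript
# Stage 6: interaction polygenic risk score.
#
# Per-SNP difference weights between the stratified scans (increasing
# minus stable, with the 20-point MAF-difference exclusion), scoring of
# the control / stable / increasing groups, standardization over the
# combined population, and the forest-plot comparison, per model 1-4.

library(nafldtraj)

SEED <- 20260930L
out <- "results/prs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

derived <- read_cohort("results/phenotypes/derived.tsv")
lab_tab <- read.delim("results/trajectory/trajectory_labels.tsv")
groups <- setNames(lab_tab$group, lab_tab$participant_id)
geno <- read_genotypes_dosage("results/cohort/genotypes_dosage.tsv")
ids <- names(groups)

# control group: genotyped participants outside the trajectory set with
# no observed NAFLD, sampled to match the analysis-set size
pool <- setdiff(geno$sample_ids, ids)
hist_ <- tapply(!is.na(derived$nafld) & derived$nafld,
                derived$participant_id, any)
controls <- select_control_group(pool, length(ids), hist_, seed = SEED)
group_all <- c(setNames(rep("control", length(controls)), controls),
               groups)
g_score <- subset_genotypes(geno, samples = c(controls, ids))

for (m in 1:4) {
  inc <- read.delim(sprintf("results/gwas/sumstats_increasing_model%d.tsv",
                            m))
  sta <- read.delim(sprintf("results/gwas/sumstats_stable_model%d.tsv", m))
  w <- compute_diff_weights(inc, sta)
  data.table::fwrite(w, file.path(out, sprintf("weights_model%d.tsv", m)),
                     sep = "\t", na = "NA")
  sc <- interaction_prs(w, subset_genotypes(g_score,
                                            variants = w$snp[w$included]))
  pr <- prs_result(sc, group_all, model_id = m)
  data.table::fwrite(pr, file.path(out, sprintf("scores_model%d.tsv", m)),
                     sep = "\t")
  cmp <- compare_groups(pr, n_perm = 1000, seed = SEED + m)
  data.table::fwrite(cmp$table,
                     file.path(out, sprintf("forest_model%d.tsv", m)),
                     sep = "\t")
  data.table::fwrite(cmp$pairwise,
                     file.path(out, sprintf("pairwise_model%d.tsv", m)),
                     sep = "\t", na = "NA")
  mz <- setNames(round(cmp$table$mean_z, 3), cmp$table$group)
  message("model ", m, ": included SNPs = ", attr(w, "N_included"),
          "; mean z (control/stable/increasing) = ",
          paste(mz[c("control", "stable", "increasing")], collapse = " / "))
}
message("outputs in ", out)
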