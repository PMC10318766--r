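# nafldtraj

Longitudinal non-HDL cholesterol trajectories, incident non-alcoholic
fatty liver disease (NAFLD), and the genetics that separates the
trajectory groups — as one tested, reproducible R pipeline.

## Who this is for

Epidemiologists and statistical geneticists analysing biennial cohort
data who want the full chain from raw visit records to an interaction
polygenic risk score: phenotype derivation, group-based trajectory
modelling, person-time survival analysis, stratified GWAS, and PRS
construction. The cohort class of data this targets is access-restricted,
so the package ships a synthetic-cohort generator with known truth that
exercises every stage; all tests and the acceptance script run on it.

## The models at the core

**Phenotype.** NAFLD is called from the liver fat score
`LFS = -2.89 + 1.18·MetS + 0.9·DM + 0.15·insulin + 0.04·AST - 0.94·AST/ALT`,
with NAFLD present when `LFS > -0.640` (strict). Non-HDL cholesterol is
`TC - HDL`; Friedewald LDL is `TC - HDL - TG/5` for `TG < 400` mg/dL.

**Trajectories.** A K-class Gaussian mixture of polynomial mean curves
over the 4 exposure-period visits, fit by EM (posterior E-step,
weighted-least-squares M-step, shared residual variance), best of 10
seeded starts, class count by BIC or fixed at the two-group design;
classes are named *stable*/*increasing* by fitted shape, never by index.

**Survival.** Interval-detected events at visit dates: person-years,
rates per 1000 person-years and per 2-year interval, Kaplan–Meier with
log-rank, and Cox models 0–4 (0 unadjusted; 1 + age, sex; 2 + BMI,
energy intake, smoking, drinking, physical activity; 3 + HTN, DM, CRP;
4 + ALT, triglyceride), Efron ties.

**Stratified scans.** QC (MAF < 0.05, call rate < 0.95, HWE exact
p < 1e-6 removed; samples below 0.90 call rate removed), 10 genotype
PCs, then per-SNP logistic regression of incident NAFLD on dosage plus
model covariates, separately in each trajectory stratum.

**Interaction PRS.** Per SNP `diff_i = beta_increasing - beta_stable`
with `se(diff_i) = sqrt(se_inc^2 + se_sta^2)`, excluding SNPs whose
between-stratum minor-allele-frequency difference exceeds 0.20; scores
are `sum_i diff_i · dosage_ij`, z-standardized over the combined
control + stable + increasing population and compared as a forest-plot
table.

## Worked example

```r
library(nafldtraj)

# the printed-table arithmetic
non_hdl(186.4, 47.0)                    # 139.4 mg/dL
nafld_lfs(1, 0, 6.4, 21, 21)            # -0.85  -> below the -0.640 cut
classify_nafld(-0.640)                  # FALSE (strictly greater than)
incidence_rate_per_1000py(322, 16958.1) # 18.99 per 1000 person-years

# the full pipeline on the default synthetic cohort
res <- run_all(cohort_config(seed = 1), models = 1L)
res$cohort
#> synthetic_cohort: 5203 participants ( control=3000, increasing=934,
#>   stable=1269 ), 1000 SNPs, 709 incident events
res$survival$rates
#>        group    n cases person_years rate_per_1000py
#> 1     stable 1265   345        11088           31.11
#> 2 increasing  937   364         7692           47.32
res$prs$model1$comparison$table
#>        group    n   mean_z ci_lower ci_upper
#> 1    control 2202 -0.05392  -0.0923  -0.0156
#> 2     stable 1265  0.00376  -0.0530   0.0606
#> 3 increasing  937  0.12163   0.0496   0.1937
```

At this seed the Cox Model-1 hazard ratio for the increasing vs stable
group is 1.55 (95% CI 1.34–1.80; log-rank p = 4.4e-09) against a
simulated group contrast of 1.5, and the standardized interaction PRS
is highest in the increasing group, then stable, then control — the
qualitative pattern the score is built to detect. (The increasing-group
rate per 1000 person-years exceeds the stable group's, 47.3 vs 31.1,
because rising non-HDL carries both the group hazard and the
group-specific genetic liability.)

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort TSV + VCF + dosage text
Rscript analysis/02_phenotypes_cohort_flow.R # derived covariates + cohort flow
Rscript analysis/03_trajectories.R           # EM fit, BIC profile, labels
Rscript analysis/04_survival.R               # rates, KM/log-rank, Cox 0-4
Rscript analysis/05_gwas.R                   # QC, PCs, stratified scans 1-4
Rscript analysis/06_interaction_prs.R        # weights, scores, forest tables
```

Each stage reads the previous stage's files, so any step can be rerun
in isolation; all randomness flows from the seed constant at the top of
each script.

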