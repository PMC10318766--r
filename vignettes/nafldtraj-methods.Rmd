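---
title: "Methods: non-HDL cholesterol trajectories, incident NAFLD and the interaction PRS"
author: "nafldtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-HDL cholesterol trajectories, incident NAFLD and the interaction PRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Non-HDL cholesterol (total minus HDL cholesterol) aggregates the
cholesterol carried by atherogenic apoB-containing lipoproteins. In
middle-aged cohorts followed with biennial examinations, individuals
whose non-HDL cholesterol *rises* over several years may face different
liver-disease risk than individuals whose level stays flat, and the two
groups may differ genetically. This package implements the full analysis
chain for that question on longitudinal cohort data:

1. derive a non-invasive NAFLD phenotype (the liver fat score) and
   standard cardiometabolic covariates from visit records;
2. classify each participant's exposure-period non-HDL series into
   latent trajectory groups;
3. estimate incidence and hazard ratios for interval-detected NAFLD
   across groups;
4. scan genotypes for association with incident NAFLD separately within
   each trajectory stratum;
5. combine the stratified scans into an *interaction polygenic risk
   score* whose weights are the per-SNP differences in effect size
   between strata.

Access-restricted cohort data cannot ship with the package, so a
synthetic-cohort generator with known truth stands in for the data in
every test; the generator is first-class, tested code.

## Phenotypes

The liver fat score (LFS) is

$$\mathrm{LFS} = -2.89 + 1.18\,\mathrm{MetS} + 0.9\,\mathrm{DM}
  + 0.15\,\mathrm{insulin} + 0.04\,\mathrm{AST}
  - 0.94\,\mathrm{AST/ALT},$$

with insulin in uIU/mL and the aminotransferases in U/L; NAFLD is
present when LFS exceeds $-0.640$ *strictly*. All categorical
thresholds are implemented exactly as printed in the field's
definitions: hypertension at SBP $\ge 140$ or DBP $\ge 90$ mmHg or
treatment; diabetes at FPG $\ge 126$ mg/dL, 2-h OGTT $\ge 200$ mg/dL,
HbA1c $\ge 6.5\%$, or treatment; dyslipidemia at TC $\ge 240$,
LDL $\ge 160$, HDL $< 40$, TG $\ge 200$ mg/dL or treatment; heavy
drinking at $\ge 30$ (men) / $\ge 20$ (women) g alcohol/day; physical
activity low below 7.5, moderate on the closed interval [7.5, 30] and
high above 30 MET-hr/day (the boundary values are assigned to
"moderate" because the neighbouring categories are printed as strict
inequalities). Mean blood pressure is taken as DBP plus a third of the
pulse pressure, the usual convention, since no formula is printed in
the source definitions. Friedewald LDL (TC $-$ HDL $-$ TG/5) is
reported only when TG $< 400$ mg/dL and is `NA` otherwise.

The metabolic syndrome indicator entering the LFS is consumed as a
given column. Its defining criteria are not fixed by the analysis that
motivated this package, so `mets_atp3()` is provided as a clearly
marked assumption (harmonized ATP-III with Asian waist cut-offs) for
cohorts lacking the column, and is never called implicitly.

## Latent-class trajectory model

The exposure period comprises the first four biennial visits (years 0,
2, 4, 6). Group-based trajectory modelling is implemented explicitly as
a $K$-class Gaussian mixture of polynomial mean curves with shared
residual variance:

$$y_{it} \mid \text{class } k \sim
  N\!\left(\textstyle\sum_{p=0}^{d}\beta_{kp}t^{p},\ \sigma^{2}\right),$$

with class weights $\pi_k$ and independence across a participant's
observed visits given the class. The likelihood runs over observed time
points only, so missed visits need no imputation; participants need a
baseline plus at least one follow-up. EM alternates posterior class
probabilities (E-step) with posterior-weighted least squares per class
and closed-form $\sigma^2$, $\pi_k$ updates (M-step). Initialization is
k-means on per-participant (mean, slope) summaries; nine jittered
restarts follow the k-means start (`n_starts = 10`), and the best
log-likelihood wins. Convergence is declared when the relative
log-likelihood change falls below `tol = 1e-8` (cap `max_iter = 200`);
the per-iteration log-likelihood trace is retained so tests can assert
EM monotonicity. $\sigma$ is floored at $10^{-6}$ and a degenerate-fit
warning is emitted when all series are identical with $K \ge 2$.

The number of classes can be chosen by BIC
($-2\log L + p\log n$, $n$ = participants,
$p = K(d{+}1) + (K{-}1) + 1$), ties toward smaller $K$. Two caveats are
documented deliberately. First, when the data contain between-person
random intercepts — which the mixture family does not model — BIC
tends to add classes to absorb the intercept heterogeneity; on the
default synthetic cohort the BIC profile keeps decreasing past
$K = 2$. This mirrors the well-known behaviour of group-based
trajectory models on real data, where the class count is usually fixed
on substantive grounds. The pipeline therefore fits $K = 2$ by default,
matching the two-group design it implements, and exposes `K = "auto"`
separately. Second, "stable" and "increasing" are *shape-defined*
names: the class with the higher fitted mean at the last exposure
visit **and** positive net change is called increasing, assignment is
by maximum posterior, and exact posterior ties go to the lower class
index with a flag — so relabelling class indices can never silently
flip group names.

## Survival analysis

NAFLD is interval-detected: the event time is the date of the first
attended accrual visit with LFS above the threshold, and participants
are otherwise censored at their last attended visit, matching the
person-year arithmetic of visit-based cohort studies; no
interval-censored likelihood is used. Entry is the third follow-up
visit (year 6). Incidence is reported as cases per 1000 person-years
and per 2-year interval (both to two decimals, the table convention),
Kaplan–Meier curves with the 1-df log-rank test compare groups, and Cox
proportional-hazards models are fit with Efron ties (visit-based times
are heavily tied; Breslow is available):

* Model 0 — unadjusted group indicator;
* Model 1 — + age, sex;
* Model 2 — + BMI, total energy intake, smoking status, drinking
  status, physical activity;
* Model 3 — + hypertension, diabetes, CRP;
* Model 4 — + ALT and triglyceride.

Covariates enter at baseline. Aliased covariates (constant in a given
cohort) are dropped with a warning rather than failing the fit.

## Stratified association scans

Genotype QC removes SNPs with MAF $< 0.05$, call rate $< 0.95$, or
Hardy–Weinberg exact-test $p < 10^{-6}$ (all strict), then samples with
call rate $< 0.90$ — the "approximately 90%" exclusion is read as
*below 0.90* — and a genotype-sex check against X heterozygosity when X
variants exist (skipped with a warning otherwise); SNP statistics are
recomputed after sample removal (fixed order SNP → sample → SNP). The
HWE exact test is implemented from the conditional distribution of the
heterozygote count given allele counts and is unit-tested against a
direct enumeration oracle.

Genotype principal components are the leading axes of the
column-standardized dosage matrix (missing dosages mean-imputed for
this step only), via exact SVD for small problems and randomized
subspace iteration otherwise, with each component's sign fixed by its
largest-magnitude loading. Ten PCs enter the scans as ancestry
covariates.

The per-SNP scan is logistic regression of incident NAFLD on dosage
plus the model covariate set (the scan's Model 4 adds ALT only; the Cox
Model 4 also adds triglyceride — the two covariate lists intentionally
differ, following the two analysis descriptions they implement), fit
separately within the increasing and stable strata, with Wald
statistics. The original analysis used a generalized mixed model with a
relatedness random effect; synthetic cohorts contain no relatedness, so
fixed-effect logistic regression with PCs is the appropriate desk-scale
equivalent — a design decision, not a re-implementation of that tool.
Per-SNP failures (monomorphic dosage, separation, non-convergence) are
flagged and skipped, never fatal. Significance is reported against the
fixed thresholds $10^{-5}$ (weak) and $5\times10^{-8}$ (strong) with no
further multiple-testing correction. The genomic inflation factor is
the median scan chi-square over $\chi^2_{1,0.5} \approx 0.455$.

A calibration caveat: with a desk-scale SNP panel ($m \approx 10^3$,
comparable to $n$), principal components computed from the same matrix
being scanned carry non-negligible loadings on every SNP. When the
phenotype has a real polygenic component, conditioning on such PCs
couples the test statistics across SNPs, and the *pipeline's* reported
$\lambda$ then varies across seeds well beyond the nominal median
noise (roughly 0.9–1.2 at defaults). This is an artifact of small $m$,
absent at genome scale; the package's dedicated calibration tests
(signal-free simulations) show the scan itself holds its type-I error
and $\lambda \in [0.95, 1.05]$.

## Interaction polygenic risk score

For SNP $i$ with stratified effects $\beta^{\mathrm{inc}}_i$ (increasing)
and $\beta^{\mathrm{sta}}_i$ (stable), harmonized to a common effect
allele,

$$\mathrm{diff}_i = \beta^{\mathrm{inc}}_i - \beta^{\mathrm{sta}}_i,
\qquad
se(\mathrm{diff}_i) = \sqrt{se(\beta^{\mathrm{inc}}_i)^2 +
                            se(\beta^{\mathrm{sta}}_i)^2},$$

and the score of individual $j$ is
$\mathrm{PRS}_j = \sum_i \mathrm{diff}_i \times \mathrm{dosage}_{ij}$
over included SNPs. SNPs are excluded when the absolute between-stratum
*minor-allele-frequency* difference exceeds 0.20 (the "greater than
20%" rule read as an absolute difference in frequency), when alleles
cannot be harmonized, or when a stratum produced no estimate — each
with a reason code. Missing dosages score at the SNP's mean observed
dosage so scores stay comparable across missingness patterns. No
clumping, pruning or p-value thresholding is applied: all surviving
SNPs enter the score.

Scores are standardized ("normalized") as z-scores over the combined
control + stable + increasing population, sample-SD convention. The
control group is drawn uniformly without replacement from genotyped
participants outside the trajectory set with no observed NAFLD at any
attended visit, matched to the trajectory-set size. Group comparisons
report mean z with 95% confidence intervals of the mean
(mean $\pm 1.96\,SE$; the choice of CI over SD is a documented
convention) and pairwise Welch two-sample tests, with a permutation
alternative — the underlying comparison procedure is under-specified in
the design this package follows, so both are emitted.

One caveat is inherited deliberately: the difference weights are
estimated on the same stratified samples that are then compared, so the
construction contains train/evaluation leakage by design. The tests
document the behaviour of this construction rather than "fixing" it.

## The synthetic cohort generator

The generator emulates the study conditions end to end; its defaults
*are* those conditions and are not tuned per test.

| parameter | default | rationale |
|---|---|---|
| `n_stable`, `n_increasing` | 1269, 934 | trajectory-group sizes at the cohort's scale |
| `n_control_pool` | 3000 | non-trajectory pool; ≥ analysis-set size after the ~15% NAFLD-history exclusion |
| `n_snps` | 1000 | desk-scale panel: small enough for minute-scale scans, large enough for calibration tests |
| `n_causal_shared` / `n_causal_increasing_only` | 10 / 20 | sparse causal architecture; effects `causal_effect_size = 0.2` per allele keep the unobserved-liability attenuation of the group hazard ratio below ~5% |
| `maf_range` | (0.05, 0.5) | post-QC frequency spectrum |
| visits | 4 exposure + 5 accrual, 2-year spacing | biennial design |
| `stable_nonhdl_mean`, `increasing_nonhdl_start`, `increasing_slope` | 129, 154, +8/visit | baseline group means reproduce the published baseline lipid table (the increasing group starts ~25 mg/dL higher); the slope gives the rising limb |
| `nonhdl_noise_sd`, `lipid_intercept_sd` | 10, 6 | visit noise plus moderate within-person tracking; keeps the two classes Bayes-separable at the ≥95% level the trajectory-recovery property assumes |
| `baseline_hazard_logit`, `group_log_hr` | −2.79, ln 1.5 | solved analytically so 5 biennial intervals give ~30% cumulative incidence and a ~1.5 group contrast (expected case split ≈ 327/333) |
| `dropout_prob_per_visit` | 0.07 | at-risk counts fluctuate realistically; baseline never missing |
| `geno_missing_prob` | 0.005 | gives call-rate QC something to act on |
| `group_genetic_weight` | 1 | half the trajectory-membership liability variance is genetic |
| `control_history_prob` | 0.15 | exercises the control-selection exclusion |

Genotypes are independent binomial draws under HWE. Trajectory-group
membership is then assigned by *ranking* a liability equal to the
standardized sum of the increasing-only causal dosages (weight
`group_genetic_weight`) plus standard-normal noise: the top ranks form
the increasing group, the next the stable group, the rest the control
pool. Marginal genotypes remain exactly HWE while selection creates a
monotone allele-frequency gradient (increasing > stable > control,
about 0.04 between strata at defaults — well inside the 0.20 PRS
filter). This is the mechanism by which lipid-trajectory genetics can
make the interaction PRS differ between groups at all; with genotypes
fully independent of membership the expected group means would be
identical.

Outcomes follow a discrete-time per-visit hazard,
$\mathrm{logit}^{-1}(\alpha + \gamma\,I[\text{increasing}] + \ell_j)$,
where $\ell_j$ is the causal-SNP liability *centered within each
group*: the centering makes $\gamma$ the marginal group contrast
(otherwise the membership–genotype correlation would confound it
upward) while SNP effects still drive within-group risk. Onset is the
first Bernoulli success over the five accrual intervals; detection
happens at the first *attended* visit at or after onset, otherwise
censoring at the last attended visit — so event times are visit dates,
exactly as the survival module assumes.

Liver-fat-score components are generated backwards from the intended
status: AST, ALT and the MetS/DM flags are drawn from case or non-case
distributions and fasting insulin is solved from a target score
(uniform over case or non-case score ranges), with a floor at
0.5 uIU/mL. The component ranges are chosen so that flooring can never
cross the threshold in either direction, making phenotype derivation
*exactly* invertible — a simulation convenience that the round-trip
test exploits (derived status equals simulated truth for 100% of
participants). Control-pool participants attend only baseline (a
`control_history_prob` fraction with baseline NAFLD), so the
cohort-flow filters reproduce the trajectory analysis set without
consulting truth labels.

What the generator does **not** emulate: linkage disequilibrium
(independent loci only), relatedness, time-varying covariates,
marginal distributions beyond the published scales, genotyping-array
error modes, or a plausible joint distribution of all clinical
covariates (most are independent draws at cohort-scale means). Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated data-generating process, not robustness to real-data
pathologies such as LD, cryptic relatedness or informative missingness.

## Seeds, determinism and problem sizes

One master seed expands into fixed per-stage substreams (genotypes,
labels, lipids, outcomes, components, covariates, control selection),
so any stage can be regenerated independently and two runs of
`run_all()` on one configuration are byte-identical — asserted
file-by-file in the tests. The test suite and acceptance checks use
problem sizes chosen to keep the default run in minutes while leaving
the assertions well-powered: trajectory recovery on 1000 planted
series; Cox coverage over 100 replicate cohorts at full epidemiologic
scale but a 60-SNP panel (the group hazard ratio does not depend on the
panel size; the 30 causal SNPs are kept); scan calibration on a
10,000-SNP null panel at $n = 600$; and ten full-pipeline replicates
for the PRS group-ordering rate.

## Known limitations

* The two-class mixture ignores within-person correlation; with strong
  random intercepts its class posteriors blur and BIC overstates the
  class count (see above).
* The interaction-PRS group separation at default conditions is a few
  standard errors of the group-mean difference; individual seeds can
  produce a reversed increasing/stable ordering (the acceptance
  property is a ≥90% replicate rate, not a per-seed guarantee).
* The scan replaces a mixed model with fixed-effect logistic
  regression; cohorts with relatedness would need the original tool.
* Wald p-values are used throughout the scan; rare-variant or
  low-event-count settings would need score or penalized methods.
* The pipeline's reported $\lambda$ at desk-scale $m$ inherits the
  PC-conditioning artifact described above.
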