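#' Non-HDL cholesterol
#'
#' Non-HDL cholesterol is total serum cholesterol minus HDL cholesterol,
#' the aggregate cholesterol carried by atherogenic apoB-containing
#' lipoproteins.
#'
#' @param total_chol Total cholesterol, mg/dL (non-negative).
#' @param hdl_chol HDL cholesterol, mg/dL (non-negative).
#' @return Non-HDL cholesterol in mg/dL. If HDL exceeds total cholesterol a
#'   warning is emitted and the (negative) difference is returned so the
#'   record can be flagged downstream rather than silently dropped.
#' @examples
#' non_hdl(186.4, 47.0)
#' @export
non_hdl <- function(total_chol, hdl_chol) {
  stopifnot(is.numeric(total_chol), is.numeric(hdl_chol))
  if (any(total_chol < 0, na.rm = TRUE) || any(hdl_chol < 0, na.rm = TRUE))
    stop("cholesterol values must be non-negative")
  if (any(hdl_chol > total_chol, na.rm = TRUE))
    warning("HDL exceeds total cholesterol for some records; negative non-HDL returned for QC")
  total_chol - hdl_chol
}

#' Friedewald LDL cholesterol
#'
#' LDL = TC - HDL - TG/5, valid only when triglyceride < 400 mg/dL;
#' above that the estimate is undefined and `NA` is returned.
#'
#' @param total_chol,hdl_chol,triglyceride mg/dL, non-negative.
#' @return Estimated LDL cholesterol (mg/dL), `NA` where TG >= 400.
#' @examples
#' friedewald_ldl(186.4, 47.0, 125.1)
#' @export
friedewald_ldl <- function(total_chol, hdl_chol, triglyceride) {
  if (any(c(total_chol, hdl_chol, triglyceride) < 0, na.rm = TRUE))
    stop("lipid values must be non-negative")
  ldl <- total_chol - hdl_chol - triglyceride / 5
  ldl[!is.na(triglyceride) & triglyceride >= 400] <- NA_real_
  ldl
}

#' NAFLD liver fat score
#'
#' Clinical prediction score for hepatic steatosis built from the presence
#' of metabolic syndrome and diabetes, fasting insulin, AST and the
#' AST/ALT ratio:
#' \deqn{-2.89 + 1.18\,\mathrm{MetS} + 0.9\,\mathrm{DM} + 0.15\,\mathrm{insulin}
#'       + 0.04\,\mathrm{AST} - 0.94\,\mathrm{AST/ALT}}
#'
#' @param mets_flag Metabolic syndrome present, 0/1 (or logical).
#' @param dm_flag Diabetes mellitus present, 0/1 (or logical).
#' @param insulin Fasting serum insulin, uIU/mL.
#' @param ast Aspartate aminotransferase, U/L.
#' @param alt Alanine aminotransferase, U/L; must be > 0 (the AST/ALT
#'   ratio is undefined at ALT = 0).
#' @return The liver fat score (dimensionless).
#' @seealso [classify_nafld()] for the diagnostic cut-off.
#' @export
nafld_lfs <- function(mets_flag, dm_flag, insulin, ast, alt) {
  mets_flag <- as.numeric(mets_flag)
  dm_flag <- as.numeric(dm_flag)
  if (any(alt <= 0, na.rm = TRUE))
    stop("ALT must be positive: AST/ALT ratio undefined")
  if (any(insulin < 0, na.rm = TRUE) || any(ast < 0, na.rm = TRUE))
    stop("insulin and AST must be non-negative")
  -2.89 + 1.18 * mets_flag + 0.9 * dm_flag + 0.15 * insulin +
    0.04 * ast - 0.94 * (ast / alt)
}

#' Threshold of the liver fat score above which NAFLD is called.
#' @export
LFS_THRESHOLD <- -0.640

#' Classify NAFLD from a liver fat score
#'
#' NAFLD is present when the liver fat score is strictly greater than
#' -0.640; a score exactly at the cut-off is negative.
#'
#' @param score Liver fat score(s) from [nafld_lfs()].
#' @return Logical vector.
#' @export
classify_nafld <- function(score) {
  if (any(!is.finite(score) & !is.na(score)))
    stop("liver fat score must be finite")
  score > LFS_THRESHOLD
}

#' Metabolic syndrome from components (harmonized ATP-III, Asian waist)
#'
#' Optional helper: the cohort analyses consume `mets_flag` as a given
#' column; this function derives one from components when a source cohort
#' lacks it. The criteria (3+ of: waist >= 90/80 cm M/F, TG >= 150 mg/dL,
#' HDL < 40/50 mg/dL M/F, BP >= 130/85 mmHg or treatment, FPG >= 100 mg/dL
#' or diabetes treatment) are an assumption of this package, not a
#' definition taken from any single source cohort.
#'
#' @param sex "male"/"female".
#' @param wc Waist circumference, cm.
#' @param triglyceride,hdl_chol mg/dL.
#' @param sbp,dbp mmHg.
#' @param fpg Fasting plasma glucose, mg/dL.
#' @param htn_treatment,dm_treatment Logical treatment indicators.
#' @return Logical vector: metabolic syndrome present.
#' @export
mets_atp3 <- function(sex, wc, triglyceride, hdl_chol, sbp, dbp, fpg,
                      htn_treatment = FALSE, dm_treatment = FALSE) {
  male <- sex == "male"
  comp <- cbind(
    wc >= ifelse(male, 90, 80),
    triglyceride >= 150,
    hdl_chol < ifelse(male, 40, 50),
    sbp >= 130 | dbp >= 85 | htn_treatment,
    fpg >= 100 | dm_treatment
  )
  rowSums(comp, na.rm = TRUE) >= 3
}

#' Derive analysis covariates from visit records
#'
#' Appends derived columns to a long-format visit table: non-HDL and
#' Friedewald LDL cholesterol, mean blood pressure, hypertension, diabetes
#' and dyslipidemia indicators, drinking and physical-activity categories,
#' the heavy-drinker exclusion flag, and the NAFLD liver fat score with
#' its classification. Raw columns are never overwritten.
#'
#' Definitions: hypertension is SBP >= 140 or DBP >= 90 mmHg or
#' antihypertensive treatment; diabetes is FPG >= 126 mg/dL, 2-h OGTT
#' glucose >= 200 mg/dL, HbA1c >= 6.5%, antidiabetic treatment or insulin
#' therapy; dyslipidemia is TC >= 240, LDL >= 160, HDL < 40 or TG >= 200
#' mg/dL or lipid-lowering treatment; heavy drinking is >= 30 (men) or
#' >= 20 (women) g alcohol/day; physical activity is low (< 7.5), moderate
#' ([7.5, 30]) or high (> 30 MET-hr/day); mean blood pressure is
#' DBP + (SBP - DBP)/3.
#'
#' @param records Data frame of visit records (one row per
#'   participant-visit) with the raw measurement columns; see the data
#'   dictionary written by [write_cohort()].
#' @return The input with derived columns appended: `non_hdl`, `ldl`,
#'   `mbp`, `htn`, `dm`, `dyslipidemia`, `heavy_drinker_excluded`,
#'   `current_drinker`, `pa_category`, `nafld_lfs`, `nafld`, and
#'   `covar_missing` naming any required raw field found missing in that
#'   row (empty string when complete). Derived values computed from a
#'   missing input are `NA`, never silently defaulted.
#' @export
derive_covariates <- function(records) {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records)
  need <- c("total_chol", "hdl_chol", "triglyceride", "sbp", "dbp", "fpg",
            "insulin", "ast", "alt", "alcohol_g_per_day", "met_hr_day",
            "sex", "mets_flag")
  miss_mat <- sapply(need, function(cl)
    if (cl %in% names(df)) is.na(df[[cl]]) else rep(TRUE, nrow(df)))
  if (nrow(df) == 1L) miss_mat <- matrix(miss_mat, nrow = 1,
                                         dimnames = list(NULL, need))
  df$covar_missing <- apply(miss_mat, 1L, function(r)
    paste(need[r], collapse = ","))

  gv <- function(cl) if (cl %in% names(df)) df[[cl]] else rep(NA, nrow(df))
  lgl <- function(cl) {
    v <- gv(cl)
    if (all(is.na(v))) rep(FALSE, nrow(df)) else !is.na(v) & as.logical(v)
  }

  df$non_hdl <- suppressWarnings(gv("total_chol") - gv("hdl_chol"))
  df$ldl <- friedewald_ldl(pmax(gv("total_chol"), 0),
                           pmax(gv("hdl_chol"), 0),
                           pmax(gv("triglyceride"), 0))
  df$mbp <- gv("dbp") + (gv("sbp") - gv("dbp")) / 3

  df$htn <- gv("sbp") >= 140 | gv("dbp") >= 90 | lgl("htn_treatment")
  df$dm <- gv("fpg") >= 126 |
    (!is.na(gv("ogtt_2h_glucose")) & gv("ogtt_2h_glucose") >= 200) |
    (!is.na(gv("hba1c")) & gv("hba1c") >= 6.5) |
    lgl("dm_treatment") | lgl("insulin_therapy")
  df$dyslipidemia <- gv("total_chol") >= 240 |
    (!is.na(df$ldl) & df$ldl >= 160) |
    gv("hdl_chol") < 40 | gv("triglyceride") >= 200 | lgl("lipid_treatment")

  alc <- gv("alcohol_g_per_day")
  male <- gv("sex") == "male"
  df$heavy_drinker_excluded <- ifelse(male, alc >= 30, alc >= 20)
  df$current_drinker <- !df$heavy_drinker_excluded & alc > 0

  met <- gv("met_hr_day")
  df$pa_category <- factor(
    ifelse(is.na(met), NA_character_,
           ifelse(met < 7.5, "low", ifelse(met <= 30, "moderate", "high"))),
    levels = c("low", "moderate", "high"))

  alt_ok <- !is.na(gv("alt")) & gv("alt") > 0
  df$nafld_lfs <- rep(NA_real_, nrow(df))
  ok <- alt_ok & !is.na(gv("mets_flag")) & !is.na(gv("insulin")) &
    !is.na(gv("ast"))
  # DM flag inside the score: derived DM indicator, falling back to NA-safe
  dm_for_lfs <- df$dm
  if (ok_any <- any(ok)) {
    df$nafld_lfs[ok] <- nafld_lfs(gv("mets_flag")[ok],
                                  ifelse(is.na(dm_for_lfs[ok]), 0,
                                         dm_for_lfs[ok]),
                                  gv("insulin")[ok], gv("ast")[ok],
                                  gv("alt")[ok])
  }
  df$nafld <- ifelse(is.na(df$nafld_lfs), NA, df$nafld_lfs > LFS_THRESHOLD)
  df
}
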