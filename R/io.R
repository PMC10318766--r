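# File interchange: long-format cohort TSV with a data dictionary, VCF
# (GT) and PLINK-like transposed text dosage matrices for genotypes.

#' Write the cohort visit table as TSV with a data dictionary
#'
#' @param table Long-format visit table.
#' @param path Output TSV path; a `<path>.dictionary.tsv` documenting the
#'   columns is written alongside.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", na = "NA", quote = FALSE)
  dict <- cohort_dictionary()
  dict <- dict[dict$column %in% names(table), ]
  extra <- setdiff(names(table), dict$column)
  if (length(extra))
    dict <- rbind(dict, data.frame(column = extra,
                                   description = "derived or auxiliary column"))
  data.table::fwrite(dict, paste0(path, ".dictionary.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort visit table written by [write_cohort()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

cohort_dictionary <- function() {
  data.frame(
    column = c("participant_id", "visit_index", "age", "sex", "height",
               "weight", "bmi", "wc", "sbp", "dbp", "total_chol",
               "hdl_chol", "triglyceride", "fpg", "insulin", "ast", "alt",
               "crp", "platelet", "energy_intake", "alcohol_g_per_day",
               "smoking", "met_hr_day", "mets_flag", "dm_flag",
               "dm_treatment", "htn_treatment", "lipid_treatment",
               "insulin_therapy", "ogtt_2h_glucose", "hba1c", "hepatitis"),
    description = c(
      "participant identifier", "visit number, 0 = baseline",
      "age at visit, years", "male/female", "height, cm", "weight, kg",
      "body mass index, kg/m^2", "waist circumference, cm",
      "systolic blood pressure, mmHg", "diastolic blood pressure, mmHg",
      "total cholesterol, mg/dL", "HDL cholesterol, mg/dL",
      "triglyceride, mg/dL", "fasting plasma glucose, mg/dL",
      "fasting serum insulin, uIU/mL", "AST, U/L", "ALT, U/L",
      "C-reactive protein, mg/dL", "platelet count, 10^9/L",
      "total energy intake, kcal/day", "alcohol intake, g/day",
      "never/ex/intermittent/daily smoker",
      "physical activity, MET-hr/day",
      "metabolic syndrome present, 0/1",
      "diabetes component of the liver fat score, 0/1",
      "antidiabetic treatment", "antihypertensive treatment",
      "lipid-lowering treatment", "insulin therapy",
      "2-h OGTT glucose, mg/dL (optional)", "HbA1c, % (optional)",
      "history of hepatitis"),
    stringsAsFactors = FALSE)
}

#' Write genotypes as a VCF (GT field)
#'
#' Integer dosages become diploid GT calls (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, missing -> ./.).
#'
#' @param g A `genotype_matrix`.
#' @param path Output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=nafldtraj synthetic cohort",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", g$sample_ids),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  m <- ncol(g$dosages)
  gt <- matrix("./.", nrow(g$dosages), m)
  obs <- !is.na(g$dosages)
  gt[obs] <- gt_code[g$dosages[obs] + 1L]
  v <- g$variants
  lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                 "GT", apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from a VCF with GT calls
#'
#' Parses the VCF via the vcfR package and converts diploid GT calls to
#' alt-allele dosages.
#'
#' @param path VCF path.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt))
  norm <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(matrix(map[norm], nrow(gt), ncol(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  g <- list(dosages = dos,
            sample_ids = colnames(gt),
            variants = data.frame(id = fix$ID, chrom = fix$CHROM,
                                  pos = as.integer(fix$POS),
                                  ref = fix$REF, alt = fix$ALT,
                                  stringsAsFactors = FALSE))
  rownames(g$dosages) <- g$sample_ids
  colnames(g$dosages) <- g$variants$id
  class(g) <- "genotype_matrix"
  g
}

#' Write genotypes as a PLINK-like transposed text dosage matrix
#'
#' One row per variant: id, chrom, pos, ref (other allele), alt (counted
#' allele), then one dosage column per sample (NA = missing).
#'
#' @param g A `genotype_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes_dosage <- function(g, path) {
  out <- cbind(g$variants[c("id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(g$dosages)))
  names(out) <- c("id", "chrom", "pos", "ref", "alt", g$sample_ids)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a PLINK-like transposed text dosage matrix
#' @param path TSV path from [write_genotypes_dosage()].
#' @return A `genotype_matrix`.
#' @export
read_genotypes_dosage <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  meta <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% names(d)))
    stop("dosage file lacks variant metadata columns")
  samp <- setdiff(names(d), meta)
  dos <- t(as.matrix(d[samp]))
  storage.mode(dos) <- "integer"
  g <- list(dosages = dos, sample_ids = samp,
            variants = data.frame(id = as.character(d$id),
                                  chrom = as.character(d$chrom),
                                  pos = as.integer(d$pos),
                                  ref = d$ref, alt = d$alt,
                                  stringsAsFactors = FALSE))
  rownames(g$dosages) <- samp
  colnames(g$dosages) <- g$variants$id
  class(g) <- "genotype_matrix"
  g
}

# deterministic TSV writer for pipeline outputs
write_tsv_out <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
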