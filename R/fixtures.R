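#' Path to a bundled data file
#' @param file file name under the package's `extdata`.
#' @return absolute path.
#' @export
panelval_extdata <- function(file) {
  p <- system.file("extdata", file, package = "panelval", mustWork = TRUE)
  p
}

#' Reference-standard validation tallies
#'
#' The bundled per-tier detection tallies for the commercial reference
#' standards used in the assay's analytical validation: true/false positives
#' per variant type, the design truth-set size per tier, the number of
#' interrogated wild-type positions, mean depth and design VAF. False
#' negatives are derived as `truth_n - tp` and true negatives as
#' `negative_n - fp`.
#'
#' @return `data.frame`, one row per standard x variant-type x depth tier,
#'   with derived `fn` and `tn` columns.
#' @export
reference_standard_results <- function() {
  df <- utils::read.table(panelval_extdata("reference_standard_results.tsv"),
                          sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$fn <- df$truth_n - df$tp
  df$tn <- df$negative_n - df$fp
  df
}

#' Paired tissue/plasma findings from the liquid-biopsy applicability study
#'
#' Ten patients with tissue variant calls (orthogonal-assay VAFs or copy
#' numbers) and the matched plasma findings of the panel; non-shedding cases
#' have no plasma detection. Loci are assigned synthetic coordinates (one
#' unique position per distinct gene/HGVS label) so that identity matching
#' by [pair_concordance()] works on the tabulated labels.
#'
#' @return list of per-patient lists, each with `tissue` and `plasma`
#'   variant-call `data.frame`s.
#' @export
paired_tissue_plasma_findings <- function() {
  df <- utils::read.table(panelval_extdata("paired_tissue_plasma_findings.tsv"),
                          sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "")
  key <- paste(df$gene, df$hgvs)
  pos <- match(key, unique(key)) * 1000L   # synthetic unique loci
  mk <- function(rows, vaf, copies, compartment) {
    variant_calls(kind = df$kind[rows],
                  chrom = ifelse(df$kind[rows] %in% c("SNV", "INDEL"),
                                 "chr1", NA),
                  pos = ifelse(df$kind[rows] %in% c("SNV", "INDEL"),
                               pos[rows], NA),
                  ref = ifelse(df$kind[rows] %in% c("SNV", "INDEL"), "A", NA),
                  alt = ifelse(df$kind[rows] %in% c("SNV", "INDEL"), "T", NA),
                  gene = df$gene[rows],
                  gene5 = ifelse(df$kind[rows] == "FUSION", df$gene[rows], NA),
                  gene3 = ifelse(df$kind[rows] == "FUSION", df$gene3[rows], NA),
                  vaf = vaf[rows], copies = copies[rows],
                  compartment = compartment,
                  hgvs = df$hgvs[rows])
  }
  lapply(split(seq_len(nrow(df)), df$patient), function(rows) {
    det <- rows[df$plasma_detected[rows] == "yes"]
    list(tissue = mk(rows, df$tissue_vaf, df$tissue_copies, "FFPE"),
         plasma = mk(det, df$plasma_vaf, df$plasma_copies, "PLASMA"))
  })
}

#' Clinical-validation cohort tallies
#'
#' The patient- and alteration-level tallies of the assay's clinical
#' validation cohort (1368 eligible cases, 1345 successfully sequenced),
#' including actionability-tier counts, immunotherapy-biomarker counts, HRR
#' counts, the ovarian gLOH subgroup, and the orthogonal MSI and HER2
#' comparison counts.
#'
#' @return named numeric vector of tallies.
#' @export
cohort_validation_tallies <- function() {
  df <- utils::read.table(panelval_extdata("clinical_cohort_tallies.tsv"),
                          sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$key)
}

#' Expand cohort tallies into a patient-level table
#'
#' Deterministically realizes the tally sheet as one row per sequenced
#' patient with an actionability tier and immunotherapy flags, so the cohort
#' fractions can be recomputed by [actionability_rollup()] rather than read
#' off. The printed marginals fix the flag/tier overlap: the number of
#' flagged patients outside the on-label tier must equal
#' `patients_combined_on_label - patients_on_label`; MSI-high patients are
#' placed inside the TMB-flagged block.
#'
#' @param tallies named vector from [cohort_validation_tallies()].
#' @return `data.frame` with `patient_id`, `tier`, `msi_high`, `tmb_high`.
#' @export
cohort_from_counts <- function(tallies = cohort_validation_tallies()) {
  n <- tallies[["patients_sequenced"]]
  n_on <- tallies[["patients_on_label"]]
  n_off <- tallies[["patients_off_label"]]
  n_res <- tallies[["patients_resistance"]]
  n_tmb <- tallies[["patients_tmb_high"]]
  n_msi <- tallies[["patients_msi_high"]]
  extra <- tallies[["patients_combined_on_label"]] - n_on
  stopifnot(n_on + n_off + n_res <= n, extra >= n_msi, n_tmb >= extra)
  tier <- rep("none", n)
  tier[seq_len(n_on)] <- "on_label"
  tier[n_on + seq_len(n_off)] <- "off_label"
  tier[n_on + n_off + seq_len(n_res)] <- "resistance"
  tmb_high <- rep(FALSE, n)
  # `extra` flagged patients sit outside the on-label tier; the remaining
  # TMB-high flags overlap the on-label tier (they do not add to the
  # combined count)
  tmb_high[n_on + seq_len(extra)] <- TRUE
  tmb_high[n_on - seq_len(n_tmb - extra) + 1L] <- TRUE
  msi_high <- rep(FALSE, n)
  msi_high[n_on + seq_len(n_msi)] <- TRUE
  data.frame(patient_id = seq_len(n), tier = tier,
             msi_high = msi_high, tmb_high = tmb_high,
             stringsAsFactors = FALSE)
}

#' Build a reference-standard truth table
#'
#' Constructs the truth set of a multi-analyte standard in the style of the
#' commercial 2%/0.5% standards: `n_snv` SNV/indel variants at the design
#' VAF across recurrent hotspot genes, `n_cnv` amplifications at the design
#' copy number, and `n_fusion` rearrangements at the design VAF.
#'
#' @param design_vaf design VAF for SNV/indel/fusion variants.
#' @param n_snv,n_cnv,n_fusion variant counts (defaults 27/3/6).
#' @param design_copies CNV design copy number (default 6).
#' @return variant-call style truth `data.frame`.
#' @export
standard_truth <- function(design_vaf, n_snv = 27L, n_cnv = 3L,
                           n_fusion = 6L, design_copies = 6) {
  snv_genes <- rep(c("EGFR", "KRAS", "NRAS", "KIT", "BRAF", "PIK3CA"),
                   length.out = n_snv)
  fusion5 <- rep(c("EML4", "CD74", "KIF5B", "CCDC6", "TPM3", "SDC4"),
                 length.out = n_fusion)
  fusion3 <- rep(c("ALK", "ROS1", "RET"), length.out = n_fusion)
  rbind(
    variant_calls(kind = rep("SNV", n_snv), chrom = "chr7",
                  pos = 55000000L + seq_len(n_snv) * 1000L,
                  ref = "A", alt = "G", gene = snv_genes, vaf = design_vaf),
    variant_calls(kind = rep("CNV", n_cnv),
                  gene = rep(c("ERBB2", "MET", "MYCN"), length.out = n_cnv),
                  copies = design_copies),
    variant_calls(kind = rep("FUSION", n_fusion), gene5 = fusion5,
                  gene3 = fusion3, vaf = design_vaf)
  )
}

#' Example driver-mutation exclusion catalog
#' @return `data.frame` with `gene` and `rule` columns.
#' @export
driver_catalog_example <- function() {
  utils::read.table(panelval_extdata("driver_catalog_example.tsv"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
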