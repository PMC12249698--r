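#' Round half-up at a fixed number of decimals
#'
#' Percentages in validation reports are printed at 2 decimals with half-up
#' rounding (so 12.565 prints as 12.57), matching clinical-report convention
#' rather than R's banker's rounding.
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' TMB scoring policy
#'
#' The assay's tumor-mutational-burden algorithm counts all somatic SNVs and
#' indels — synonymous included — falling in the coding footprint or within
#' +/- 2 bp of a splice junction, keeps only mutations with VAF strictly
#' above 5%, and excludes catalogued driver mutations (tumor-suppressor
#' inactivating, driver-gene sensitive, and driver-gene high-frequency
#' classes). The count is divided by the coding footprint in megabases,
#' which must exceed 1 Mb.
#'
#' @param coding_megabases coding footprint in Mb (> 1).
#' @param min_vaf VAF floor, strict inequality (default 0.05).
#' @param include_synonymous count synonymous mutations (default `TRUE`).
#' @param splice_window splice-region window in bp (default 2).
#' @param driver_catalog `data.frame` with columns `gene` and `rule`
#'   (`tumor_suppressor_inactivating`, `driver_sensitive`,
#'   `driver_high_frequency`); matching calls are excluded from the count.
#' @return a `tmb_policy` list.
#' @export
tmb_policy <- function(coding_megabases, min_vaf = 0.05,
                       include_synonymous = TRUE, splice_window = 2L,
                       driver_catalog = NULL) {
  if (coding_megabases <= 1)
    stop("coding footprint must exceed 1 Mb")
  if (min_vaf <= 0 || min_vaf >= 1) stop("min_vaf must lie in (0,1)")
  if (is.null(driver_catalog))
    driver_catalog <- data.frame(gene = character(), rule = character(),
                                 stringsAsFactors = FALSE)
  structure(list(coding_megabases = coding_megabases, min_vaf = min_vaf,
                 include_synonymous = isTRUE(include_synonymous),
                 splice_window = as.integer(splice_window),
                 driver_catalog = driver_catalog),
            class = "tmb_policy")
}

#' Identify the calls eligible for the TMB count
#'
#' @param calls variant-call `data.frame` with annotation columns `consequence`
#'   (e.g. `"synonymous"`, `"missense"`), logical `coding`, numeric
#'   `splice_distance` (bp to nearest junction, `NA` if far), and optional
#'   `driver_class` matching the catalog's `rule` values.
#' @param policy a [tmb_policy()].
#' @return logical vector over rows of `calls`.
#' @export
tmb_eligible <- function(calls, policy) {
  if (nrow(calls) == 0L) return(logical(0))
  kind_ok <- calls$kind %in% c("SNV", "INDEL")
  vaf_ok <- !is.na(calls$vaf) & calls$vaf > policy$min_vaf
  coding <- if ("coding" %in% names(calls)) calls$coding else TRUE
  spl <- if ("splice_distance" %in% names(calls)) calls$splice_distance else NA_real_
  region_ok <- (coding %in% TRUE) |
    (!is.na(spl) & abs(spl) <= policy$splice_window)
  cons <- if ("consequence" %in% names(calls)) calls$consequence else NA_character_
  syn_ok <- policy$include_synonymous | is.na(cons) | cons != "synonymous"
  drv <- if ("driver_class" %in% names(calls)) calls$driver_class else NA_character_
  cat_key <- paste(policy$driver_catalog$gene, policy$driver_catalog$rule)
  driver_excluded <- !is.na(drv) & paste(calls$gene, drv) %in% cat_key
  kind_ok & vaf_ok & region_ok & syn_ok & !driver_excluded
}

#' Tumor mutational burden in mutations per megabase
#'
#' @inheritParams tmb_eligible
#' @return TMB score (eligible mutation count / coding footprint in Mb).
#' @export
tmb_score <- function(calls, policy) {
  stopifnot(inherits(policy, "tmb_policy"))
  sum(tmb_eligible(calls, policy)) / policy$coding_megabases
}

#' Classify microsatellite instability status
#'
#' MSI-high iff the unstable-site fraction reaches the compartment cutoff
#' (inclusive): >= 19.5% for FFPE tissue, >= 18% for plasma.
#'
#' @param score fraction of unstable microsatellite sites in `[0,1]`.
#' @param compartment `"FFPE"` or `"PLASMA"`.
#' @param policy a [positivity_policy()] carrying the MSI cutoffs.
#' @return list with `score`, `status` (`"MSI-H"` or `"MSS"`), `compartment`.
#' @export
msi_classify <- function(score, compartment = c("FFPE", "PLASMA"),
                         policy = positivity_policy()) {
  compartment <- match.arg(compartment)
  if (any(score < 0 | score > 1)) stop("MSI score must lie in [0,1]")
  cutoff <- if (compartment == "FFPE") policy$msi_cutoff_ffpe else policy$msi_cutoff_plasma
  list(score = score,
       status = ifelse(score >= cutoff, "MSI-H", "MSS"),
       compartment = compartment)
}

#' Summarize homologous recombination repair (HRR) gene alterations
#'
#' Computes per-patient HRR flags and cohort fractions: patients with any
#' loss-of-function alteration in the HRR gene set, with BRCA1/2, with
#' high-risk genes, and with more than one distinct HRR gene altered.
#' Fractions are percents of `n_patients`, rounded half-up at 2 decimals.
#'
#' @param alterations `data.frame` with `patient_id`, `gene` and logical
#'   `lof` columns (one row per altered gene per patient).
#' @param n_patients cohort denominator.
#' @param hrr_genes character vector of HRR gene symbols (the assay panels
#'   26 of them; see [hrr_gene_list()]).
#' @param high_risk_genes high-risk subset (default BRCA1/2, PALB2, RAD51C).
#' @return list with `per_patient` flags and `fractions` (percents).
#' @export
hrr_summary <- function(alterations, n_patients,
                        hrr_genes = hrr_gene_list(),
                        high_risk_genes = c("BRCA1", "BRCA2", "PALB2", "RAD51C")) {
  if (length(hrr_genes) == 0L) stop("HRR gene list must be non-empty")
  lof <- alterations[alterations$lof %in% TRUE &
                       alterations$gene %in% hrr_genes, , drop = FALSE]
  per <- if (nrow(lof)) {
    agg <- stats::aggregate(gene ~ patient_id, lof,
                            function(g) length(unique(g)))
    names(agg)[2] <- "n_hrr_genes"
    agg$brca <- agg$patient_id %in%
      lof$patient_id[lof$gene %in% c("BRCA1", "BRCA2")]
    agg$high_risk <- agg$patient_id %in%
      lof$patient_id[lof$gene %in% high_risk_genes]
    agg
  } else {
    data.frame(patient_id = integer(), n_hrr_genes = integer(),
               brca = logical(), high_risk = logical())
  }
  pct <- function(k) round_half_up(100 * k / n_patients, 2)
  list(per_patient = per,
       fractions = c(any_hrr_lof = pct(nrow(per)),
                     brca12 = pct(sum(per$brca)),
                     high_risk = pct(sum(per$high_risk)),
                     multiple_hrr = pct(sum(per$n_hrr_genes > 1))))
}

#' The 26 HRR genes interrogated by the panel
#' @return character vector of gene symbols.
#' @export
hrr_gene_list <- function() {
  c("BRCA1", "BRCA2", "PALB2", "RAD51C", "RAD51B", "RAD51D", "RAD54L",
    "ATM", "ATR", "BAP1", "BARD1", "BRIP1", "CHEK1", "CHEK2", "CDK12",
    "FANCA", "FANCC", "FANCD2", "FANCE", "FANCF", "FANCM", "MRE11",
    "NBN", "PPP2R2A", "RAD50", "EMSY"
  )
}

.tier_levels <- c("on_label", "off_label", "resistance", "none")

#' Most actionable tier among a patient's variants
#'
#' @param tiers character vector of per-variant tiers
#'   (`on_label` > `off_label` > `resistance` > `none`).
#' @return the single highest tier (`"none"` for an empty vector).
#' @export
most_actionable <- function(tiers) {
  bad <- setdiff(tiers, .tier_levels)
  if (length(bad)) stop("unknown tier label(s): ", paste(bad, collapse = ", "))
  if (length(tiers) == 0L) return("none")
  .tier_levels[min(match(tiers, .tier_levels))]
}

#' Cohort actionability roll-up
#'
#' Tallies patients by their most actionable variant tier, and a second
#' roll-up in which immunotherapy biomarkers (MSI-high status or TMB above
#' 10 muts/Mb, strict) count as site-agnostic on-label markers, yielding the
#' combined on-label fraction. Fractions are percents of the cohort,
#' rounded half-up at 2 decimals; the per-tier fractions sum to 100 up to
#' rounding.
#'
#' @param records per-patient `data.frame` with columns `tier` (the most
#'   actionable tier) and logicals `msi_high`, `tmb_high` (alternatively a
#'   numeric `tmb` column, thresholded at `tmb_high_cutoff`).
#' @param tmb_high_cutoff TMB-high threshold in muts/Mb (default 10, strict).
#' @return list with `counts`, `fractions` (per tier), and
#'   `combined_on_label` (percent) plus `combined_count`.
#' @export
actionability_rollup <- function(records, tmb_high_cutoff = 10) {
  bad <- setdiff(records$tier, .tier_levels)
  if (length(bad)) stop("unknown tier label(s): ", paste(bad, collapse = ", "))
  n <- nrow(records)
  if (n == 0L) stop("no patient records")
  tmb_high <- if ("tmb_high" %in% names(records)) records$tmb_high %in% TRUE
              else records$tmb > tmb_high_cutoff
  msi_high <- if ("msi_high" %in% names(records)) records$msi_high %in% TRUE
              else rep(FALSE, n)
  counts <- vapply(.tier_levels, function(t) sum(records$tier == t), integer(1))
  combined <- sum(records$tier == "on_label" | msi_high | tmb_high)
  list(counts = counts,
       fractions = round_half_up(100 * counts / n, 2),
       immunotherapy = c(msi_high = sum(msi_high), tmb_high = sum(tmb_high)),
       immunotherapy_fractions = round_half_up(
         100 * c(msi_high = sum(msi_high), tmb_high = sum(tmb_high)) / n, 2),
       combined_count = combined,
       combined_on_label = round_half_up(100 * combined / n, 2),
       n = n)
}
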