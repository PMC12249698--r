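#' Construct a table of variant calls
#'
#' The canonical call container used throughout the package is a plain
#' `data.frame` with one row per called alteration. Four kinds are supported:
#' `"SNV"` and `"INDEL"` (located by `chrom`/`pos`/`ref`/`alt`, quantified by
#' `vaf`), `"CNV"` (located by `gene`, quantified by `copies`) and `"FUSION"`
#' (located by the unordered gene pair `gene5`/`gene3`, quantified by `vaf`
#' as a supporting-read fraction). `compartment` is `"FFPE"` or `"PLASMA"`.
#'
#' Columns irrelevant to a row's kind are `NA`. Additional annotation columns
#' (consequence, coding flag, splice distance, driver class, loss-of-function
#' flag, actionability tier, HGVS label) are passed through untouched.
#'
#' @param kind character vector in `c("SNV","INDEL","CNV","FUSION")`.
#' @param chrom,pos,ref,alt SNV/indel locus (1-based position, VCF-style
#'   alleles). `NA` for CNV/fusion rows.
#' @param gene gene symbol (CNV rows; optional annotation elsewhere).
#' @param gene5,gene3 fusion partners (fusion rows).
#' @param vaf variant allele frequency in `[0,1]` (SNV/indel/fusion).
#' @param copies observed copy number `>= 0` (CNV).
#' @param depth total read depth at the locus.
#' @param alt_reads alternate-supporting read count.
#' @param compartment `"FFPE"` or `"PLASMA"`.
#' @param ... further equal-length annotation columns.
#' @return a `data.frame` of calls.
#' @export
variant_calls <- function(kind = character(), chrom = NA_character_,
                          pos = NA_integer_, ref = NA_character_,
                          alt = NA_character_, gene = NA_character_,
                          gene5 = NA_character_, gene3 = NA_character_,
                          vaf = NA_real_, copies = NA_real_,
                          depth = NA_real_, alt_reads = NA_real_,
                          compartment = NA_character_, ...) {
  n <- length(kind)
  df <- data.frame(
    kind = as.character(kind),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    gene = rep_len(as.character(gene), n),
    gene5 = rep_len(as.character(gene5), n),
    gene3 = rep_len(as.character(gene3), n),
    vaf = rep_len(as.numeric(vaf), n),
    copies = rep_len(as.numeric(copies), n),
    depth = rep_len(as.numeric(depth), n),
    alt_reads = rep_len(as.numeric(alt_reads), n),
    compartment = rep_len(as.character(compartment), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_variant_calls(df)
  df
}

#' @keywords internal
validate_variant_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0L) return(invisible(calls))
  bad_kind <- !calls$kind %in% c("SNV", "INDEL", "CNV", "FUSION")
  if (any(bad_kind))
    stop("unknown variant kind in row(s): ", paste(which(bad_kind), collapse = ", "))
  v <- calls$vaf
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("vaf outside [0,1] in row(s): ",
         paste(which(!is.na(v) & (v < 0 | v > 1)), collapse = ", "))
  cp <- calls$copies
  if (any(!is.na(cp) & cp < 0))
    stop("negative copy number in row(s): ", paste(which(!is.na(cp) & cp < 0), collapse = ", "))
  invisible(calls)
}

#' Positivity thresholds for call reporting
#'
#' Reporting (positivity) thresholds by variant class and compartment.
#' The assay's stated rule reports SNVs/indels/SVs at allele frequency
#' >= 1% in both compartments, CNVs at copy number >= 3.0 in FFPE tissue and
#' >= 2.2 in plasma, and MSI-high at unstable-site fractions >= 19.5% (FFPE)
#' and >= 18% (plasma). The default preset keeps the plasma SNV/indel
#' threshold at the 0.5% limit-of-detection tier the assay validates, since
#' plasma findings are reported down to that range; the literal 1%-everywhere
#' rule is available as `preset = "vaf_1pct"`.
#'
#' @param preset `"default"` (plasma SNV/indel threshold 0.005) or
#'   `"vaf_1pct"` (0.01 in both compartments).
#' @param snv_min_vaf_ffpe,snv_min_vaf_plasma minimum VAF for SNV/indel/fusion.
#' @param cnv_min_copies_ffpe,cnv_min_copies_plasma minimum copy number.
#' @param msi_cutoff_ffpe,msi_cutoff_plasma MSI-high cutoffs on the
#'   unstable-site fraction (used by [msi_classify()]).
#' @return a `positivity_policy` list.
#' @export
positivity_policy <- function(preset = c("default", "vaf_1pct"),
                              snv_min_vaf_ffpe = 0.01,
                              snv_min_vaf_plasma = NULL,
                              cnv_min_copies_ffpe = 3.0,
                              cnv_min_copies_plasma = 2.2,
                              msi_cutoff_ffpe = 0.195,
                              msi_cutoff_plasma = 0.18) {
  preset <- match.arg(preset)
  if (is.null(snv_min_vaf_plasma))
    snv_min_vaf_plasma <- if (preset == "vaf_1pct") 0.01 else 0.005
  pol <- list(
    snv_min_vaf_ffpe = snv_min_vaf_ffpe,
    snv_min_vaf_plasma = snv_min_vaf_plasma,
    cnv_min_copies_ffpe = cnv_min_copies_ffpe,
    cnv_min_copies_plasma = cnv_min_copies_plasma,
    msi_cutoff_ffpe = msi_cutoff_ffpe,
    msi_cutoff_plasma = msi_cutoff_plasma
  )
  if (any(unlist(pol) <= 0)) stop("all positivity thresholds must be > 0")
  if (cnv_min_copies_plasma >= cnv_min_copies_ffpe)
    stop("plasma CNV cutoff must be below the tissue cutoff")
  class(pol) <- "positivity_policy"
  pol
}

#' Filter calls by compartment-specific positivity thresholds
#'
#' SNV/indel/fusion rows are retained iff `vaf >=` the compartment VAF
#' threshold (inclusive); CNV rows iff `copies >=` the compartment copy-number
#' cutoff. Row order is preserved and the operation is idempotent.
#'
#' @param calls a variant-call `data.frame` with `compartment` set.
#' @param policy a [positivity_policy()].
#' @return the retained subset of `calls`.
#' @export
apply_positivity <- function(calls, policy = positivity_policy()) {
  validate_variant_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  if (any(is.na(calls$compartment)))
    stop("compartment missing in row(s): ",
         paste(which(is.na(calls$compartment)), collapse = ", "))
  is_cnv <- calls$kind == "CNV"
  if (any(is_cnv & is.na(calls$copies)))
    stop("CNV call missing copy number in row(s): ",
         paste(which(is_cnv & is.na(calls$copies)), collapse = ", "))
  if (any(!is_cnv & is.na(calls$vaf)))
    stop("call missing VAF in row(s): ",
         paste(which(!is_cnv & is.na(calls$vaf)), collapse = ", "))
  plasma <- calls$compartment == "PLASMA"
  vaf_thr <- ifelse(plasma, policy$snv_min_vaf_plasma, policy$snv_min_vaf_ffpe)
  cn_thr <- ifelse(plasma, policy$cnv_min_copies_plasma, policy$cnv_min_copies_ffpe)
  keep <- ifelse(is_cnv, calls$copies >= cn_thr, calls$vaf >= vaf_thr)
  calls[keep, , drop = FALSE]
}

#' Confusion-matrix counts
#'
#' @param tp,fp,fn true-positive, false-positive, false-negative counts.
#' @param tn true negatives; `NA` when the truth set declares no negative
#'   universe (hotspot panels without wild-type positions).
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn = NA_integer_) {
  cnt <- c(tp = tp, fp = fp, fn = fn)
  if (any(cnt < 0) || (!is.na(tn) && tn < 0)) stop("confusion counts must be >= 0")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

# Left-align an indel (trim shared suffix, then shared prefix, advancing pos):
# removes representation differences between VCF dialects before matching.
#' @keywords internal
normalize_allele <- function(pos, ref, alt) {
  if (is.na(ref) || is.na(alt)) return(list(pos = pos, ref = ref, alt = alt))
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' @keywords internal
match_key <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    k <- calls$kind[i]
    if (k %in% c("SNV", "INDEL")) {
      nz <- normalize_allele(calls$pos[i], calls$ref[i], calls$alt[i])
      paste("snvindel", calls$chrom[i], nz$pos, nz$ref, nz$alt, sep = ":")
    } else if (k == "CNV") {
      paste("cnv", calls$gene[i], sep = ":")
    } else {
      pair <- sort(c(calls$gene5[i], calls$gene3[i]))
      paste("fusion", pair[1], pair[2], sep = ":")
    }
  }, character(1))
}

#' Match calls against a truth set
#'
#' SNVs/indels match on left-aligned (chrom, pos, ref, alt); CNVs on gene
#' symbol; fusions on the unordered gene pair. Each truth variant is matched
#' at most once. False positives are calls with no truth partner; false
#' negatives are truth variants with no call. When the truth set carries a
#' declared list of interrogated wild-type positions
#' (`attr(truth, "negative_positions")`, a data.frame with `chrom`/`pos`),
#' true negatives are the wild-type positions with no call at them; otherwise
#' `tn` is `NA` (specificity undefined).
#'
#' @param calls variant-call `data.frame`.
#' @param truth truth-set `data.frame` in the same schema (its `vaf` column is
#'   read as the design VAF; not used for matching).
#' @return list with `confusion` ([confusion_counts()]) and `matches`, a per-
#'   truth-variant table with the index of the matching call (`NA` if missed).
#' @export
match_calls <- function(calls, truth) {
  if (nrow(truth) == 0L) stop("truth set is empty")
  tk <- match_key(truth)
  if (anyDuplicated(tk))
    stop("duplicate truth entries: ", paste(unique(tk[duplicated(tk)]), collapse = "; "))
  ck <- if (nrow(calls)) match_key(calls) else character(0)
  call_idx <- match(tk, ck)                    # first call per truth key
  tp <- sum(!is.na(call_idx))
  fn <- sum(is.na(call_idx))
  fp <- sum(!ck %in% tk)
  tn <- NA_integer_
  neg <- attr(truth, "negative_positions")
  if (!is.null(neg)) {
    negk <- paste(neg$chrom, neg$pos, sep = ":")
    called_pos <- paste(calls$chrom, calls$pos, sep = ":")
    tn <- sum(!negk %in% called_pos)
  }
  list(
    confusion = confusion_counts(tp = tp, fp = fp, fn = fn, tn = tn),
    matches = data.frame(truth_key = tk, call_index = call_idx,
                         stringsAsFactors = FALSE)
  )
}

#' Paired tissue/plasma concordance for one patient
#'
#' Matches plasma calls against the patient's tissue calls using the same
#' identity rules as [match_calls()] and reports, per tissue variant, the
#' tissue and plasma quantitation ("Not Detected" where the plasma assay saw
#' nothing). A case is concordant when at least one tissue variant is
#' recovered in plasma.
#'
#' @param tissue_calls,plasma_calls variant-call `data.frame`s for one patient.
#' @return list with `table` (per-tissue-variant comparison) and
#'   `case_concordant` (logical; `FALSE` when tissue is empty).
#' @export
pair_concordance <- function(tissue_calls, plasma_calls) {
  if (nrow(tissue_calls) == 0L) {
    return(list(table = data.frame(), case_concordant = FALSE))
  }
  tk <- match_key(tissue_calls)
  pk <- if (nrow(plasma_calls)) match_key(plasma_calls) else character(0)
  hit <- match(tk, pk)
  quant <- function(df, i) {
    if (is.na(i)) return(c(NA_real_, NA_real_))
    c(df$vaf[i], df$copies[i])
  }
  pq <- t(vapply(hit, function(i) quant(plasma_calls, i), numeric(2)))
  lab <- tissue_calls$gene
  lab[tissue_calls$kind == "FUSION"] <-
    paste0(tissue_calls$gene5[tissue_calls$kind == "FUSION"], "-",
           tissue_calls$gene3[tissue_calls$kind == "FUSION"])
  tab <- data.frame(
    variant = ifelse(!is.na(tissue_calls$chrom) & tissue_calls$kind %in% c("SNV", "INDEL"),
                     paste0(tissue_calls$chrom, ":", tissue_calls$pos), lab),
    gene = lab,
    kind = tissue_calls$kind,
    tissue_vaf = tissue_calls$vaf,
    tissue_copies = tissue_calls$copies,
    plasma_vaf = pq[, 1],
    plasma_copies = pq[, 2],
    plasma_status = ifelse(is.na(hit), "Not Detected", "Detected"),
    stringsAsFactors = FALSE
  )
  list(table = tab, case_concordant = any(!is.na(hit)))
}
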