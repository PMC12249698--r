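#' Write SNV/indel calls as VCF 4.2
#'
#' Emits a minimal VCF 4.2 with INFO keys `VAF` (alternate allele fraction),
#' `DP` (total depth) and `AD` (alternate read count). Only SNV/INDEL rows
#' are written.
#'
#' @param calls variant-call `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  snv <- calls[calls$kind %in% c("SNV", "INDEL"), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelval",
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Alternate allele fraction">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=AD,Number=1,Type=Integer,Description="Alternate-supporting reads">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf("VAF=%s;DP=%s;AD=%s",
                  format(snv$vaf, digits = 10, scientific = FALSE, trim = TRUE),
                  ifelse(is.na(snv$depth), ".", format(snv$depth, trim = TRUE)),
                  ifelse(is.na(snv$alt_reads), ".", format(snv$alt_reads, trim = TRUE)))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                 snv$chrom, snv$pos, snv$ref, snv$alt, info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read SNV/indel calls from a VCF
#'
#' Parses with `vcfR` and requires the `VAF` INFO key; `DP` and `AD` are
#' read when present. Malformed or missing VAF values raise an error naming
#' the offending record.
#'
#' @param path VCF path.
#' @param compartment compartment to stamp on the calls.
#' @return variant-call `data.frame`.
#' @export
read_vcf <- function(path, compartment = "FFPE") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_calls())
  raw_vaf <- vcfR::extract.info(v, "VAF")
  if (all(is.na(raw_vaf)))
    stop("VAF INFO field missing in ", path)
  vaf <- suppressWarnings(as.numeric(raw_vaf))
  bad <- which(is.na(vaf) | is.na(raw_vaf))
  if (length(bad))
    stop("missing or malformed VAF in ", path, " at record(s): ",
         paste(bad, collapse = ", "))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  ad <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AD")))
  kind <- ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "SNV", "INDEL")
  variant_calls(kind = kind, chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT, vaf = vaf, depth = dp,
                alt_reads = ad, compartment = compartment)
}

#' Write a variant-call table as TSV
#'
#' Tabular interchange for CNV and fusion calls (and whole mixed call sets):
#' the full call schema as tab-separated text.
#' @param calls variant-call `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a variant-call table written by [write_calls_tsv()]
#' @param path TSV path.
#' @return variant-call `data.frame`.
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = NA)
  validate_variant_calls(df)
  df
}

#' Write segments in SEG format
#'
#' Standard tab-delimited segmented-data format (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`); the logR mean is the segment mean.
#' An extended TSV with the allele-specific columns (`nA`, `nB`, `is_loh`)
#' can be written alongside via [write_calls_tsv()]-style `write.table`.
#'
#' @param segments segment table (from [segment_profile()] or [call_ascn()]).
#' @param path output path.
#' @param sample sample identifier for the `ID` column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  seg <- data.frame(ID = sample, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_snps, seg.mean = segments$mean_logr)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#' @param path SEG path.
#' @return `data.frame` with `sample`, `chrom`, `start`, `end`, `n_snps`,
#'   `mean_logr`.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- c("sample", "chrom", "start", "end", "n_snps", "mean_logr")
  df
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are returned in those coordinates
#' (the convention [gene_loh_intersect()] expects), with the `name` column
#' as `gene`.
#'
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end`, `gene`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a SNP profile as TSV
#' @param profile SNP profile `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP profile TSV
#' @param path TSV path with columns `chrom`, `pos`, `baf`, `logr`.
#' @return SNP profile `data.frame`.
#' @export
read_snp_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "baf", "logr") %in% names(df)))
  df
}

#' Assemble a run configuration
#'
#' A schema-versioned configuration bundling the seed, compartment mode and
#' the policy objects driving a pipeline run; serialized as YAML.
#'
#' @param seed master seed.
#' @param mode `"FFPE"` or `"PLASMA"`.
#' @param positivity a [positivity_policy()].
#' @param tmb a [tmb_policy()] or `NULL`.
#' @param qc a [qc_policy()].
#' @param loh named list of LOH settings.
#' @param paths named list of input/output paths.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, mode = c("FFPE", "PLASMA"),
                       positivity = positivity_policy(), tmb = NULL,
                       qc = qc_policy(),
                       loh = list(whole_chrom_fraction = 0.9,
                                  high_gloh_cutoff = 16),
                       paths = list()) {
  mode <- match.arg(mode)
  structure(list(schema_version = "1", seed = as.integer(seed), mode = mode,
                 positivity = unclass(positivity),
                 tmb = if (is.null(tmb)) NULL else
                   unclass(tmb)[setdiff(names(tmb), "driver_catalog")],
                 qc = unclass(qc), loh = loh, paths = paths),
            class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Fails if the schema version is unknown or any referenced input path is
#' unresolvable.
#' @param path YAML path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != "1")
    stop("unsupported config schema version: ", cfg$schema_version)
  for (p in cfg$paths) {
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p)
  }
  class(cfg) <- "run_config"
  cfg
}
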