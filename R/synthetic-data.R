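#' Derive a stream-specific seed from a master seed
#'
#' All simulators take one explicit integer seed; independent random streams
#' (replicates, patients) are derived from it with a small multiplicative
#' congruential step so that sub-streams are reproducible and distinct.
#' @param seed master seed (integer).
#' @param stream stream index (integer >= 0).
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

#' Specification of a reference standard
#'
#' Describes a commercial-style reference standard: a fixed list of truth
#' variants with design VAFs (or design copy numbers for CNVs), a target mean
#' sequencing depth, and a replicate count. The assay's validation tiers put
#' SNV/indel/fusion variants at 2%, 1-1.3% and 0.5-0.65% design VAF at mean
#' depths of roughly 1000x, 993x/560x and 794x-2000x.
#'
#' @param name standard name.
#' @param truth a variant-call style `data.frame` (see [variant_calls()]);
#'   `vaf` holds the design VAF for SNV/indel/fusion rows, `copies` the design
#'   copy number for CNV rows. Loci must be unique.
#' @param depth_target target mean depth (> 0).
#' @param n_replicates number of simulated library replicates.
#' @param compartment `"FFPE"` or `"PLASMA"`.
#' @param seed master seed.
#' @return a `reference_standard_spec` list.
#' @export
reference_standard_spec <- function(name, truth, depth_target,
                                    n_replicates = 1L,
                                    compartment = "FFPE", seed = 1L) {
  validate_variant_calls(truth)
  if (depth_target <= 0) stop("depth_target must be > 0")
  snv <- truth$kind %in% c("SNV", "INDEL", "FUSION")
  if (any(is.na(truth$vaf[snv])) || any(truth$vaf[snv] < 0) || any(truth$vaf[snv] > 1))
    stop("design VAFs must lie in [0,1]")
  if (anyDuplicated(match_key(truth)))
    stop("truth loci must be unique within a standard")
  structure(list(name = name, truth = truth, depth_target = depth_target,
                 n_replicates = as.integer(n_replicates),
                 compartment = compartment, seed = as.integer(seed)),
            class = "reference_standard_spec")
}

# Read-level detection model shared by every simulator: total depth is
# Poisson around the target, alternate reads are Binomial(depth, VAF), and a
# call is emitted iff alt_reads >= min_alt_reads and the observed VAF clears
# the caller-level reporting floor (0 by default; compartment positivity is a
# separate downstream stage, see apply_positivity()).
#' @keywords internal
sample_snv_detection <- function(design_vaf, depth_target, min_alt_reads,
                                 reporting_min_vaf) {
  depth <- stats::rpois(length(design_vaf), depth_target)
  depth[depth < 1] <- 1L
  alt <- stats::rbinom(length(design_vaf), depth, design_vaf)
  obs_vaf <- alt / depth
  list(depth = depth, alt = alt, vaf = obs_vaf,
       called = alt >= min_alt_reads & obs_vaf >= reporting_min_vaf)
}

#' Simulate replicate call sets for a reference standard
#'
#' For each replicate and each SNV/indel/fusion truth variant, total depth is
#' drawn Poisson around the target and alternate reads Binomial(depth, design
#' VAF); the variant is called iff at least `min_alt_reads` alternate reads
#' are observed and the observed VAF clears `reporting_min_vaf`. CNVs are
#' always observed, with Gaussian noise on the design copy number
#' (sd 0.15 in FFPE, 0.3 in plasma). Deterministic given the spec seed.
#'
#' @param spec a [reference_standard_spec()].
#' @param min_alt_reads minimum alternate reads for a call (default 3).
#' @param reporting_min_vaf caller-level observed-VAF floor (default 0).
#' @param cnv_noise_sd_ffpe,cnv_noise_sd_plasma copy-number observation noise.
#' @return list with `truth` (the spec's truth table) and `replicates`, a list
#'   of variant-call `data.frame`s (called variants only).
#' @export
simulate_reference_standard <- function(spec, min_alt_reads = 3L,
                                        reporting_min_vaf = 0,
                                        cnv_noise_sd_ffpe = 0.15,
                                        cnv_noise_sd_plasma = 0.3) {
  stopifnot(inherits(spec, "reference_standard_spec"))
  truth <- spec$truth
  is_cnv <- truth$kind == "CNV"
  cnv_sd <- if (identical(spec$compartment, "PLASMA")) cnv_noise_sd_plasma else cnv_noise_sd_ffpe
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    set.seed(derive_seed(spec$seed, r))
    out <- truth
    out$compartment <- spec$compartment
    det <- sample_snv_detection(ifelse(is_cnv, 0, truth$vaf), spec$depth_target,
                                min_alt_reads, reporting_min_vaf)
    out$depth <- det$depth
    out$alt_reads <- det$alt
    out$vaf[!is_cnv] <- det$vaf[!is_cnv]
    out$copies[is_cnv] <- truth$copies[is_cnv] + stats::rnorm(sum(is_cnv), 0, cnv_sd)
    out$copies[is_cnv & out$copies < 0] <- 0
    keep <- det$called | is_cnv
    out[keep, , drop = FALSE]
  })
  list(truth = truth, replicates = reps)
}

#' Specification of a simulated clinical cohort
#'
#' @param n_patients cohort size.
#' @param tumor_type_mix named numeric vector of tumor-type proportions
#'   (must sum to 1).
#' @param gene_alt_freqs named numeric vector: per-gene probability that a
#'   patient carries an alteration in that gene (independent Bernoulli draws).
#' @param msi_high_prev MSI-high prevalence.
#' @param tmb_meanlog,tmb_sdlog log-normal parameters of the TMB distribution
#'   (muts/Mb); the defaults put ~9-10% of patients above 10 muts/Mb,
#'   matching pan-cancer TMB-high prevalence in a solid-tumor referral mix.
#' @param gloh_mean,gloh_sd Gaussian parameters (truncated at 0) of percent
#'   gLOH for designated tumor types; defaults put roughly half of ovarian
#'   cases above a 16% cutoff.
#' @param gloh_tumor_types tumor types for which gLOH is measured.
#' @param seed master seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients,
                        tumor_type_mix = c(pancreatic = 0.2, lung = 0.18,
                                           colorectal = 0.16, breast = 0.14,
                                           ovarian = 0.06, other = 0.26),
                        gene_alt_freqs = c(TP53 = 0.4766, KRAS = 0.2625,
                                           CDKN2A = 0.1441, PIK3CA = 0.1279,
                                           TERT = 0.1152),
                        msi_high_prev = 0.0119,
                        tmb_meanlog = log(3.5), tmb_sdlog = 0.8,
                        gloh_mean = 16.3, gloh_sd = 8,
                        gloh_tumor_types = "ovarian",
                        seed = 1L) {
  if (length(tumor_type_mix) == 0L) stop("tumor type mix must be non-empty")
  if (abs(sum(tumor_type_mix) - 1) > 1e-9) stop("tumor type proportions must sum to 1")
  if (any(gene_alt_freqs < 0 | gene_alt_freqs > 1) ||
      msi_high_prev < 0 || msi_high_prev > 1)
    stop("probabilities must lie in [0,1]")
  structure(list(n_patients = as.integer(n_patients),
                 tumor_type_mix = tumor_type_mix,
                 gene_alt_freqs = gene_alt_freqs,
                 msi_high_prev = msi_high_prev,
                 tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
                 gloh_mean = gloh_mean, gloh_sd = gloh_sd,
                 gloh_tumor_types = gloh_tumor_types,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a clinical cohort with biomarker annotations
#'
#' Each patient receives a tumor type (multinomial over the configured mix),
#' independent per-gene alteration indicators, a log-normal TMB value, an MSI
#' status drawn at the configured prevalence (MSI-high patients get an
#' unstable-site score above the FFPE cutoff, others below), and — for
#' designated tumor types — a truncated-Gaussian percent gLOH.
#'
#' @param spec a [cohort_spec()].
#' @return list with `patients` (one row per patient: `patient_id`,
#'   `tumor_type`, `tmb`, `msi_score`, `gloh`) and `alterations`
#'   (`patient_id`, `gene` pairs).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  types <- sample(names(spec$tumor_type_mix), n, replace = TRUE,
                  prob = spec$tumor_type_mix)
  tmb <- stats::rlnorm(n, spec$tmb_meanlog, spec$tmb_sdlog)
  msi_high <- stats::runif(n) < spec$msi_high_prev
  # score placed clear of the 19.5% FFPE cutoff on the proper side
  msi_score <- ifelse(msi_high, stats::runif(n, 0.25, 0.6), stats::runif(n, 0, 0.1))
  gloh <- rep(NA_real_, n)
  gl <- types %in% spec$gloh_tumor_types
  gloh[gl] <- pmax(0, stats::rnorm(sum(gl), spec$gloh_mean, spec$gloh_sd))
  alt <- do.call(rbind, lapply(names(spec$gene_alt_freqs), function(g) {
    hit <- stats::runif(n) < spec$gene_alt_freqs[[g]]
    if (!any(hit)) return(NULL)
    data.frame(patient_id = which(hit), gene = g, stringsAsFactors = FALSE)
  }))
  if (is.null(alt))
    alt <- data.frame(patient_id = integer(), gene = character(),
                      stringsAsFactors = FALSE)
  list(
    patients = data.frame(patient_id = seq_len(n), tumor_type = types,
                          tmb = tmb, msi_score = msi_score, gloh = gloh,
                          stringsAsFactors = FALSE),
    alterations = alt[order(alt$patient_id, alt$gene), , drop = FALSE]
  )
}

#' Specification of a paired tissue/plasma sample
#'
#' Plasma design VAF for each tissue variant is the tissue VAF scaled by the
#' circulating-tumor-DNA fraction; a non-shedding tumor contributes no signal
#' to plasma at all (the clinical situation in treated patients whose tissue
#' alterations are absent from plasma).
#'
#' @param tissue_truth variant-call style truth table with tissue VAFs
#'   (`vaf`) and CNV design copies (`copies`).
#' @param ctdna_fraction fraction of cell-free DNA that is tumor-derived,
#'   in `[0,1]`.
#' @param tissue_depth,plasma_depth target mean depths per compartment.
#' @param shedding does the tumor shed DNA into plasma at all?
#' @param seed master seed.
#' @return a `paired_sample_spec` list.
#' @export
paired_sample_spec <- function(tissue_truth, ctdna_fraction,
                               tissue_depth = 1000, plasma_depth = 2000,
                               shedding = TRUE, seed = 1L) {
  validate_variant_calls(tissue_truth)
  if (ctdna_fraction < 0 || ctdna_fraction > 1)
    stop("ctdna_fraction must lie in [0,1]")
  structure(list(tissue_truth = tissue_truth,
                 ctdna_fraction = ctdna_fraction,
                 tissue_depth = tissue_depth, plasma_depth = plasma_depth,
                 shedding = isTRUE(shedding), seed = as.integer(seed)),
            class = "paired_sample_spec")
}

#' Simulate paired tissue and plasma call sets
#'
#' Tissue calls are generated at tissue VAFs and plasma calls at VAFs diluted
#' by the ctDNA fraction, both through the binomial read-sampling detection
#' model of [simulate_reference_standard()]. Plasma CNV signal shrinks toward
#' the diploid baseline with dilution: observed copies =
#' 2 + (design - 2) * ctdna_fraction + noise.
#'
#' @param spec a [paired_sample_spec()].
#' @param min_alt_reads minimum alternate reads for a call.
#' @param reporting_min_vaf caller-level observed-VAF floor.
#' @return list with `tissue` and `plasma` variant-call `data.frame`s.
#' @export
simulate_paired_tissue_plasma <- function(spec, min_alt_reads = 3L,
                                          reporting_min_vaf = 0) {
  stopifnot(inherits(spec, "paired_sample_spec"))
  truth <- spec$tissue_truth
  tis_spec <- reference_standard_spec("tissue", truth, spec$tissue_depth,
                                      1L, "FFPE", derive_seed(spec$seed, 1L))
  tissue <- simulate_reference_standard(tis_spec, min_alt_reads,
                                        reporting_min_vaf)$replicates[[1]]
  dil <- if (spec$shedding) spec$ctdna_fraction else 0
  pl_truth <- truth
  pl_truth$vaf <- truth$vaf * dil
  is_cnv <- truth$kind == "CNV"
  pl_truth$copies[is_cnv] <- 2 + (truth$copies[is_cnv] - 2) * dil
  pl_spec <- reference_standard_spec("plasma", pl_truth, spec$plasma_depth,
                                     1L, "PLASMA", derive_seed(spec$seed, 2L))
  plasma <- simulate_reference_standard(pl_spec, min_alt_reads,
                                        reporting_min_vaf)$replicates[[1]]
  # no circulating tumor DNA: no tumor-derived plasma signal of any kind
  if (!spec$shedding) plasma <- plasma[0, , drop = FALSE]
  list(tissue = tissue, plasma = plasma)
}

#' Simulate a SNP BAF/logR profile under an allele-specific copy-number model
#'
#' Heterozygous population SNPs are placed uniformly within each segment at
#' the requested density. For tumor purity rho and allele-specific copies
#' (nA, nB) on a segment, the expected B-allele frequency is
#' `(1 - rho + rho * nB) / (2 (1 - rho) + rho (nA + nB))` (allele phase is
#' randomized per SNP, i.e. `b` or `1 - b`), and the expected log2 ratio is
#' `log2((2 (1 - rho) + rho (nA + nB)) / (2 (1 - rho) + rho * psi))` where
#' psi is the tumor genome ploidy. Gaussian noise is added to both channels.
#'
#' @param purity tumor purity rho in (0, 1].
#' @param segments `data.frame` with columns `chrom`, `length_bp`, `nA`, `nB`
#'   (non-negative integers, `nA >= nB`); segments are laid end to end within
#'   each chromosome in row order.
#' @param ploidy tumor genome ploidy psi; default is the length-weighted mean
#'   total copy number of `segments`.
#' @param snps_per_mb SNP density (default 3).
#' @param baf_sd,logr_sd Gaussian noise standard deviations.
#' @param seed master seed.
#' @return a `data.frame` (`chrom`, `pos`, `baf`, `logr`) with attributes
#'   `chrom_lengths` (named bp per chromosome) and `truth` (the segment table
#'   with start/end coordinates added).
#' @export
simulate_snp_profile <- function(purity, segments, ploidy = NULL,
                                 snps_per_mb = 3, baf_sd = 0.02,
                                 logr_sd = 0.05, seed = 1L) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0,1]")
  stopifnot(all(c("chrom", "length_bp", "nA", "nB") %in% names(segments)))
  if (any(segments$nA < 0 | segments$nB < 0 | segments$nB > segments$nA))
    stop("allele-specific copies must satisfy nA >= nB >= 0")
  if (nrow(segments) == 0L) stop("zero-length profile")
  if (is.null(ploidy))
    ploidy <- sum((segments$nA + segments$nB) * segments$length_bp) /
      sum(segments$length_bp)
  set.seed(as.integer(seed))
  segs <- segments
  segs$start <- NA_real_; segs$end <- NA_real_
  for (ch in unique(segs$chrom)) {
    i <- which(segs$chrom == ch)
    ends <- cumsum(segs$length_bp[i])
    segs$start[i] <- c(0, ends[-length(ends)])
    segs$end[i] <- ends
  }
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    nsnp <- max(2L, round(segs$length_bp[i] / 1e6 * snps_per_mb))
    pos <- sort(stats::runif(nsnp, segs$start[i], segs$end[i]))
    nA <- segs$nA[i]; nB <- segs$nB[i]
    denom <- 2 * (1 - purity) + purity * (nA + nB)
    b <- (1 - purity + purity * nB) / denom
    phase <- stats::runif(nsnp) < 0.5
    baf <- ifelse(phase, b, 1 - b) + stats::rnorm(nsnp, 0, baf_sd)
    logr <- log2(denom / (2 * (1 - purity) + purity * ploidy)) +
      stats::rnorm(nsnp, 0, logr_sd)
    data.frame(chrom = segs$chrom[i], pos = pos,
               baf = pmin(1, pmax(0, baf)), logr = logr,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof <- prof[order(prof$chrom, prof$pos), , drop = FALSE]
  rownames(prof) <- NULL
  chrom_lengths <- tapply(segs$end, segs$chrom, max)
  structure(prof,
            chrom_lengths = chrom_lengths[unique(prof$chrom)],
            truth = segs, purity = purity, ploidy = ploidy)
}

#' Simulate a microsatellite site-instability table
#'
#' Produces a site table with exactly `round(n_sites * unstable_fraction)`
#' unstable sites (which sites are unstable is randomized under the seed).
#'
#' @param n_sites number of interrogated microsatellite sites (> 0).
#' @param unstable_fraction fraction of unstable sites in `[0,1]`.
#' @param seed master seed.
#' @return `data.frame` with `site_id` and logical `unstable`.
#' @export
simulate_msi_sites <- function(n_sites, unstable_fraction, seed = 1L) {
  if (n_sites <= 0) stop("n_sites must be > 0")
  if (unstable_fraction < 0 || unstable_fraction > 1)
    stop("unstable_fraction must lie in [0,1]")
  set.seed(as.integer(seed))
  k <- round(n_sites * unstable_fraction)
  unstable <- rep(FALSE, n_sites)
  unstable[sample.int(n_sites, k)] <- TRUE
  data.frame(site_id = sprintf("MS%04d", seq_len(n_sites)),
             unstable = unstable, stringsAsFactors = FALSE)
}
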