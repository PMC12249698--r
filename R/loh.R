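#' Fold B-allele frequencies about 0.5
#'
#' Allele phase is arbitrary, so allele-specific callers consume the mirrored
#' BAF: `0.5 + |baf - 0.5|`, always in `[0.5, 1]`.
#' @param baf numeric BAF values in `[0,1]`.
#' @return folded BAF values.
#' @export
fold_baf <- function(baf) 0.5 + abs(baf - 0.5)

# Robust per-channel noise scale from successive differences; floored so that
# noise-free profiles do not divide by zero.
#' @keywords internal
diff_sd <- function(x) {
  if (length(x) < 3) return(1e-4)
  max(stats::median(abs(diff(x))) / (sqrt(2) * 0.6745), 1e-4)
}

# Exact penalized least-squares change-point partition of one chromosome.
# Joint L2 cost on the two standardized channels; O(n^2) dynamic program
# with the inner minimization vectorized over candidate split points.
#' @keywords internal
changepoint_partition <- function(y1, y2, beta) {
  n <- length(y1)
  s1 <- c(0, cumsum(y1)); q1 <- c(0, cumsum(y1^2))
  s2 <- c(0, cumsum(y2)); q2 <- c(0, cumsum(y2^2))
  v1 <- diff_sd(y1)^2; v2 <- diff_sd(y2)^2
  seg_cost <- function(i, j) {
    # cost of segment (i+1)..j for vector i, scalar j
    m <- j - i
    c1 <- (q1[j + 1] - q1[i + 1]) - (s1[j + 1] - s1[i + 1])^2 / m
    c2 <- (q2[j + 1] - q2[i + 1]) - (s2[j + 1] - s2[i + 1])^2 / m
    c1 / v1 + c2 / v2
  }
  f <- c(-beta, rep(Inf, n))
  back <- integer(n)
  for (j in seq_len(n)) {
    cand <- f[seq_len(j)] + seg_cost(0:(j - 1), j) + beta
    back[j] <- which.min(cand) - 1L
    f[j + 1] <- cand[back[j] + 1L]
  }
  ends <- integer(0); j <- n
  while (j > 0) { ends <- c(j, ends); j <- back[j] }
  ends
}

#' Segment a SNP profile into regions of constant allelic state
#'
#' Per chromosome, fits a piecewise-constant model jointly to the folded BAF
#' and logR channels by exact penalized least-squares change-point detection
#' (both channels standardized by a robust noise estimate). Segment
#' boundaries are placed at midpoints between flanking SNPs so the segments
#' tile each chromosome.
#'
#' @param profile SNP profile `data.frame` (`chrom`, `pos`, `baf`, `logr`),
#'   positions strictly increasing within chromosome; an optional
#'   `chrom_lengths` attribute (named bp) fixes chromosome ends.
#' @param penalty change-point penalty; default `10 * log(n)` per chromosome.
#' @param min_snps minimum SNPs required per chromosome (default 10).
#' @return `data.frame` of segments (`chrom`, `start`, `end` half-open bp,
#'   `n_snps`, `mean_baf` folded, `mean_logr`) with the `chrom_lengths`
#'   attribute propagated.
#' @export
segment_profile <- function(profile, penalty = NULL, min_snps = 10L) {
  stopifnot(all(c("chrom", "pos", "baf", "logr") %in% names(profile)))
  chroms <- unique(profile$chrom)
  lens <- attr(profile, "chrom_lengths")
  out <- lapply(chroms, function(ch) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    if (is.unsorted(p$pos, strictly = TRUE))
      stop("profile positions must be strictly increasing within ", ch)
    n <- nrow(p)
    if (n < min_snps) stop("fewer than ", min_snps, " SNPs on ", ch)
    beta <- if (is.null(penalty)) 10 * log(n) else penalty
    fb <- fold_baf(p$baf)
    ends <- changepoint_partition(fb, p$logr, beta)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    chrom_end <- if (!is.null(lens) && ch %in% names(lens)) lens[[ch]]
                 else max(p$pos)
    # bp boundaries: midpoints between the SNPs flanking each breakpoint
    bp_start <- c(0, (p$pos[utils::head(ends, -1)] +
                        p$pos[utils::head(ends, -1) + 1L]) / 2)
    bp_end <- c(utils::tail(bp_start, -1), chrom_end)
    data.frame(
      chrom = ch, start = bp_start, end = bp_end,
      n_snps = ends - starts + 1L,
      mean_baf = vapply(seq_along(ends), function(k)
        mean(fb[starts[k]:ends[k]]), numeric(1)),
      mean_logr = vapply(seq_along(ends), function(k)
        mean(p$logr[starts[k]:ends[k]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  if (is.null(lens)) {
    lens <- tapply(segs$end, segs$chrom, max)
    lens <- lens[unique(segs$chrom)]
  }
  structure(segs, chrom_lengths = lens)
}

# Invert the BAF/logR model at (rho, psi): continuous total and minor copy
# numbers per segment. mean_baf is folded, so the minor-allele fraction is
# 1 - mean_baf.
#' @keywords internal
invert_ascn <- function(mean_baf, mean_logr, rho, psi) {
  base <- 2 * (1 - rho)
  n_total <- ((base + rho * psi) * 2^mean_logr - base) / rho
  b_minor <- 1 - mean_baf
  n_b <- (b_minor * (base + rho * n_total) - (1 - rho)) / rho
  list(n_total = n_total, n_a = n_total - n_b, n_b = n_b)
}

#' Fit tumor purity and ploidy by grid search
#'
#' For every (purity, ploidy) grid point the segment means are inverted to
#' continuous allele-specific copy numbers; the goodness of fit is the
#' length-weighted squared distance of (nA, nB) to the nearest non-negative
#' integers. Tumor-only BAF/logR data carry an exact degeneracy: for purity
#' rho < 0.5 the solution at purity rho/(1 - rho) with every allele copy
#' number incremented (and correspondingly higher ploidy) reproduces the
#' segment means perfectly, so family members differ in goodness only by
#' noise — proportionally, not absolutely. Among near-equivalent optima
#' (goodness within a factor `1 + tie_tol` of the minimum, which collapses
#' to exact ties on noise-free data) the fit therefore prefers the lowest
#' ploidy
#' — the standard parsimony resolution of the copy-number-shift family —
#' and, at equal ploidy, the highest purity. Profiles in which every
#' segment is allelically balanced with a flat logR are flagged
#' non-identifiable (many grid points fit them equally well).
#'
#' @param segments segment table from [segment_profile()] (needs `mean_baf`,
#'   `mean_logr`, `start`, `end`; at least 3 segments).
#' @param rho_grid purity grid (default 0.10 to 1.00 by 0.01).
#' @param psi_grid ploidy grid (default 1.50 to 5.00 by 0.05).
#' @param tie_tol relative goodness band within which solutions count as
#'   equivalent optima (default 1: up to twice the minimum).
#' @return list with `purity`, `ploidy`, `goodness`, `non_identifiable`, and
#'   the searched `grid` extents.
#' @export
fit_purity_ploidy <- function(segments,
                              rho_grid = seq(0.10, 1.00, by = 0.01),
                              psi_grid = seq(1.50, 5.00, by = 0.05),
                              tie_tol = 1) {
  if (nrow(segments) < 3) stop("need at least 3 segments to fit purity/ploidy")
  w <- (segments$end - segments$start)
  w <- w / sum(w)
  grid <- expand.grid(rho = rho_grid, psi = psi_grid)
  goodness <- vapply(seq_len(nrow(grid)), function(k) {
    inv <- invert_ascn(segments$mean_baf, segments$mean_logr,
                       grid$rho[k], grid$psi[k])
    na_i <- pmax(0, round(inv$n_a)); nb_i <- pmax(0, round(inv$n_b))
    sum(w * ((inv$n_a - na_i)^2 + (inv$n_b - nb_i)^2))
  }, numeric(1))
  best <- which(goodness <= min(goodness) * (1 + tie_tol) + 1e-9)
  cand <- grid[best, , drop = FALSE]
  cand$goodness <- goodness[best]
  cand <- cand[order(cand$psi, -cand$rho), , drop = FALSE]
  non_id <- all(segments$mean_baf < 0.53) &&
    diff(range(segments$mean_logr)) < 0.05
  list(purity = cand$rho[1], ploidy = cand$psi[1],
       goodness = cand$goodness[1], non_identifiable = non_id,
       grid = list(rho = range(rho_grid), psi = range(psi_grid)))
}

#' Call allele-specific copy number and LOH per segment
#'
#' Rounds the model inversion at the fitted purity/ploidy to integer
#' (nA, nB). A segment is LOH iff its minor copy number is zero while at
#' least one major copy remains; homozygous deletion (0,0) is not LOH.
#'
#' @param segments segment table from [segment_profile()].
#' @param fit a [fit_purity_ploidy()] result.
#' @param whole_chrom_fraction fraction of a chromosome a segment must span
#'   to be marked whole-chromosome (default 0.9).
#' @return the segment table with `nA`, `nB`, `is_loh`,
#'   `spans_whole_chromosome` columns added.
#' @export
call_ascn <- function(segments, fit, whole_chrom_fraction = 0.9) {
  inv <- invert_ascn(segments$mean_baf, segments$mean_logr,
                     fit$purity, fit$ploidy)
  nb <- pmax(0, round(inv$n_b))
  na_ <- pmax(nb, pmax(0, round(inv$n_a)))
  segs <- segments
  segs$nA <- as.integer(na_)
  segs$nB <- as.integer(nb)
  segs$is_loh <- segs$nB == 0L & segs$nA >= 1L
  lens <- attr(segments, "chrom_lengths")
  if (is.null(lens)) lens <- tapply(segments$end, segments$chrom, max)
  segs$spans_whole_chromosome <-
    (segs$end - segs$start) >= whole_chrom_fraction * as.numeric(lens[segs$chrom])
  structure(segs, chrom_lengths = lens)
}

#' Sample-level percent LOH
#'
#' Aggregates segment-level LOH to the genome-wide percent of the eligible
#' genome in LOH. Sex chromosomes are excluded (the model assumes two
#' germline alleles). Whole-chromosome LOH events — segments spanning at
#' least `whole_chrom_fraction` of their chromosome — are by default excluded
#' from both numerator and denominator, following genome-wide LOH score
#' conventions that treat whole-chromosome loss as a distinct mechanism.
#'
#' @param ascn segment table from [call_ascn()].
#' @param exclude_whole_chromosome drop whole-chromosome LOH events
#'   (default `TRUE`).
#' @param whole_chrom_fraction span fraction defining "whole chromosome".
#' @param high_gloh_cutoff percent gLOH at or above which the sample is
#'   flagged high-gLOH (default 16).
#' @param sex_chroms chromosome names excluded from the computation.
#' @return list with `sample_percent_loh`, `high_gloh`,
#'   `excluded_whole_chromosome_bp`, `eligible_bp`, `loh_bp`.
#' @export
sample_percent_loh <- function(ascn, exclude_whole_chromosome = TRUE,
                               whole_chrom_fraction = 0.9,
                               high_gloh_cutoff = 16,
                               sex_chroms = c("chrX", "chrY", "X", "Y")) {
  segs <- ascn[!ascn$chrom %in% sex_chroms, , drop = FALSE]
  len <- segs$end - segs$start
  whole_loh <- segs$is_loh &
    (segs$end - segs$start) >= whole_chrom_fraction *
      as.numeric(attr(ascn, "chrom_lengths")[segs$chrom])
  excluded <- exclude_whole_chromosome & whole_loh
  eligible <- !excluded
  if (sum(len[eligible]) <= 0) stop("zero eligible genome length")
  loh_bp <- sum(len[eligible & segs$is_loh])
  pct <- 100 * loh_bp / sum(len[eligible])
  list(sample_percent_loh = pct,
       high_gloh = pct >= high_gloh_cutoff,
       excluded_whole_chromosome_bp = sum(len[excluded]),
       eligible_bp = sum(len[eligible]),
       loh_bp = loh_bp)
}

#' Intersect LOH segments with gene intervals
#'
#' A gene is flagged LOH iff some LOH segment overlaps at least
#' `min_overlap_fraction` of the gene interval (default: any overlap of at
#' least 1 bp).
#'
#' @param ascn segment table from [call_ascn()] (half-open bp coordinates).
#' @param genes `data.frame` with `chrom`, `start`, `end` (half-open bp, as
#'   read from BED by [read_bed()]) and `gene` columns.
#' @param min_overlap_fraction minimum overlapped fraction of the gene.
#' @return `genes` with a logical `loh` column added.
#' @export
gene_loh_intersect <- function(ascn, genes, min_overlap_fraction = 0) {
  if (any(genes$end <= genes$start)) stop("malformed gene interval(s)")
  loh <- ascn[ascn$is_loh, , drop = FALSE]
  genes$loh <- FALSE
  if (nrow(loh) == 0L || nrow(genes) == 0L) return(genes)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
  s_gr <- GenomicRanges::GRanges(loh$chrom,
                                 IRanges::IRanges(floor(loh$start) + 1,
                                                  ceiling(loh$end)))
  hits <- GenomicRanges::findOverlaps(g_gr, s_gr)
  if (length(hits) == 0L) return(genes)
  ov <- GenomicRanges::pintersect(g_gr[S4Vectors::queryHits(hits)],
                                  s_gr[S4Vectors::subjectHits(hits)])
  need <- pmax(1, min_overlap_fraction *
                 (genes$end - genes$start)[S4Vectors::queryHits(hits)])
  ok <- unique(S4Vectors::queryHits(hits)[GenomicRanges::width(ov) >= need])
  genes$loh[ok] <- TRUE
  genes
}

#' Run the full LOH pipeline on a SNP profile
#'
#' Convenience wrapper: segmentation, purity/ploidy fit, allele-specific
#' copy-number calls, and sample-level percent LOH.
#'
#' @param profile SNP profile (see [segment_profile()]).
#' @param genes optional gene interval table for per-gene LOH flags.
#' @param ... passed to [sample_percent_loh()].
#' @return list with `segments`, `fit`, `ascn`, `loh` and (optionally)
#'   `gene_loh`.
#' @export
loh_pipeline <- function(profile, genes = NULL, ...) {
  segs <- segment_profile(profile)
  fit <- fit_purity_ploidy(segs)
  ascn <- call_ascn(segs, fit)
  res <- list(segments = segs, fit = fit, ascn = ascn,
              loh = sample_percent_loh(ascn, ...))
  if (!is.null(genes)) res$gene_loh <- gene_loh_intersect(ascn, genes)
  res
}
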