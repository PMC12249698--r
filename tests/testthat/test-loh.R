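test_that("noise-free segmentation recovers change points exactly", {
  segs <- data.frame(chrom = "chr1", length_bp = c(30e6, 30e6),
                     nA = c(1, 2), nB = c(1, 0))
  prof <- simulate_snp_profile(0.6, segs, snps_per_mb = 2, baf_sd = 0,
                               logr_sd = 0, seed = 13)
  fit <- segment_profile(prof)
  expect_equal(nrow(fit), 2)
  # breakpoint within one SNP spacing (~0.5 Mb at 2 SNPs/Mb) of 30 Mb
  expect_lt(abs(fit$end[1] - 30e6), 1e6)

  # homogeneous chromosome: a single segment
  flat <- simulate_snp_profile(0.6, data.frame(chrom = "chr1",
                                               length_bp = 60e6, nA = 1, nB = 1),
                               snps_per_mb = 2, baf_sd = 0.02, logr_sd = 0.05,
                               seed = 14)
  expect_equal(nrow(segment_profile(flat)), 1)

  unsorted <- prof[rev(seq_len(nrow(prof))), ]
  expect_error(segment_profile(unsorted), "strictly increasing")
  expect_error(segment_profile(prof[1:5, ]), "fewer than")
})

test_that("three-segment profiles are recovered in at least 95% of seeded runs", {
  segs <- data.frame(chrom = "chr1", length_bp = c(40e6, 30e6, 30e6),
                     nA = c(1, 2, 2), nB = c(1, 0, 1))
  hits <- vapply(1:200, function(s) {
    prof <- simulate_snp_profile(0.6, segs, snps_per_mb = 3, baf_sd = 0.02,
                                 logr_sd = 0.05, seed = s)
    nrow(segment_profile(prof)) == 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("purity and ploidy are recovered on the grid", {
  prof <- simulate_snp_profile(0.6, three_state_genome(), snps_per_mb = 3,
                               seed = 41)
  fit <- fit_purity_ploidy(segment_profile(prof))
  expect_lt(abs(fit$purity - 0.6), 0.05 + 1e-9)
  expect_lt(abs(fit$ploidy - 2.3), 0.1 + 1e-9)

  # pure noise-free diploid fits (1.0, 2.0) exactly and is flagged
  dp <- do.call(rbind, lapply(1:3, function(ch) data.frame(
    chrom = paste0("chr", ch), length_bp = 80e6, nA = 1, nB = 1)))
  pr <- simulate_snp_profile(1, dp, ploidy = 2, baf_sd = 0, logr_sd = 0,
                             seed = 2)
  f <- fit_purity_ploidy(segment_profile(pr))
  expect_equal(f$purity, 1.0)
  expect_equal(f$ploidy, 2.0)
  expect_true(f$non_identifiable)
  expect_error(fit_purity_ploidy(segment_profile(pr)[1:2, ]), "3 segments")
})

test_that("equivalent optima at the same ploidy resolve toward higher purity", {
  # a (1,1)+(2,2) genome at logR reference psi=2 is fit exactly by every
  # purity (nT = psi family): the reported solution takes the highest purity
  segs <- data.frame(chrom = "chr1", start = c(0, 50e6), end = c(50e6, 100e6),
                     n_snps = c(100L, 100L),
                     mean_baf = 0.5, mean_logr = c(0, 1))
  attr(segs, "chrom_lengths") <- c(chr1 = 100e6)
  f <- fit_purity_ploidy(rbind(segs, segs[2, ]))
  expect_equal(f$purity, 1.0)
})

test_that("allele-specific copy-number calls define LOH correctly", {
  rho <- 0.6; psi <- 2
  exp_seg <- function(nA, nB) {
    denom <- 2 * (1 - rho) + rho * (nA + nB)
    data.frame(mean_baf = fold_baf((1 - rho + rho * nB) / denom),
               mean_logr = log2(denom / (2 * (1 - rho) + rho * psi)))
  }
  segs <- cbind(chrom = "chr1", start = c(0, 40e6, 80e6),
                end = c(40e6, 80e6, 120e6), n_snps = 100L,
                rbind(exp_seg(2, 0), exp_seg(1, 1), exp_seg(0, 0)))
  attr(segs, "chrom_lengths") <- c(chr1 = 120e6)
  fit <- list(purity = rho, ploidy = psi)
  asc <- call_ascn(segs, fit)
  expect_equal(asc$nA, c(2L, 1L, 0L))
  expect_equal(asc$nB, c(0L, 1L, 0L))
  expect_equal(asc$is_loh, c(TRUE, FALSE, FALSE))  # homozygous deletion is not LOH
})

test_that("sample %LOH aggregates segment lengths with whole-chromosome exclusion", {
  mk <- function(chrom, start, end, loh, lens) {
    df <- data.frame(chrom = chrom, start = start, end = end,
                     nA = ifelse(loh, 2L, 1L), nB = ifelse(loh, 0L, 1L),
                     is_loh = loh)
    attr(df, "chrom_lengths") <- lens
    df
  }
  asc <- mk("chr1", c(0, 30e6), c(30e6, 100e6), c(TRUE, FALSE),
            c(chr1 = 100e6))
  expect_equal(sample_percent_loh(asc)$sample_percent_loh, 30)

  # LOH spanning 95% of chr2 drops out of numerator and denominator
  asc2 <- mk(c("chr1", "chr1", "chr2"), c(0, 30e6, 0), c(30e6, 100e6, 95e6),
             c(TRUE, FALSE, TRUE), c(chr1 = 100e6, chr2 = 100e6))
  r <- sample_percent_loh(asc2)
  expect_equal(r$sample_percent_loh, 30)
  expect_equal(r$excluded_whole_chromosome_bp, 95e6)
  r_off <- sample_percent_loh(asc2, exclude_whole_chromosome = FALSE)
  expect_equal(r_off$sample_percent_loh, 100 * 125e6 / 195e6)

  # no LOH -> 0%; sex chromosomes never contribute
  asc3 <- mk(c("chr1", "chrX"), c(0, 0), c(100e6, 150e6), c(FALSE, TRUE),
             c(chr1 = 100e6, chrX = 155e6))
  expect_equal(sample_percent_loh(asc3)$sample_percent_loh, 0)

  # adding an LOH segment never decreases %LOH
  base <- mk("chr1", c(0, 30e6), c(30e6, 100e6), c(TRUE, FALSE),
             c(chr1 = 100e6, chr2 = 100e6))
  more <- rbind(base, mk("chr2", 0, 40e6, TRUE, NULL)[1, ])
  attr(more, "chrom_lengths") <- c(chr1 = 100e6, chr2 = 100e6)
  expect_gte(sample_percent_loh(more)$sample_percent_loh,
             sample_percent_loh(base)$sample_percent_loh)
})

test_that("gene-level LOH flags come from interval intersection", {
  asc <- data.frame(chrom = "chr1", start = c(0, 50e6), end = c(50e6, 100e6),
                    nA = c(2L, 1L), nB = c(0L, 1L), is_loh = c(TRUE, FALSE))
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr1"),
                      start = c(10e6, 50e6 - 1, 10e6, 60e6),
                      end = c(10.1e6, 50e6 + 1e5, 10.1e6, 60.1e6),
                      gene = c("inside", "straddle", "otherchrom", "outside"))
  flags <- gene_loh_intersect(asc, genes)
  expect_equal(flags$loh, c(TRUE, TRUE, FALSE, FALSE))  # 1 bp overlap suffices
  expect_error(gene_loh_intersect(asc, data.frame(chrom = "chr1", start = 5,
                                                  end = 5, gene = "bad")),
               "malformed")
})

test_that("%LOH is invariant to uniform SNP density", {
  pcts <- vapply(c(2, 6), function(dens) {
    prof <- simulate_snp_profile(0.6, three_state_genome(), snps_per_mb = dens,
                                 seed = 17)
    loh_pipeline(prof)$loh$sample_percent_loh
  }, numeric(1))
  expect_lt(abs(pcts[1] - pcts[2]), 2)
})

test_that("paired noisy gLOH measurements grow more concordant as noise shrinks", {
  truth <- seq(5, 45, length.out = 30)
  rs <- vapply(c(8, 4, 1), function(sd) {
    set.seed(71)
    a <- truth + rnorm(30, 0, sd)
    b <- truth + rnorm(30, 0, sd)
    pearson_concordance(a, b)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[1], 0)
})
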