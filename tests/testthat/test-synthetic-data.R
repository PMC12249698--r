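test_that("reference-standard simulation is deterministic and honors the binomial detection model", {
  spec <- reference_standard_spec("std", standard_truth(0.02), 1000, 3, seed = 11)
  a <- simulate_reference_standard(spec)
  b <- simulate_reference_standard(spec)
  expect_identical(a, b)

  # high-VAF, high-depth tier: every variant detected in every replicate
  # (per-SNV detection probability 1 - pbinom(2, 1000, 0.02) > 0.9999)
  tps <- vapply(a$replicates,
                function(r) match_calls(r, a$truth)$confusion$tp, integer(1))
  expect_equal(tps, rep(nrow(a$truth), 3))

  # empirical detection rate at a marginal tier matches the binomial tail
  # within 3 standard errors
  n_var <- 2000L
  truth <- variant_calls(kind = rep("SNV", n_var), chrom = "chr1",
                         pos = seq_len(n_var) * 10L, ref = "A", alt = "T",
                         vaf = 0.006)
  lo <- simulate_reference_standard(
    reference_standard_spec("lod", truth, 794, 1L, seed = 5))
  rate <- nrow(lo$replicates[[1]]) / n_var
  p <- 1 - pbinom(2, 794, 0.006)             # 0.8548
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n_var))
})

test_that("variants with zero design VAF are never called and bad specs are rejected", {
  truth <- variant_calls(kind = c("SNV", "SNV"), chrom = "chr1",
                         pos = c(10L, 20L), ref = "A", alt = "T",
                         vaf = c(0, 0.5))
  sim <- simulate_reference_standard(
    reference_standard_spec("z", truth, 500, 5, seed = 3))
  for (r in sim$replicates) expect_false(10L %in% r$pos)

  expect_error(reference_standard_spec("bad", truth, -10), "depth_target")
  expect_error(reference_standard_spec("bad", variant_calls(
    kind = "SNV", chrom = "chr1", pos = 1L, ref = "A", alt = "T", vaf = 1.2)))
})

test_that("cohort simulation reproduces configured prevalences and is seed-stable", {
  spec <- cohort_spec(1000, msi_high_prev = 0.0119, seed = 21)
  co <- simulate_cohort(spec)
  expect_identical(co, simulate_cohort(spec))
  expect_equal(nrow(co$patients), 1000)

  # MSI-high count within the binomial 99% interval around 11.9
  n_msi <- sum(co$patients$msi_score >= 0.195)
  expect_gte(n_msi, qbinom(0.005, 1000, 0.0119))
  expect_lte(n_msi, qbinom(0.995, 1000, 0.0119))

  # zero alteration frequencies give an empty alteration table
  none <- simulate_cohort(cohort_spec(50, gene_alt_freqs = c(TP53 = 0),
                                      seed = 1))
  expect_equal(nrow(none$alterations), 0)
  expect_error(cohort_spec(10, tumor_type_mix = numeric()), "non-empty")
})

test_that("plasma detection dilutes with ctDNA fraction and vanishes without shedding", {
  n_var <- 200L
  truth <- variant_calls(kind = rep("SNV", n_var), chrom = "chr1",
                         pos = seq_len(n_var) * 10L, ref = "A", alt = "T",
                         vaf = 0.3)
  rate_at <- function(fr, shed = TRUE) {
    pp <- simulate_paired_tissue_plasma(
      paired_sample_spec(truth, fr, plasma_depth = 2000, shedding = shed,
                         seed = 9))
    nrow(pp$plasma) / n_var
  }
  rates <- vapply(c(1, 0.01, 0.003, 0.001), rate_at, numeric(1))
  expect_true(all(diff(rates) <= 0))        # monotone in dilution
  expect_equal(rate_at(0.5, shed = FALSE), 0)

  # near-clinical dilution: tissue 32.25% VAF to ~0.68% plasma at 2000x
  # should still be detected essentially always
  kras <- variant_calls(kind = "SNV", chrom = "chr12", pos = 25398284L,
                        ref = "G", alt = "T", vaf = 0.3225)
  det <- vapply(1:50, function(s) {
    pp <- simulate_paired_tissue_plasma(
      paired_sample_spec(kras, 0.0211, plasma_depth = 2000, seed = s))
    nrow(pp$plasma) == 1L
  }, logical(1))
  expect_gte(mean(det), 0.95)               # analytic: 0.9999 at VAF 0.0068
  expect_error(paired_sample_spec(kras, 1.5), "ctdna_fraction")
})

test_that("undiluted plasma reproduces tissue VAFs up to sampling error", {
  truth <- variant_calls(kind = rep("SNV", 50), chrom = "chr1",
                         pos = seq_len(50) * 10L, ref = "A", alt = "T",
                         vaf = 0.25)
  pp <- simulate_paired_tissue_plasma(
    paired_sample_spec(truth, 1, plasma_depth = 5000, seed = 4))
  expect_lt(abs(mean(pp$plasma$vaf) - 0.25), 0.01)
})

test_that("SNP profiles follow the allele-specific copy-number closed forms", {
  # pure diploid: BAF 0.5 and logR 0 exactly when noise-free
  dp <- data.frame(chrom = "chr1", length_bp = 50e6, nA = 1, nB = 1)
  pr <- simulate_snp_profile(1, dp, ploidy = 2, baf_sd = 0, logr_sd = 0,
                             seed = 1)
  expect_true(all(pr$baf == 0.5))
  expect_true(all(pr$logr == 0))

  # rho = 0.5, (2,0) against psi = 2: BAF 0.25 or 0.75 by phase, logR 0
  seg <- data.frame(chrom = "chr1", length_bp = 50e6, nA = 2, nB = 0)
  pr2 <- simulate_snp_profile(0.5, seg, ploidy = 2, baf_sd = 0, logr_sd = 0,
                              seed = 2)
  expect_true(all(abs(pr2$baf - 0.25) < 1e-12 | abs(pr2$baf - 0.75) < 1e-12))
  expect_true(all(abs(pr2$logr) < 1e-12))

  # segment means converge to the closed form as noise shrinks
  seg2 <- data.frame(chrom = "chr1", length_bp = 80e6, nA = 2, nB = 1)
  for (sd in c(0.05, 0.005)) {
    p <- simulate_snp_profile(0.6, seg2, ploidy = 3, snps_per_mb = 10,
                              baf_sd = sd, logr_sd = sd, seed = 3)
    b_exp <- (1 - 0.6 + 0.6 * 1) / (2 * 0.4 + 0.6 * 3)  # 0.3846
    expect_lt(abs(mean(fold_baf(p$baf)) - (1 - b_exp)), 0.02 + 2 * sd)
  }
  expect_error(simulate_snp_profile(0, dp), "purity")
  expect_error(simulate_snp_profile(0.5, dp[0, ]), "zero-length")
})

test_that("MSI site tables carry exactly the requested unstable fraction", {
  s <- simulate_msi_sites(200, 0.25, seed = 7)
  expect_equal(sum(s$unstable), 50)
  expect_equal(msi_classify(mean(s$unstable), "FFPE")$status, "MSI-H")

  s0 <- simulate_msi_sites(120, 0, seed = 7)
  expect_equal(sum(s0$unstable), 0)
  expect_equal(msi_classify(0, "FFPE")$status, "MSS")

  # boundary: 19.5% unstable on FFPE classifies MSI-H
  sb <- simulate_msi_sites(200, 0.195, seed = 7)
  expect_equal(msi_classify(mean(sb$unstable), "FFPE")$status, "MSI-H")
  expect_error(simulate_msi_sites(0, 0.5), "n_sites")
})
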