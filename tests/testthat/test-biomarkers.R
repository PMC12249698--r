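mut <- function(n, vaf = 0.2, gene = "GENE", consequence = "missense",
                coding = TRUE, splice_distance = NA_real_,
                driver_class = NA_character_) {
  variant_calls(kind = rep("SNV", n), chrom = "chr1", pos = seq_len(n),
                ref = "A", alt = "T", gene = gene, vaf = vaf,
                consequence = consequence, coding = coding,
                splice_distance = splice_distance,
                driver_class = driver_class)
}

test_that("TMB counts eligible mutations per megabase under the stated filters", {
  pol <- tmb_policy(coding_megabases = 1.5)
  expect_equal(tmb_score(mut(45), pol), 30)          # high-TMB control level
  expect_equal(tmb_score(mut(0), pol), 0)

  # 10 mutations: 3 catalogued drivers and 2 below the 5% VAF floor -> 5
  calls <- rbind(
    mut(3, gene = "TP53", driver_class = "tumor_suppressor_inactivating"),
    mut(2, vaf = 0.04),
    mut(5)
  )
  cat <- data.frame(gene = "TP53", rule = "tumor_suppressor_inactivating")
  pol2 <- tmb_policy(1.5, driver_catalog = cat)
  expect_equal(sum(tmb_eligible(calls, pol2)), 5)

  # VAF floor is strict: exactly 5% is excluded
  expect_equal(sum(tmb_eligible(mut(1, vaf = 0.05), pol)), 0)
  # splice-region mutations within +/-2 bp count even outside coding exons
  spl <- mut(2, coding = FALSE, splice_distance = c(2, 3))
  expect_equal(sum(tmb_eligible(spl, pol)), 1)
  # synonymous calls counted by default, excluded when toggled off
  syn <- mut(4, consequence = "synonymous")
  expect_equal(tmb_score(syn, pol) * pol$coding_megabases, 4)
  pol_ns <- tmb_policy(1.5, include_synonymous = FALSE)
  expect_equal(tmb_score(syn, pol_ns), 0)

  expect_error(tmb_policy(coding_megabases = 1), "exceed 1 Mb")
})

test_that("TMB is invariant when count and footprint scale together", {
  calls <- mut(12)
  s1 <- tmb_score(calls, tmb_policy(1.2))
  s2 <- tmb_score(rbind(calls, mut(12)), tmb_policy(2.4))
  expect_equal(s1, s2)
})

test_that("MSI classification uses the compartment cutoffs inclusively and monotonically", {
  expect_equal(msi_classify(0.195, "FFPE")$status, "MSI-H")
  expect_equal(msi_classify(0.194, "FFPE")$status, "MSS")
  expect_equal(msi_classify(0.18, "PLASMA")$status, "MSI-H")
  expect_equal(msi_classify(0.18, "FFPE")$status, "MSS")

  scores <- seq(0, 1, by = 0.01)
  st <- msi_classify(scores, "FFPE")$status
  expect_true(all(diff(st == "MSI-H") >= 0))   # never flips back to MSS
  expect_error(msi_classify(1.2, "FFPE"), "score")
})

test_that("HRR summary fractions follow patient-level arithmetic", {
  alt <- data.frame(
    patient_id = c(1:50, 51, 51),
    gene = c(rep(c("BRCA1", "BRCA2"), 25), "ATM", "BRCA1"),
    lof = TRUE
  )
  s <- hrr_summary(alt, n_patients = 1345)
  expect_equal(s$fractions[["brca12"]], round_half_up(100 * 51 / 1345, 2))
  expect_equal(s$fractions[["any_hrr_lof"]], round_half_up(100 * 51 / 1345, 2))
  expect_equal(s$fractions[["multiple_hrr"]], round_half_up(100 * 1 / 1345, 2))

  # 50 BRCA carriers out of 1345 print as 3.72%
  s50 <- hrr_summary(alt[1:50, ], n_patients = 1345)
  expect_equal(s50$fractions[["brca12"]], 3.72)

  none <- hrr_summary(data.frame(patient_id = integer(), gene = character(),
                                 lof = logical()), 100)
  expect_true(all(none$fractions == 0))
  expect_error(hrr_summary(alt, 10, hrr_genes = character()), "non-empty")
})

test_that("actionability ordering and roll-up fractions behave as specified", {
  expect_equal(most_actionable(c("none", "resistance", "off_label")), "off_label")
  expect_equal(most_actionable(character(0)), "none")
  expect_error(most_actionable("investigational"), "unknown tier")

  rec <- data.frame(tier = c("off_label", "none", "none"),
                    msi_high = FALSE, tmb_high = c(TRUE, FALSE, FALSE))
  r <- actionability_rollup(rec)
  expect_equal(unname(r$counts["on_label"]), 0L)      # flag never changes the tier table
  expect_equal(r$combined_count, 1L)                  # ... but counts on-label combined
  expect_equal(sum(r$fractions), 100, tolerance = 0.02)

  allnone <- actionability_rollup(data.frame(tier = rep("none", 20),
                                             msi_high = FALSE, tmb_high = FALSE))
  expect_equal(allnone$combined_on_label, 0)
  expect_error(actionability_rollup(data.frame(tier = "tier4")), "unknown tier")
})

test_that("combined on-label uplift never falls below the targeted-only fraction", {
  set.seed(31)
  for (i in 1:10) {
    n <- 200
    rec <- data.frame(
      tier = sample(c("on_label", "off_label", "resistance", "none"), n, TRUE),
      msi_high = runif(n) < 0.05, tmb_high = runif(n) < 0.1)
    r <- actionability_rollup(rec)
    expect_gte(r$combined_on_label, r$fractions[["on_label"]])
  }
})
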