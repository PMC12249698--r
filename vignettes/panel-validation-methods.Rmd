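---
title: "Methods: validation statistics and biomarker models in panelval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validation statistics and biomarker models in panelval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

`panelval` re-implements, as tested and reusable code, the computations
behind the analytical and clinical validation of a 1021-gene hybrid-capture
tumor profiling assay run on FFPE tissue and on plasma cell-free DNA. This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions taken where the underlying procedures left choices
open.

## The detection model

The package does not simulate reads. Variant detection is modeled at the
summary level: for a variant with design allele fraction $f$ sequenced to a
target depth $d$, the total depth is drawn $D \sim \mathrm{Poisson}(d)$ and
the alternate-read count $K \sim \mathrm{Binomial}(D, f)$. A variant is
*called* iff $K \ge k_{\min}$ (default $k_{\min} = 3$ alternate reads) and
the observed fraction $K/D$ clears a caller-level reporting floor (default
0). The analytic detection probability at nominal depth is therefore the
binomial tail $1 - F_{\mathrm{Binom}}(k_{\min} - 1;\, d, f)$, and every
simulation-based check in the test suite is validated against that closed
form. Poisson depth captures run-to-run mean-depth variation (the validated
tiers span roughly 560x to 2000x) without modeling flow cells.

Reporting thresholds are applied *downstream* of the caller by
`apply_positivity()`, deliberately as a separate stage: the assay's
reporting rule (SNV/indel/SV at VAF $\ge$ 1%, CNV at $\ge$ 3.0 copies in
tissue and $\ge$ 2.2 in plasma) is a clinical positivity policy, while the
$k_{\min}$ gate is a property of the caller. Keeping them separate lets the
limit-of-detection analyses study the caller itself, and lets the 1%
reporting rule be toggled without touching the detection model. Because the
assay validates a 0.5% plasma tier and reports plasma findings down to that
range, the default `positivity_policy()` sets the plasma SNV/indel floor at
0.005; the literal 1%-everywhere rule is available as the `"vaf_1pct"`
preset.

CNV observations are modeled as design copy number plus Gaussian noise
(sd 0.15 copies in tissue, 0.3 in plasma) — arbitrary but fixed values,
small relative to the 3.0/2.2 reporting cutoffs. Fusions are treated like
SNVs with a supporting-read fraction.

## Reference standards, cohorts, and paired samples

`simulate_reference_standard()` realizes a named truth set (the bundled
`standard_truth()` builds the 27 SNV/indel + 3 CNV + 6 fusion composition of
the commercial multi-analyte standards) at a design VAF and depth, in
replicates, through the detection model. `simulate_cohort()` draws, per
patient, a tumor type, independent per-gene alteration indicators, a
log-normal TMB, an MSI status at the configured prevalence, and — for
designated tumor types — a truncated-Gaussian percent gLOH. Defaults are
fixed once at the observed study conditions: MSI-high prevalence 1.19%; TMB
$\log$-normal with meanlog $\log 3.5$ and sdlog 0.8, putting roughly 9–10%
of patients above the 10 muts/Mb immunotherapy threshold, as seen in
solid-tumor referral mixes; ovarian gLOH Gaussian(16.3, 8) truncated at
zero, putting about half of ovarian cases above a 16% cutoff.

`simulate_paired_tissue_plasma()` scales each tissue VAF by the ctDNA
fraction to obtain the plasma design VAF and pushes both compartments
through the same detection model; a non-shedding tumor (the clinical
situation of treated patients whose tissue alterations are absent from
plasma) contributes no plasma signal of any kind. Plasma CNV signal shrinks
toward the diploid baseline as $2 + (c - 2) \cdot f_{\mathrm{ctDNA}}$.

What the generator does *not* emulate: read-level artifacts (deamination,
UMI consensus errors), clonal hematopoiesis interference, germline
contamination, panel-specific capture bias, and correlated co-mutation
structure. Tests passing on this generator therefore demonstrate that the
downstream arithmetic and algorithms are correct under the stated
statistical model — not that the wet assay achieves these numbers on real
specimens.

## Matching and agreement statistics

Calls match truth on left-aligned (chrom, pos, ref, alt) for SNVs/indels
(left alignment removes VCF dialect differences in indel anchoring), on the
gene symbol for CNVs, and on the *unordered* gene pair for fusions
(breakpoints are carried but not required — fusion callers disagree on
partner order far more often than on partners). Each truth variant matches
at most once. Specificity needs a negative universe: reference standards may
declare interrogated wild-type positions, and `tn` is otherwise `NA`
(undefined, never silently 0).

Rates are plain confusion-matrix arithmetic; PPA/NPA are
sensitivity/specificity computed against an orthogonal method treated as
truth. Confidence intervals are exact Clopper–Pearson from beta quantiles,
with the closed-form edge cases $x = n \Rightarrow$ lower bound
$(\alpha/2)^{1/n}$ and $x = 0 \Rightarrow$ upper bound
$1 - (\alpha/2)^{1/n}$. Pearson concordance uses the product-moment
estimator with a two-sided $t$-test on $n - 2$ degrees of freedom, reported
as `"<1e-05"` below that threshold. Display rounding is half-up at two
decimals (clinical-report convention), except MSI specificity, reported at
integer precision.

One tally deserves note: the bundled per-tier reference-standard table
carries the designed truth-set size per tier (40 variants for the
low-frequency tiers) and derives false negatives as `truth_n - tp`, because
the alternative — reading the false-negative column at face value — is
internally inconsistent with the tier percentages it sits next to. The
derived arithmetic (97.50%, 92.5%, 85%) is the self-consistent reading.

## TMB, MSI, HRR, actionability

The TMB score counts somatic SNVs and indels — synonymous included by
default — in the coding footprint or within ±2 bp of a splice junction,
keeps only mutations with VAF strictly above 5%, removes catalogued driver
mutations (tumor-suppressor inactivating, driver-sensitive,
driver-high-frequency; the catalog is an input table, never inferred), and
divides by the coding footprint in Mb, which must exceed 1 Mb. The VAF
filter is global and unconditional: no sample-quality-dependent adjustment
is applied, the simplest faithful reading of the underlying rule, and the
choice is isolated in `tmb_policy()` should a conditional variant ever be
needed. TMB-high uses strictly greater than 10 muts/Mb.

MSI classification thresholds the fraction of unstable microsatellite sites
at $\ge$ 19.5% (FFPE) and $\ge$ 18% (plasma), inclusive. Site instability
arrives precomputed; calling instability from read-length distributions is
out of scope.

Actionability tiers (`on_label` > `off_label` > `resistance` > `none`) are
consumed as annotations; a patient's tier is the maximum over their
variants. The combined roll-up additionally counts MSI-high or TMB-high
patients as on-label (site-agnostic immunotherapy markers), so the combined
on-label fraction can only exceed the targeted-only fraction.

## The LOH pipeline

SNP profiles carry per-SNP BAF and logR. Under tumor purity $\rho$ and
segment allele copies $(n_A, n_B)$ with tumor ploidy $\psi$:

$$ b = \frac{1 - \rho + \rho\, n_B}{2(1 - \rho) + \rho (n_A + n_B)}, \qquad
   r = \log_2 \frac{2(1 - \rho) + \rho (n_A + n_B)}{2(1 - \rho) + \rho\,\psi}. $$

Phase is arbitrary, so fitting consumes the folded BAF
$0.5 + |b - 0.5|$.

**Segmentation.** No specific segmentation algorithm is prescribed by the
modeled pipeline, so the package uses exact penalized least-squares
change-point detection, jointly on the folded-BAF and logR channels, each
standardized by a robust noise estimate (median absolute successive
difference). The penalty defaults to $10 \log n$ per chromosome — well
above the $\sim 4 \log n$ BIC scale of chance fluctuations, yet orders of
magnitude below the cost reduction of a true copy-number jump at the noise
levels of interest (a (1,1) to (2,0) transition at $\rho = 0.6$ moves folded
BAF by 15 noise standard deviations at the default BAF sd of 0.02). The
noise floor is clamped at $10^{-4}$ so noise-free profiles segment exactly.
Chromosomes need at least 10 SNPs; positions must be strictly increasing.

**Purity/ploidy.** A grid search ($\rho$ from 0.10 to 1.00 by 0.01, $\psi$
from 1.5 to 5.0 by 0.05) inverts the two closed forms per segment to
continuous $(n_A, n_B)$ and scores each grid point by the length-weighted
squared distance to the nearest non-negative integers. Tumor-only BAF/logR
carries an exact degeneracy: for $\rho < 0.5$, the parameter set
$\rho' = \rho/(1-\rho)$ with every allele copy number incremented (and a
correspondingly higher $\psi'$) reproduces all segment means *perfectly*.
Members of this family differ in goodness only through noise, i.e.
proportionally. The fit therefore collects all grid points within a factor
2 of the minimum goodness and prefers the lowest ploidy among them, then
the highest purity — the standard parsimony resolution of the copy-number
shift/doubling family, and the choice that makes low-purity samples
recoverable at all. On noise-free data the band collapses to exact ties, so
a pure diploid fits $(1.0, 2.0)$ exactly; all-balanced flat profiles are
additionally flagged non-identifiable.

**LOH calls and %LOH.** Integer $(n_A, n_B)$ come from rounding the
inversion at the fitted parameters. A segment is LOH iff $n_B = 0$ and
$n_A \ge 1$ — homozygous deletion is not LOH. Sample %LOH is the LOH
fraction of the eligible genome length; sex chromosomes are excluded (the
model assumes two germline alleles), and LOH segments spanning $\ge$ 90% of
their chromosome are excluded from numerator *and* denominator by default,
following the genome-wide LOH score conventions that treat whole-chromosome
loss as a distinct mechanism. The high-gLOH flag defaults to a 16% cutoff;
the cutoff behind the assay's own "elevated gLOH" category is not stated
anywhere in the material this package models, so 16% — the value
established for the ovarian PARP-inhibitor setting — is used and is
configurable.

## Problem sizes and numerical checks

The simulation studies run at sizes chosen to keep every property tight but
cheap: the segmentation recovery study uses 200 single-chromosome seeded
runs; the end-to-end gLOH recovery uses 100 tumors over a 10-autosome,
1-Gb synthetic genome (3 SNPs/Mb, BAF sd 0.02, logR sd 0.05, purities 0.4 /
0.6 / 0.8, 20% of the genome in copy-neutral LOH), asserting purity within
±0.05, ploidy within ±0.1 and %LOH within ±3 points in at least 90% of
runs; Monte-Carlo detection rates use 10,000 draws per VAF/depth tier and
are asserted within 3 standard errors of the binomial tail; the TMB filter
is compared against a record-by-record oracle on 1,000 random call sets.
All randomness flows from explicit integer seeds through a small
multiplicative stream-splitting step (`derive_seed()`), so every run is
reproducible bit for bit.

## Known limitations

* Detection is summary-level; error modes that depend on sequence context
  or read structure are invisible to it.
* The ASCN model has no subclonal states; segments are assumed clonal, and
  GC-wave or replication-timing corrections (array-side preprocessing in
  orthogonal platforms) are out of scope.
* Actionability is annotation-driven; the package contains no
  knowledge-base lookup.
* Cohort-level agreement figures recomputed from the bundled tally tables
  are arithmetic on those tallies: they validate the statistics code, not
  the assay.
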