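# Shared simulation scaffolding for the LOH tests: a compact synthetic
# genome of 10 autosomes, each carrying a balanced diploid block, a
# copy-neutral LOH block and a single-copy gain, so that 20% of the genome
# is in (2,0) LOH and the length-weighted tumor ploidy is 2.3.
three_state_genome <- function(n_chrom = 10) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ch) data.frame(
    chrom = paste0("chr", ch),
    length_bp = c(50e6, 20e6, 30e6),
    nA = c(1, 2, 2), nB = c(1, 0, 1),
    stringsAsFactors = FALSE
  )))
}

# A small mixed truth set in the style of the multi-analyte standards.
small_truth <- function(vaf = 0.02, n_snv = 5L) {
  standard_truth(vaf, n_snv = n_snv, n_cnv = 1L, n_fusion = 1L)
}
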