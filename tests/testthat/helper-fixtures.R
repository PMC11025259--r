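# Shared fixture builders: everything is generated in code at test time.

# Two synthetic test chromosomes with simple round geometry.
test_genome <- function() {
  gm <- data.frame(
    chrom = c("chrT1", "chrT2"),
    length = c(200e6, 100e6),
    centromere_start = c(90e6, 45e6),
    centromere_end = c(95e6, 50e6),
    stringsAsFactors = FALSE)
  class(gm) <- c("wex_genome", "data.frame")
  gm
}

mut_row <- function(sample_id = "S1", chrom = "chr1", pos = 1000,
                    ref = "C", alt = "T", gene = "TP53",
                    variant_class = "missense", alt_count = 30,
                    ref_count = 70, context3 = NA_character_,
                    protein_change = NA_character_) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, variant_class = variant_class,
             alt_count = alt_count, ref_count = ref_count,
             context3 = context3, protein_change = protein_change,
             stringsAsFactors = FALSE)
}

seg_fix <- function(sample_id = "S1", chrom = "chrT1", start = 1, end = 10e6,
                    cn_total = 2, cn_minor = 1) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cn_total = cn_total, cn_minor = cn_minor,
             stringsAsFactors = FALSE)
}

sample_row <- function(sample_id = "S1", group = "IBC", subtype = "TN",
                       age = 50, purity = 0.7, ploidy = 2,
                       panel_size_mb = 38) {
  data.frame(sample_id = sample_id, group = group, subtype = subtype,
             age = age, purity = purity, ploidy = ploidy,
             panel_size_mb = panel_size_mb, stringsAsFactors = FALSE)
}

# Preprocess a raw segment data.frame on the test genome (scar tests).
pp <- function(segs, genome = test_genome()) {
  preprocess_segments(as_segments(segs), genome)
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Small simulated cohort shared by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_per_group = c(IBC = 6, nonIBC = 6)),
                                seed = 17)
    cache
  }
})
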