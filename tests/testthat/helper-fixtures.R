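# Small in-code fixtures shared across test files.

make_calls <- function(dyads, chrom = "chr1", occupancy = 1,
                       fuzziness = 20) {
  data.frame(chrom = chrom, dyad = as.integer(dyads),
             n_reads = 10L, occupancy = occupancy, fuzziness = fuzziness,
             stringsAsFactors = FALSE)
}

make_reads <- function(chrom, start, end, strand = "+") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# one-chromosome plan with hand-set nucleosome parameters, bypassing the
# random layout, for targeted simulator tests
make_plan <- function(dyads, chrom_len = max(dyads) + 2000L,
                      mean_reads = 100, fuzz_sigma = 20,
                      h1_mean_reads = 50, h1_skew = 0, h1_dyad_frac = 0.15,
                      planted_shift = 0L, seed = 1L, ...) {
  cfg <- synthetic_config(chrom_sizes = c(chrT = as.integer(chrom_len)), ...)
  nuc <- data.frame(chrom = "chrT", dyad = as.integer(dyads),
                    mean_reads = mean_reads, fuzz_sigma = fuzz_sigma,
                    h1_mean_reads = h1_mean_reads, h1_skew = h1_skew,
                    h1_dyad_frac = h1_dyad_frac,
                    planted_shift = as.integer(planted_shift),
                    stringsAsFactors = FALSE)
  plan <- list(chrom_sizes = cfg$chrom_sizes, nucleosomes = nuc,
               genes = data.frame(), seed = seed, config = cfg)
  class(plan) <- "genome_plan"
  plan
}
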