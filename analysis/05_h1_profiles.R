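#!/usr/bin/env Rscript
# Profile H1 placement on the stage-A nucleosome map: per-nucleosome H1
# occupancy/fuzziness/border skew, the dyad-anchored composite profile
# (+/- 1 kb, 10-bp bins, 5-bin moving average), directed TSS profiles per
# expression quintile with their upstream-depletion widths, and the
# H1:nucleosome occupancy ratio by distance to the TSS.

library(chromdyn)

outdir <- "results/h1"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

calls <- read_table_tsv("results/calls/calls_stageA.tsv")
h1 <- read_bed("results/synthetic/h1.bed")
genes <- read_gene_models("results/synthetic/genes.tsv")
fpkm <- setNames(genes$fpkm, genes$gene_id)

calls <- annotate_context(calls, genes)
calls <- assign_h1(calls, h1)
write_table_tsv(calls, file.path(outdir, "calls_with_h1.tsv"))
cat(sprintf("H1 reads assigned: %d of %d (%.1f%%)\n",
            sum(calls$h1_count), nrow(h1),
            100 * sum(calls$h1_count) / nrow(h1)))

prof <- composite_profile(data.frame(chrom = calls$chrom, pos = calls$dyad),
                          h1)
write_table_tsv(prof, file.path(outdir, "dyad_profile.tsv"))
near <- prof[abs(prof$bin_center) <= 150, ]
cat(sprintf("dyad profile: border mode at %+d bp, dyad mode/border mode = %.2f\n",
            as.integer(near$bin_center[which.max(near$value)]),
            max(prof$value[abs(prof$bin_center) <= 15]) / max(near$value)))

profs <- tss_profiles_by_expression(genes, fpkm, h1)
for (cl in names(profs)) {
  write_table_tsv(profs[[cl]], file.path(outdir, paste0("tss_", cl, ".tsv")))
}
widths <- vapply(profs, upstream_depletion_width, 0)
cat("upstream H1 depletion width by expression class (top 20% first):\n")
cat(sprintf("  %s\n", paste(sprintf("%s=%d bp", names(widths),
                                    as.integer(widths)), collapse = ", ")))

gc <- genic_calls(calls, genes)
dist_bin <- cut(gc$tss_distance, c(0, 500, 1000, 2000, 4000),
                right = FALSE)
grouping <- rep(NA_character_, nrow(calls))
grouping[gc$call] <- as.character(dist_bin)
ratios <- ratio_profile(calls, grouping, seed = 1)
write_table_tsv(ratios, file.path(outdir, "ratio_by_tss_distance.tsv"))
cat("H1:nucleosome occupancy ratio by TSS distance:\n")
print(ratios, row.names = FALSE)
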