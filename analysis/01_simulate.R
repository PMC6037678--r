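#!/usr/bin/env Rscript
# Generate the synthetic two-stage chromatin dataset that every later step
# consumes: MNase reads for stages A and B, H1 ChIP reads, gene models with
# FPKM, and the planted-truth table. Stage-B repositioning direction is
# coupled to the planted H1 border skew, so the downstream skew/shift
# analysis has a known answer.

library(chromdyn)

seed <- 1L
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(chrom_sizes = c(chrSim1 = 400000L),
                        n_genes = 50L,
                        h1_skew_range = c(-0.8, 0.8),
                        shift_scheme = "h1_coupled")
plan <- build_plan(cfg, seed)
pair <- simulate_stage_pair(plan)
h1 <- simulate_h1_reads(plan)

write_bed(pair$reads_a, file.path(outdir, "mnase_stageA.bed"))
write_bed(pair$reads_b, file.path(outdir, "mnase_stageB.bed"))
write_bed(h1, file.path(outdir, "h1.bed"))
write_gene_models(plan$genes,
                  tsv_path = file.path(outdir, "genes.tsv"),
                  bed_path = file.path(outdir, "genes.bed"))
write_table_tsv(pair$truth, file.path(outdir, "truth.tsv"))
write_table_tsv(data.frame(chrom = names(plan$chrom_sizes),
                           size = unname(plan$chrom_sizes)),
                file.path(outdir, "chrom_sizes.tsv"))

cat(sprintf("planted nucleosomes: %d\n", nrow(plan$nucleosomes)))
cat(sprintf("stage A reads: %d  stage B reads: %d  H1 reads: %d\n",
            nrow(pair$reads_a), nrow(pair$reads_b), nrow(h1)))
cat(sprintf("genes: %d (FPKM %.2f-%.2f), planted NFR widths %d-%d bp\n",
            nrow(plan$genes), min(plan$genes$fpkm), max(plan$genes$fpkm),
            min(plan$genes$nfr_width), max(plan$genes$nfr_width)))
cat(sprintf("planted shift classes: %s\n",
            paste(names(table(pair$truth$class)),
                  table(pair$truth$class), collapse = ", ")))
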