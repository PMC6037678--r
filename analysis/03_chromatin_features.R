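#!/usr/bin/env Rscript
# Derive higher-order chromatin features from the stage-A nucleosome map:
# linkers, NFRs (linker > 100 bp), arrays (>= 3 nucleosomes, no internal
# NFR), orphan nucleosomes (NFR on each side) and the phasogram.

library(chromdyn)

outdir <- "results/features"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

calls <- read_table_tsv("results/calls/calls_stageA.tsv")
linkers <- compute_linkers(calls)
nfrs <- find_nfrs(linkers)
arrays <- find_arrays(calls, linkers)
orphans <- find_orphans(calls, linkers, nfrs)
phas <- phasogram(calls)

write_table_tsv(linkers, file.path(outdir, "linkers.tsv"))
write_table_tsv(nfrs, file.path(outdir, "nfrs.tsv"))
write_table_tsv(data.frame(array = rep(seq_along(arrays), lengths(arrays)),
                           call = unlist(arrays)),
                file.path(outdir, "arrays.tsv"))
write_table_tsv(data.frame(call = orphans),
                file.path(outdir, "orphans.tsv"))
write_table_tsv(phas, file.path(outdir, "phasogram.tsv"))

modal <- phas$distance[which.max(phas$count)]
cat(sprintf("linkers: %d, modal linker %d bp (phasogram mode %d bp)\n",
            nrow(linkers),
            as.integer(names(which.max(table(linkers$length)))), modal))
cat(sprintf("NFRs: %d (of %d linkers), arrays: %d covering %d nucleosomes, orphans: %d\n",
            nrow(nfrs), nrow(linkers), length(arrays),
            length(unlist(arrays)), length(orphans)))
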