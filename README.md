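# chromdyn

Nucleosome positioning and linker histone H1 placement dynamics from
coordinate-level sequencing data.

In chromatin, ~147 bp of DNA wraps each nucleosome core, and the linker
histone H1 binds near the points where linker DNA enters and exits the
core, forming the chromatosome. `chromdyn` is an analysis pipeline for
asking, from mapped single-end MNase-seq and H1 ChIP-seq reads, where
nucleosomes sit, how H1 distributes over them — on the two core borders
and the dyad — and how skewed H1 placement relates to nucleosome
repositioning between two developmental stages. It is aimed at
epigenomics analysts working with *Drosophila*-embryo-style MNase/ChIP
libraries, but nothing in it is organism-specific.

## What it computes

**Nucleosome calling.** Each single-end read is shifted 73 bp interior
to its 5′ end to mark the dyad; the per-base dyad density
d(x) = Σᵢ exp(−(x − xᵢ)²/2σ²) (σ = 20 bp) is scanned greedily for peaks
with a 147-bp exclusion zone. Per call: occupancy as RPNM
(reads per nucleosome per million mapped, calls < 0.1 discarded) and
fuzziness (population SD of the assigned read dyads).

**Features.** Linkers (Δdyad − 147), NFRs (linkers > 100 bp), arrays
(≥3 calls with no internal NFR), orphan nucleosomes (NFR on each side),
and the phasogram of adjacent dyad distances.

**Dynamics.** Each stage-A call pairs with its nearest stage-B dyad:
distance ≤ 10 bp = fixed, ≥ 127 bp = lost, otherwise shifted; shifted
calls bin into 0–10 / 30–40 / 50–74 bp magnitude groups by direction.

**H1 profiling.** Overlap-based read-to-core assignment, H1 occupancy
and fuzziness, border-skew score (R − L)/(R + L) from the windows
dyad ± 73 ± 20 bp, composite profiles (±1 kb, 10-bp bins, 5-bin moving
average) around dyads and TSSs, directed 5′→3′ profiles per expression
quintile, and H1:nucleosome occupancy ratios.

**Statistics.** Two-sided permutation tests on differences of group
means (exact by enumeration when feasible, Monte-Carlo with add-one
correction otherwise) and Spearman correlations with bootstrap CIs.

**Synthetic data.** A seeded generator plants nucleosomes (175-bp
spacing, 28-bp modal linker), MNase and H1 reads (border/dyad mixture
with tunable skew), genes with expression-scaled upstream NFRs, and
stage-B shifts optionally sign-coupled to H1 skew — so every stage of
the pipeline is testable against known truth without downloads.

## Worked example

```r
library(chromdyn)
cfg <- synthetic_config(chrom_sizes = c(chr1 = 100000L),
                        h1_skew_range = c(-0.8, 0.8),
                        shift_scheme = "h1_coupled")
res <- run_pipeline(cfg, seed = 42)
rec <- dyad_recovery(res$plan$nucleosomes, res$calls_a)
```

This plants a 100-kb chromosome, simulates both stages plus H1, calls
nucleosomes, and measures everything. Printing the headline numbers:

```
planted 561 nucleosomes; called 561; recovered within 10 bp: 99.5%
mean fuzziness 19.9 bp (planted 20); phasogram mode 176 bp
NFRs: 0; arrays: 1; dynamics: fixed 23, lost 19, shifted 519
H1 skew sign predicts shift direction for 93.3% of 240 nucleosomes
```

The caller recovers essentially every planted dyad and the planted
positional fuzziness; the phasogram sits at the planted ~175-bp repeat;
with no genes configured there are no NFRs, so the whole chromosome is
one array; and because stage-B shift direction was planted to follow H1
border skew, the measured stage-A skew predicts the measured shift
direction for >90% of shifted nucleosomes — the pipeline's end-to-end
check.

## Analysis workflow

`analysis/` holds the numbered drivers that run the full study on a
synthetic dataset and leave their tables under `results/`:

| script | writes |
|---|---|
| `01_simulate.R` | reads (BED), genes, planted truth |
| `02_call_nucleosomes.R` | per-stage call tables, density bedGraph |
| `03_chromatin_features.R` | linkers, NFRs, arrays, orphans, phasogram |
| `04_dynamics.R` | dynamics records, reassembled calls, truth recovery |
| `05_h1_profiles.R` | H1-annotated calls, dyad/TSS profiles, ratios |
| `06_stats_summary.R` | permutation tests, correlations, skew readout |

Run them in order with `Rscript analysis/01_simulate.R` etc.

## Documentation

The methods vignette (`vignettes/chromatin-h1-dynamics.Rmd`) describes
the models, defaults, tie-breaks, experiment designs and limitations;
every exported function carries full roxygen documentation.
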