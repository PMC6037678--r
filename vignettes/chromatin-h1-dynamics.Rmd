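---
title: "Mapping linker histone H1 on nucleosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping linker histone H1 on nucleosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

# The problem

In early *Drosophila* embryos, nucleosomes occupy well-defined positions
and the linker histone H1 binds the chromatosome — a nucleosome core plus
one H1 — preferentially near the points where linker DNA enters and exits
the core. `chromdyn` implements the computational side of mapping that
placement from coordinate-level sequencing data: nucleosome calling from
single-end MNase-seq reads, occupancy and fuzziness statistics,
higher-order features (linkers, nucleosome-free regions, arrays, orphan
nucleosomes), repositioning between two developmental stages, and H1
placement profiles around nucleosome dyads and transcription start sites.
Because the raw sequencing libraries are not shipped with the package, a
synthetic read generator with planted ground truth stands in for them;
every stage is validated by recovering what was planted.

# Nucleosome calling

A single-end MNase read marks one end of the ~147 bp of DNA protected by
a nucleosome core. Each read is therefore moved 73 bp interior to its 5'
end to point at the dyad: a plus-strand read maps to `start + 73`, a
minus-strand read to `(end - 1) - 73` (`shift_reads_to_dyads()`). The
per-base dyad density is a Gaussian kernel sum,

$$ d(x) = \sum_i e^{-(x - x_i)^2 / 2\sigma^2}, $$

with $\sigma$ = 20 bp by default and the kernel truncated at $\pm 4\sigma$
(`smooth_dyad_signal()`). Peaks are picked greedily: the highest remaining
density position becomes a call, and all positions closer than the
exclusion width (147 bp, one core) are removed from consideration, so
called dyads never overlap at the core level; exact ties go to the smaller
coordinate so calls are reproducible (`call_peaks()`). Read dyads are then
assigned to the nearest call within ±73 bp, ties again to the left.

Two statistics summarize each call. **Occupancy** is RPNM — reads per
nucleosome per million mapped reads, `count * 1e6 / total_mapped` — and
calls below 0.1 RPNM are discarded (inclusive threshold: exactly 0.1 is
kept). **Fuzziness** is the population standard deviation (divide by *n*,
no sample correction) of the assigned read dyad coordinates; a
single-read call has fuzziness 0. Fuzziness is computed on shifted dyad
coordinates rather than raw 5' ends; the two differ by a per-strand
constant, so a mixed-strand SD on raw ends would be slightly inflated.

Tunables and defaults: smoothing $\sigma$ 20 bp and exclusion width
147 bp (the values the underlying peak-calling approach uses for
nucleosomes), assignment half-window 73 bp (one half-core; chosen to
match the exclusion geometry), minimum RPNM 0.1, promoter window 500 bp
upstream of the TSS (no standard definition exists; exposed as an
argument). All are arguments of `call_nucleosomes()` and
`annotate_context()`.

# Higher-order features

All linker arithmetic treats a core as dyad ± 73 bp, so the linker between
adjacent calls has length $\Delta\text{dyad} - 147$ (`compute_linkers()`).
Linkers longer than 100 bp are **NFRs** (nucleosome-free regions; the
literature also says NDR, nucleosome-depleted region — we treat the terms
as synonyms). The threshold is strict (`> 100`), with an inclusive
`>= 100` variant behind the `inclusive` flag. **Arrays** are maximal runs
of at least three calls with no internal linker above 100 bp (a 100-bp
linker does not break an array). **Orphans** are calls with an NFR on each
side; chromosome-terminal calls, lacking one flank, are never orphans.
The **phasogram** — the histogram of adjacent dyad-to-dyad distances
within chromosomes — exposes the repeat length; on the default synthetic
landscape it peaks at 175 bp = 147-bp core + 28-bp modal linker.

# Two-stage dynamics

For every stage-A call, the nearest stage-B dyad on the same chromosome
gives a distance and a signed shift (`match_nucleosomes()`; equidistant
neighbors resolve leftward). Distance ≤ 10 bp means **fixed**, ≥ 127 bp
**lost** (disassembled or reassembled), anything between **shifted**. The
source material states the boundaries once exclusively and once
inclusively; we use the inclusive forms and expose both thresholds as
arguments. Shifted calls are binned by magnitude into the closed ranges
0–10 (fixed), 30–40 (intermediate) and 50–74 bp (far — half a nucleosome),
with shifts in the gaps reported as "other"; direction is the sign of the
shift. Matching is one-directional A→B, as the definition of the distance
implies; stage-B calls with no A partner within 127 bp are reported
separately as reassembled (`find_reassembled()`).

# H1 profiling

An H1 ChIP read represents one bound H1, located at its interval midpoint
(the symmetric choice; a 5'-end mode exists). A read is assigned to the
call whose core it overlaps by at least 1 bp; when it overlaps two
touching cores, the larger overlap wins, ties to the left
(`assign_h1()`). H1 occupancy and fuzziness are computed exactly as for
nucleosomes, normalized by the H1 library size, so H1:nucleosome
occupancy ratios compare depth-normalized quantities and are invariant to
sequencing depth.

**Border skew.** The H1 signal in the two border windows dyad ± 73 ± 20 bp
(i.e. ±[53, 93]) gives the skew score $(R - L)/(R + L) \in [-1, 1]$,
0 when both windows are empty. The 40-bp window covers the border peak
without touching the dyad mode. On synthetic data where stage-B shift
direction is planted to follow H1 skew, the measured stage-A skew sign
predicts the measured shift direction for >90% of nucleosomes in the
named shift bins — the pipeline's end-to-end headline check.

**Composite profiles.** Read midpoints within ±1 kb of each anchor (dyad
or TSS) are accumulated into 10-bp bins, normalized to reads per million,
and smoothed with a centered 5-bin moving average at 1-bin step
(`composite_profile()`). The moving average truncates at the profile
edges (averages the available bins) rather than padding, keeping mass
interpretable. Directed profiles flip the offset sign for minus-strand
anchors so the x axis always reads 5'→3'. At the default 175-bp spacing
the composite border modes appear near ±85 bp rather than exactly ±73:
each nucleosome's border peak blends with its neighbors' opposite borders
(at ±102 bp) under the 5-bin smoothing. Checks on mode location therefore
assert the maxima fall inside the border windows.

**Groupings.** `group_and_select()` reproduces the matched-extremes
design: group calls by intervals of one statistic (fuzziness interval 5,
occupancy interval 0.4) so it is near-constant within a group, then take
the top and bottom *k* (default 10,000) by the complementary statistic;
undersized groups fall back to a disjoint median split with a warning.
`expression_classes()` ranks genes by FPKM (ties broken by gene id) into
five equal-count classes; genes lacking expression values are excluded
from expression-grouped analyses. Genic calls inherit their gene's
direction; for nucleosomes inside overlapping plus/minus gene pairs
(bidirectional transcription units) the busier gene's direction is used
and FPKM ties are excluded (`transcription_units()`). The gene-body
profile rule keeps all calls of genes shorter than 3 kb and only calls
within the first 3 kb downstream of the TSS for longer genes.

# Permutation tests and correlations

Group comparisons use a two-sided permutation test on
$T = |\bar{a} - \bar{b}|$ (`permutation_test()`). When
$\binom{n}{n_a} \le 10^5$ all arrangements are enumerated and the p-value
is exact; otherwise 10,000 Monte-Carlo relabelings are drawn with the
add-one correction $(b+1)/(m+1)$, which avoids p = 0 and makes the test
slightly conservative. Values are permuted at the nucleosome level — the
unit being plotted. Correlations default to Spearman (the occupancy scale
is heavy-tailed) with a seeded percentile-bootstrap CI.

# The synthetic generator

`synthetic_config()` / `build_plan()` plant a chromatin landscape whose
defaults are the study conditions used by the tests: dyads spaced 175 bp
(modal linker 28 bp) with 5-bp jitter but never closer than 147 bp; 1-kb
nucleosome-free chromosome margins; fuzziness 20 bp; ~100 MNase reads per
nucleosome (Poisson counts around gamma-distributed means, CV 0.5 — the
minimal count model, keeping recovery tests analytic); ~50 H1 reads per
nucleosome, proportional to the MNase mean with lognormal noise, planting
a positive H1-vs-occupancy correlation. The expected H1 reads per
chromatosome is not a measurable biological constant here; it is exposed
as a free parameter. H1 centers follow a three-component mixture — left
border, right border, dyad at weights
$(1-f)(1\mp s)/2$ and $f$ with default dyad fraction $f = 0.15$ — each
jittered by 10 bp (border peaks have finite width; the exact value is a
modeling choice). Genes sit in equal-width slots with lognormal FPKM, and
a nucleosome-free gap is carved immediately upstream of each TSS with
width growing from 150 to 500 bp with FPKM rank, so expression-dependent
NFR footprints have a known ordering. Stage B displaces each nucleosome by
its planted shift; the `h1_coupled` scheme draws the magnitude from
{35, 60} bp and takes the sign from the nucleosome's H1 skew.

All randomness in a generator call flows from one integer seed through a
single stream with fixed iteration order, so identical (config, seed)
gives byte-identical output.

What the generator does **not** emulate: sequence content and MNase
sequence bias (coordinates only), overdispersed read counts, chromatin
heterogeneity between cells, alternative nucleosome positions within one
locus, and copy-number or mappability artifacts. Passing recovery tests
therefore demonstrates the pipeline's correctness under its own model of
the data, not robustness to every artifact of real libraries.

# Experiment design notes

Study conditions for the validation experiments were fixed once:

* **Dyad recovery** runs at the default landscape (200-kb chromosome,
  175-bp spacing, σ 20, ~100 reads/nucleosome) and asks for ≥95% of
  planted dyads within ±10 bp.
* **Fuzziness recovery** uses isolated nucleosomes (600-bp spacing) with
  a wide assignment window (±250 bp) and ~1,000 reads each. At the
  default ±73-bp window the tails of a σ = 30 read-dyad distribution are
  truncated, biasing the SD ~5% low — a property of the assignment
  window, not the estimator, and a known limitation at high fuzziness.
* **Dynamics class recovery** also uses isolated nucleosomes: with shifts
  up to ±200 bp at 175-bp spacing, roughly 39% of adjacent stage-B cores
  would collide (gap < 147 bp) and be merged by the caller, which tests
  caller merging rather than the classifier. The end-to-end skew/shift
  check still runs at the dense default spacing, where collisions are
  rare for the {35, 60}-bp magnitudes.
* **Expression-scaled NFRs** use a 400-kb chromosome with 50 genes
  (10 per expression class); the depletion-width ordering across classes
  is asserted by a one-sided Spearman rank test. The depletion width is
  read off the directed TSS profile as the contiguous run of bins below
  half the gene-body baseline, allowed to start within 100 bp of the TSS
  (the +1 nucleosome's border signal can bleed across it).
* The permutation-test **type-I error** is estimated from 1,000 null
  replicates (two i.i.d. normal groups of 50) at 500 Monte-Carlo
  permutations each — enough resolution at α = 0.05 while keeping the
  default test run fast.

# Degenerate inputs and tie-breaks

Empty read sets produce empty call tables; calls with zero assigned reads
are dropped before statistics (fuzziness would be undefined); flat-zero
density yields no peaks; equal-density peaks, equidistant reads and
equidistant stage-B neighbors all resolve toward the smaller coordinate;
FPKM ties across strands exclude a bidirectional call; `skew_score(0, 0)`
is 0 by convention. BED parsing rejects `start >= end`, negative
coordinates and unknown strands with the offending line number.

# Known limitations

Occupancy comparisons across libraries assume per-library RPNM is the
right cross-library normalization; no further scaling is applied.
Fuzziness at the default assignment window is mildly shrunk for very
fuzzy nucleosomes (above). H1 reads longer than the call spacing would
need more than the two flanking candidate cores considered by
`assign_h1()`; at the 49-bp read length this cannot occur. The caller's
exclusion geometry forbids overlapping calls by construction, so
alternative overlapping nucleosome configurations are invisible.
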