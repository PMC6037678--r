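test_that("reads shift 73 bp interior to their 5' end", {
  r <- make_reads("chr2L", c(1000L, 1951L), c(1049L, 2000L), c("+", "-"))
  d <- shift_reads_to_dyads(r)
  expect_equal(d$dyad, c(1073L, 1926L))

  d0 <- shift_reads_to_dyads(make_reads("chr1", 5L, 54L, "+"), offset = 0L)
  expect_equal(d0$dyad, 5L)
})

test_that("out-of-bounds dyads are dropped and counted", {
  r <- make_reads("chr1", c(10L, 990L), c(59L, 1039L), c("-", "+"))
  # minus read dyad = 58 - 73 < 0; plus read dyad = 1063 >= 1000
  d <- shift_reads_to_dyads(r, chrom_sizes = c(chr1 = 1000L))
  expect_equal(nrow(d), 0L)
  expect_equal(attr(d, "dropped"), 2L)
})

test_that("Gaussian smoothing is symmetric, additive and mass-conserving", {
  dens <- smooth_dyad_signal(500L, sigma = 20, chrom_len = 1000L)
  expect_equal(which.max(dens), 501L) # 0-based position 500
  expect_equal(dens[501 - 40], dens[501 + 40])

  # two far-apart kernels: each peak equals the single-kernel peak
  d2 <- smooth_dyad_signal(c(200L, 800L), sigma = 20, chrom_len = 1000L)
  expect_equal(d2[201], dens[501], tolerance = 1e-10)
  expect_equal(d2[801], dens[501], tolerance = 1e-10)

  # total mass = n_dyads * sigma * sqrt(2*pi) within truncation error
  set.seed(7)
  dyads <- sample(300:700, 25)
  dall <- smooth_dyad_signal(dyads, sigma = 20, chrom_len = 1000L)
  expect_equal(sum(dall) / (20 * sqrt(2 * pi)), 25, tolerance = 1e-3)
})

test_that("greedy peak calling enforces the exclusion zone with left tie-break", {
  dens <- numeric(1000)
  dens[c(101, 301)] <- 5 # 0-based 100 and 300: 200 bp apart
  expect_equal(call_peaks(dens), c(100L, 300L))

  dens <- numeric(1000)
  dens[c(101, 201)] <- 5 # 100 bp apart, equal height -> left wins
  expect_equal(call_peaks(dens), 100L)

  expect_equal(call_peaks(numeric(500)), integer(0))

  # called dyads never closer than the exclusion width
  set.seed(3)
  dens <- runif(2000)
  calls <- call_peaks(dens, exclusion_width = 147L)
  expect_true(all(diff(calls) >= 147L))
})

test_that("read dyads go to the nearest call within 73 bp, ties left", {
  expect_equal(assign_reads(500L, c(500L, 573L, 574L)), c(1L, 1L, NA))
  # equidistant between calls 50 bp away each -> left call
  expect_equal(assign_reads(c(400L, 500L), 450L), 1L)
  expect_equal(assign_reads(integer(0), c(1L, 2L)), rep(NA_integer_, 2))
})

test_that("occupancy is RPNM and fuzziness the population SD", {
  of <- occupancy_and_fuzziness(rep(100L, 50), total_mapped = 2e6)
  expect_equal(of$occupancy, 25.0)
  expect_equal(of$fuzziness, 0)
  expect_equal(occupancy_and_fuzziness(c(100L, 110L, 120L), 1e6)$fuzziness,
               sqrt(200 / 3))
  # doubling the library halves RPNM (scale equivariance)
  expect_equal(occupancy_and_fuzziness(1:10, 2e6)$occupancy,
               occupancy_and_fuzziness(1:10, 1e6)$occupancy / 2)
})

test_that("RPNM filter is inclusive at the threshold", {
  calls <- make_calls(c(100, 300, 500), occupancy = c(0.1, 0.0999, 5))
  kept <- filter_calls(calls)
  expect_equal(kept$dyad, c(100L, 500L))
  expect_equal(nrow(filter_calls(calls, min_rpnm = 0)), 3L)
})

test_that("context assignment: promoter window beats genic, else intergenic", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = c("chr1", "chr1"),
                      tss = c(5000L, 12000L), tes = c(8000L, 9000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  calls <- make_calls(c(4900, 6000, 12300, 20000, 4000))
  out <- annotate_context(calls, genes, promoter_window = 500L)
  expect_equal(out$context,
               c("promoter", # 100 bp upstream of + TSS
                 "genic",
                 "promoter", # 300 bp upstream of - TSS (to the right)
                 "intergenic", "intergenic"))
  # chromosome with no genes -> intergenic
  lonely <- annotate_context(make_calls(100, chrom = "chrX"), genes)
  expect_equal(lonely$context, "intergenic")
  # promoter precedence on overlap: promoter of gm sits inside gp's body?
  ov_genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                         tss = c(1000L, 2500L), tes = c(3000L, 2000L),
                         strand = c("+", "-"), stringsAsFactors = FALSE)
  out2 <- annotate_context(make_calls(2700), ov_genes, promoter_window = 500L)
  expect_equal(out2$context, "promoter")
})

test_that("simulated reads with zero fuzziness are recovered exactly", {
  plan <- make_plan(c(2000L, 2600L), fuzz_sigma = 0, mean_reads = 40)
  reads <- simulate_mnase_reads(plan, seed = 5, plus_prob = 1)
  expect_true(all(reads$start %in% c(2000L - 73L, 2600L - 73L)))
  # round-trip identity: the 73-bp rule recovers implied dyads exactly
  d <- shift_reads_to_dyads(reads)
  expect_true(all(d$dyad %in% c(2000L, 2600L)))
})

test_that("read assignment conserves reads and calling recovers planted dyads", {
  cfg <- synthetic_config(chrom_sizes = c(chrSim1 = 60000L))
  plan <- build_plan(cfg, seed = 11)
  reads <- simulate_mnase_reads(plan, seed = 12)
  calls <- call_nucleosomes(reads, plan$chrom_sizes)
  expect_equal(sum(calls$n_reads) + attr(calls, "unassigned"), nrow(reads))
  rec <- dyad_recovery(plan$nucleosomes, calls)
  expect_gt(mean(rec <= 10), 0.95)
  # per-chromosome calls are sorted and respect the exclusion width
  expect_true(all(diff(calls$dyad) >= 147L))
})

test_that("estimated fuzziness tracks the planted sigma", {
  plan <- make_plan(c(2000L, 4000L, 6000L), fuzz_sigma = 20,
                    mean_reads = 1000)
  reads <- simulate_mnase_reads(plan, seed = 21)
  calls <- call_nucleosomes(reads, plan$chrom_sizes, half_window = 250L,
                            exclusion_width = 300L)
  expect_equal(nrow(calls), 3L)
  expect_equal(mean(calls$fuzziness), 20, tolerance = 0.05)
})
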