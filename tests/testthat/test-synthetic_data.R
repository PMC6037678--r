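test_that("plan layout matches the configured spacing and margins", {
  cfg <- synthetic_config(chrom_sizes = c(c1 = 100000L), spacing_jitter_sd = 0)
  plan <- build_plan(cfg, seed = 1)
  n <- nrow(plan$nucleosomes)
  expect_true(abs(n - (100000 - 2000) / 175) <= 2) # ~560 dyads
  d <- plan$nucleosomes$dyad
  expect_true(all(diff(d) >= 147L))
  expect_true(all(d >= 1000 & d <= 99000))
})

test_that("plans are deterministic and jittered linkers stay modal at 28 bp", {
  cfg <- synthetic_config(chrom_sizes = c(c1 = 100000L))
  p1 <- build_plan(cfg, seed = 9)
  p2 <- build_plan(cfg, seed = 9)
  expect_identical(p1, p2)
  linker <- diff(p1$nucleosomes$dyad) - 147L
  modal <- as.integer(names(which.max(table(linker))))
  expect_lte(abs(modal - 28L), 1L) # jitter mode 0, finite-sample wobble
})

test_that("jitter-free plans have the 28-bp modal linker exactly", {
  cfg <- synthetic_config(chrom_sizes = c(c1 = 100000L),
                          spacing_jitter_sd = 0)
  plan <- build_plan(cfg, seed = 9)
  expect_true(all(diff(plan$nucleosomes$dyad) - 147L == 28L))
})

test_that("undersized chromosomes raise sizing errors", {
  expect_error(build_plan(synthetic_config(chrom_sizes = c(tiny = 2100L)),
                          seed = 1), "too small")
  expect_error(
    build_plan(synthetic_config(chrom_sizes = c(c1 = 30000L), n_genes = 10L),
               seed = 1),
    "too small")
})

test_that("planted NFR width grows with FPKM rank", {
  cfg <- synthetic_config(chrom_sizes = c(c1 = 400000L), n_genes = 30L)
  plan <- build_plan(cfg, seed = 2)
  g <- plan$genes
  expect_equal(nrow(g), 30L)
  expect_gt(cor(rank(g$fpkm), g$nfr_width, method = "spearman"), 0.99)
  expect_true(all(g$nfr_width > 100))
  # the carved gap upstream of each TSS really is nucleosome-free
  for (i in seq_len(nrow(g))) {
    w_lo <- if (g$strand[i] == "+") g$tss[i] - g$nfr_width[i] else g$tss[i] + 1L
    w_hi <- w_lo + g$nfr_width[i]
    nd <- plan$nucleosomes$dyad
    expect_false(any(nd + 73 >= w_lo & nd - 73 < w_hi))
  }
})

test_that("MNase simulation reproduces the planted dyad spread", {
  plan <- make_plan(5000L, fuzz_sigma = 20, mean_reads = 10000)
  reads <- simulate_mnase_reads(plan, seed = 3)
  d <- shift_reads_to_dyads(reads)
  expect_gt(nrow(d), 9000)
  expect_equal(sd(d$dyad), 20, tolerance = 0.05) # within 20 +/- 1
  expect_equal(mean(d$dyad), 5000, tolerance = 1e-4)

  empty <- simulate_mnase_reads(plan, depth_factor = 0, seed = 3)
  expect_equal(nrow(empty), 0L)
})

test_that("H1 mixture honors skew and dyad-fraction degenerate cases", {
  plan_r <- make_plan(5000L, h1_skew = 1, h1_dyad_frac = 0,
                      h1_mean_reads = 2000)
  centers <- read_centers(simulate_h1_reads(plan_r, seed = 4))
  expect_equal(mean(centers), 5073, tolerance = 1e-3)
  expect_true(all(abs(centers - 5073) < 60)) # jitter only, no left border

  plan_d <- make_plan(5000L, h1_dyad_frac = 1, h1_mean_reads = 2000)
  centers <- read_centers(simulate_h1_reads(plan_d, seed = 4))
  expect_true(all(abs(centers - 5000) < 60))
})

test_that("symmetric H1 splits evenly between the borders", {
  plan <- make_plan(5000L, h1_skew = 0, h1_dyad_frac = 0,
                    h1_mean_reads = 10000)
  centers <- read_centers(simulate_h1_reads(plan, seed = 6))
  left <- sum(centers < 5000)
  right <- sum(centers > 5000)
  pt <- prop.test(left, left + right, p = 0.5)
  expect_gt(pt$p.value, 0.001)
})

test_that("stage pairs carry a truth table consistent with the thresholds", {
  plan0 <- make_plan(c(3000L, 6000L), planted_shift = 0L)
  expect_true(all(simulate_stage_pair(plan0)$truth$class == "fixed"))

  plan35 <- make_plan(c(3000L, 6000L), planted_shift = 35L)
  tr <- simulate_stage_pair(plan35)$truth
  expect_true(all(tr$class == "shifted"))
  expect_equal(tr$dyad_b - tr$dyad_a, rep(35L, 2))

  plan200 <- make_plan(c(3000L, 6000L), planted_shift = 200L)
  expect_true(all(simulate_stage_pair(plan200)$truth$class == "lost"))
})

test_that("simulators are byte-deterministic given (plan, seed)", {
  cfg <- synthetic_config(chrom_sizes = c(c1 = 50000L))
  plan <- build_plan(cfg, seed = 8)
  expect_identical(simulate_mnase_reads(plan, seed = 1),
                   simulate_mnase_reads(plan, seed = 1))
  expect_identical(simulate_h1_reads(plan, seed = 1),
                   simulate_h1_reads(plan, seed = 1))
})
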