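test_that("read centers: midpoint by default, 5' end on request", {
  r <- make_reads("c", c(100L, 200L), c(149L, 249L), c("+", "-"))
  expect_equal(read_centers(r), c(124L, 224L))
  expect_equal(read_centers(r, "5prime"), c(100L, 248L))
})

test_that("H1 reads attach to the overlapped core, greater overlap wins", {
  gap_calls <- make_calls(c(1000, 1400)) # cores [927,1074) and [1327,1474)
  # overlaps call 1's core [927, 1074)
  a1 <- assign_h1(gap_calls, make_reads("chr1", 920L, 970L))
  expect_equal(attr(a1, "assignment"), 1L)
  # entirely inside the linker between the cores -> unassigned
  a2 <- assign_h1(gap_calls, make_reads("chr1", 1080L, 1120L))
  expect_true(is.na(attr(a2, "assignment")))

  touching <- make_calls(c(1000, 1147)) # cores [927,1074) and [1074,1221)
  # overlap 1 bp vs 3 bp -> right core
  a3 <- assign_h1(touching, make_reads("chr1", 1073L, 1077L))
  expect_equal(attr(a3, "assignment"), 2L)
  # equal 2-bp overlap -> left core
  a4 <- assign_h1(touching, make_reads("chr1", 1072L, 1076L))
  expect_equal(attr(a4, "assignment"), 1L)
})

test_that("H1 assignment conserves reads and normalizes by H1 depth", {
  plan <- make_plan(seq(2000L, 20000L, by = 175L))
  h1 <- simulate_h1_reads(plan, seed = 31)
  calls <- make_calls(plan$nucleosomes$dyad, chrom = "chrT")
  out <- assign_h1(calls, h1)
  expect_equal(sum(out$h1_count) + attr(out, "unassigned"), nrow(h1))
  expect_equal(out$h1_occupancy, out$h1_count * 1e6 / nrow(h1))
})

test_that("skew score is the normalized border asymmetry", {
  expect_equal(skew_score(0, 10), 1)
  expect_equal(skew_score(10, 0), -1)
  expect_equal(skew_score(5, 5), 0)
  expect_equal(skew_score(0, 0), 0)
})

test_that("planted H1 skew is recovered from border counts", {
  plan <- make_plan(5000L, h1_skew = -0.5, h1_mean_reads = 10000,
                    h1_dyad_frac = 0.15)
  h1 <- simulate_h1_reads(plan, seed = 33)
  out <- assign_h1(make_calls(5000, chrom = "chrT"), h1)
  expect_equal(out$skew, -0.5, tolerance = 0.1) # within +/- 0.05 absolute
})

test_that("a single read lands in one bin and smoothing spreads it over 5", {
  anchors <- data.frame(chrom = "c", pos = 5000L)
  read <- make_reads("c", 5049L, 5098L) # center 5073, offset +73
  p <- composite_profile(anchors, read, total_mapped = 1L)
  expect_equal(p$bin_center[p$raw_count > 0], 75)
  expect_equal(sum(p$raw_count), 1)
  expect_equal(sum(p$value > 0), 5)
  expect_equal(nrow(p), 200L)
})

test_that("minus-orientation anchors mirror the profile", {
  reads <- make_reads("c", c(5100L, 5300L), c(5149L, 5349L))
  plus <- composite_profile(data.frame(chrom = "c", pos = 5000L,
                                       orientation = 1L), reads)
  minus <- composite_profile(data.frame(chrom = "c", pos = 5448L,
                                        orientation = -1L), reads)
  # mirrored layout: same offsets 5' to 3'
  expect_equal(plus$value, minus$value)
  expect_error(composite_profile(data.frame(chrom = character(),
                                            pos = integer()), reads),
               "empty")
})

test_that("moving average truncates at the edges", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), k = 3),
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(rep(2, 10)), rep(2, 10))
  x <- rnorm(7)
  expect_equal(moving_average(x, k = 1), x)
})

test_that("H1:nucleosome ratios behave and are depth-invariant", {
  calls <- make_calls(c(1000, 2000), occupancy = c(2, 4))
  calls$h1_occupancy <- c(2, 0)
  rp <- ratio_profile(calls, grouping = c("g", "g"), n_boot = 50)
  expect_equal(rp$mean_ratio, mean(c(1, 0)))
  # duplicating every H1 read (double depth) leaves occupancy unchanged
  plan <- make_plan(seq(2000L, 8000L, by = 175L))
  h1 <- simulate_h1_reads(plan, seed = 35)
  cl <- make_calls(plan$nucleosomes$dyad, chrom = "chrT")
  once <- assign_h1(cl, h1)
  twice <- assign_h1(cl, rbind(h1, h1))
  expect_equal(once$h1_occupancy, twice$h1_occupancy)
})

test_that("statistic-controlled extreme sets are disjoint and sized k", {
  set.seed(41)
  calls <- make_calls(seq(1000, by = 200, length.out = 60),
                      occupancy = runif(60, 0, 4),
                      fuzziness = runif(60, 30, 35))
  sel <- group_and_select(calls, key = "fuzziness", interval = 5,
                          select_by = "occupancy", k = 10)
  expect_equal(unique(sel$group), "[30,35)")
  top <- sel$call[sel$set == "top"]
  bot <- sel$call[sel$set == "bottom"]
  expect_length(top, 10)
  expect_length(bot, 10)
  expect_length(intersect(top, bot), 0)
  expect_true(min(calls$occupancy[top]) >= max(calls$occupancy[bot]))

  # undersized group falls back to a median split with a warning
  expect_warning(
    sel2 <- group_and_select(calls, key = "fuzziness", interval = 5,
                             select_by = "occupancy", k = 50),
    "median split")
  expect_length(intersect(sel2$call[sel2$set == "top"],
                          sel2$call[sel2$set == "bottom"]), 0)
})

test_that("expression classes are equal-count with deterministic ties", {
  genes <- data.frame(gene_id = paste0("g", 1:5), chrom = "c",
                      tss = seq(1000L, 5000L, by = 1000L),
                      tes = seq(1500L, 5500L, by = 1000L), strand = "+",
                      stringsAsFactors = FALSE)
  fpkm <- c(g1 = 5, g2 = 50, g3 = 1, g4 = 5, g5 = 100)
  ec <- expression_classes(genes, fpkm)
  expect_equal(ec$gene_id[ec$expr_class == 1], "g5")
  expect_equal(ec$gene_id[ec$expr_class == 5], "g3")
  # g1/g4 tie broken by id: g1 ranks ahead
  expect_lt(ec$expr_class[ec$gene_id == "g1"],
            ec$expr_class[ec$gene_id == "g4"])
  expect_error(expression_classes(genes[1:3, ], fpkm), "at least 5")
})

test_that("genic calls carry oriented TSS distances and length rules", {
  genes <- data.frame(gene_id = c("plus", "minus", "long"),
                      chrom = "c",
                      tss = c(1000L, 9000L, 20000L),
                      tes = c(3900L, 6100L, 25000L),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  calls <- make_calls(c(1200, 8800, 22000), chrom = "c")
  gc <- genic_calls(calls, genes)
  expect_equal(gc$tss_distance[gc$gene_id == "plus"], 200)
  expect_equal(gc$tss_distance[gc$gene_id == "minus"], 200) # 3' of - TSS
  # gene-length rule: short genes keep everything, long genes only [0, 3kb)
  h1 <- make_reads("c", c(1150L, 8750L, 21950L), c(1199L, 8799L, 21999L))
  prof <- genic_nucleosome_profiles(calls, genes, h1, by = "gene_length")
  expect_setequal(names(prof), c("short_gene", "gene_start"))
  expect_equal(unique(prof$short_gene$n_anchors), 2L) # 2.9-kb genes
  expect_equal(unique(prof$gene_start$n_anchors), 1L)

  # call 4 kb into the 5-kb gene is excluded
  far <- make_calls(24000, chrom = "c")
  expect_length(genic_nucleosome_profiles(far, genes[3, , drop = FALSE], h1,
                                          by = "gene_length"), 0)
})

test_that("transcription units take the busier strand on overlap", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "c",
                      tss = c(1000L, 5000L), tes = c(4000L, 2000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  calls <- make_calls(c(3000, 4500, 8000), chrom = "c")
  tu <- transcription_units(calls, genes, c(gp = 10, gm = 3))
  expect_equal(tu$unit, c("bidirectional", "unidirectional", "none"))
  expect_equal(tu$direction, c("+", "-", NA))
  expect_warning(
    tu2 <- transcription_units(calls, genes, c(gp = 3, gm = 3)),
    "tie")
  expect_true(is.na(tu2$direction[1]))
})

test_that("H1 occupancy tracks nucleosome occupancy at generator defaults", {
  cfg <- synthetic_config(chrom_sizes = c(c1 = 150000L))
  plan <- build_plan(cfg, seed = 51)
  mn <- simulate_mnase_reads(plan)
  h1 <- simulate_h1_reads(plan)
  calls <- assign_h1(call_nucleosomes(mn, plan$chrom_sizes), h1)
  rho <- correlation(calls$occupancy, calls$h1_occupancy, n_boot = 100)
  expect_gt(rho$estimate, 0.5)
})
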