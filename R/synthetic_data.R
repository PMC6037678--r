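#' Configuration for the synthetic chromatin generator
#'
#' Defaults describe a compact early-embryo-like chromatin landscape:
#' 147-bp nucleosome cores spaced 175 bp apart on average (so the modal
#' linker is 28 bp, jittered with SD \code{spacing_jitter_sd}),
#' positional fuzziness around 20 bp, roughly 100 MNase reads per
#' nucleosome, and H1 reads concentrated at the two core borders
#' (dyad ± 73 bp, 10-bp jitter) with a minor dyad component. Per-nucleosome
#' MNase read means vary (gamma with CV 0.5) and H1 read means follow them
#' proportionally with lognormal noise, planting a positive
#' H1-vs-nucleosome occupancy correlation. Genes are laid out in
#' equal-width slots with lognormal FPKM; a nucleosome-free gap is planted
#' immediately upstream of each TSS whose width grows with the gene's FPKM
#' rank from \code{nfr_width_range[1]} to \code{nfr_width_range[2]}.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param spacing Mean dyad-to-dyad distance, bp (147 core + 28 modal
#'   linker).
#' @param spacing_jitter_sd SD of the per-step spacing jitter, bp.
#' @param margin Nucleosome-free margin at each chromosome end, bp.
#' @param mean_reads Mean MNase reads per nucleosome.
#' @param read_count_cv Coefficient of variation of per-nucleosome read
#'   means (0 = identical means).
#' @param fuzz_range Per-nucleosome fuzziness SD drawn uniformly from this
#'   range, bp.
#' @param h1_mean_reads Mean H1 reads per nucleosome (the expected H1
#'   reads per chromatosome is not a measured quantity; it is exposed here
#'   as a free parameter).
#' @param h1_noise_sd Lognormal SD coupling H1 means to MNase means.
#' @param h1_skew_range Per-nucleosome H1 border skew drawn uniformly from
#'   this range (in [-1, 1]; -1 all-left, +1 all-right).
#' @param h1_dyad_frac Fraction of H1 reads placed at the dyad.
#' @param h1_jitter_sd SD of H1 placement jitter around each mixture
#'   component, bp.
#' @param read_len Read length, bp (49-bp single-end protocol).
#' @param n_genes Number of genes.
#' @param gene_length Gene length, bp.
#' @param fpkm_meanlog,fpkm_sdlog Lognormal FPKM parameters.
#' @param nfr_width_range Planted upstream-NFR width range (lowest to
#'   highest FPKM rank), bp; both ends must exceed 100 so planted gaps are
#'   NFRs.
#' @param shift_scheme Stage-B repositioning: \code{"none"} (all 0),
#'   \code{"h1_coupled"} (magnitude from \code{shift_magnitudes}, sign from
#'   the nucleosome's H1 skew), or \code{"classes"} (draws from 0, ±35,
#'   ±60, ±200).
#' @param shift_magnitudes Magnitudes used by \code{"h1_coupled"}.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(chrom_sizes = c(chrSim1 = 200000L),
                             spacing = 175L, spacing_jitter_sd = 5,
                             margin = 1000L,
                             mean_reads = 100, read_count_cv = 0.5,
                             fuzz_range = c(20, 20),
                             h1_mean_reads = 50, h1_noise_sd = 0.3,
                             h1_skew_range = c(0, 0), h1_dyad_frac = 0.15,
                             h1_jitter_sd = 10, read_len = 49L,
                             n_genes = 0L, gene_length = 4000L,
                             fpkm_meanlog = 2, fpkm_sdlog = 1.5,
                             nfr_width_range = c(150L, 500L),
                             shift_scheme = c("none", "h1_coupled", "classes"),
                             shift_magnitudes = c(35, 60)) {
  cfg <- list(chrom_sizes = chrom_sizes, spacing = spacing,
              spacing_jitter_sd = spacing_jitter_sd, margin = margin,
              mean_reads = mean_reads, read_count_cv = read_count_cv,
              fuzz_range = fuzz_range, h1_mean_reads = h1_mean_reads,
              h1_noise_sd = h1_noise_sd, h1_skew_range = h1_skew_range,
              h1_dyad_frac = h1_dyad_frac, h1_jitter_sd = h1_jitter_sd,
              read_len = read_len, n_genes = n_genes,
              gene_length = gene_length, fpkm_meanlog = fpkm_meanlog,
              fpkm_sdlog = fpkm_sdlog, nfr_width_range = nfr_width_range,
              shift_scheme = match.arg(shift_scheme),
              shift_magnitudes = shift_magnitudes)
  stopifnot(cfg$spacing >= 147, cfg$h1_dyad_frac >= 0, cfg$h1_dyad_frac <= 1,
            all(cfg$fuzz_range >= 0), all(cfg$nfr_width_range > 100),
            all(abs(cfg$h1_skew_range) <= 1))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Build a genome plan with planted nucleosomes and genes
#'
#' Lays out nucleosome dyads chromosome by chromosome at the configured
#' spacing (jittered, but never closer than 147 bp so cores do not
#' overlap) inside the end margins, places genes in equal-width slots,
#' plants a nucleosome-free gap upstream of every TSS whose width grows
#' with FPKM rank, and draws the per-nucleosome parameters (read means,
#' fuzziness, H1 means, H1 skew, stage-B shift). Deterministic given
#' (config, seed).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List of class \code{genome_plan}: \code{chrom_sizes},
#'   \code{nucleosomes} (data frame: chrom, dyad, mean_reads, fuzz_sigma,
#'   h1_mean_reads, h1_skew, h1_dyad_frac, planted_shift), \code{genes}
#'   (data frame: gene_id, chrom, tss, tes, strand, fpkm, nfr_width),
#'   \code{seed}, \code{config}.
#' @export
build_plan <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  genes <- plan_genes(config)
  nuc <- list()
  for (ch in names(config$chrom_sizes)) {
    len <- config$chrom_sizes[[ch]]
    lo <- config$margin
    hi <- len - config$margin
    if (hi - lo < config$spacing) {
      stop("chromosome ", ch, " too small (", len,
           " bp) for margin ", config$margin, " and spacing ", config$spacing)
    }
    d <- lo
    dyads <- integer(0)
    repeat {
      if (d > hi) break
      dyads <- c(dyads, d)
      step <- config$spacing +
        round(stats::rnorm(1, 0, config$spacing_jitter_sd))
      d <- d + max(147L, as.integer(step))
    }
    nuc[[ch]] <- data.frame(chrom = ch, dyad = dyads,
                            stringsAsFactors = FALSE)
  }
  nuc <- do.call(rbind, nuc)
  rownames(nuc) <- NULL
  # carve planted NFRs: drop nucleosomes whose core intersects the
  # upstream window [tss - w, tss) (strand-mirrored)
  if (nrow(genes)) {
    drop <- rep(FALSE, nrow(nuc))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$strand == "+") {
        w_lo <- g$tss - g$nfr_width
        w_hi <- g$tss
      } else {
        w_lo <- g$tss + 1L
        w_hi <- g$tss + 1L + g$nfr_width
      }
      drop <- drop | (nuc$chrom == g$chrom &
                        nuc$dyad + 73L >= w_lo & nuc$dyad - 73L < w_hi)
    }
    nuc <- nuc[!drop, , drop = FALSE]
    rownames(nuc) <- NULL
  }
  n <- nrow(nuc)
  if (config$read_count_cv > 0) {
    shape <- 1 / config$read_count_cv^2
    nuc$mean_reads <- stats::rgamma(n, shape = shape,
                                    scale = config$mean_reads / shape)
  } else {
    nuc$mean_reads <- rep(config$mean_reads, n)
  }
  nuc$fuzz_sigma <- stats::runif(n, config$fuzz_range[1], config$fuzz_range[2])
  nuc$h1_mean_reads <- config$h1_mean_reads *
    (nuc$mean_reads / config$mean_reads) *
    exp(stats::rnorm(n, 0, config$h1_noise_sd))
  nuc$h1_skew <- stats::runif(n, config$h1_skew_range[1],
                              config$h1_skew_range[2])
  nuc$h1_dyad_frac <- rep(config$h1_dyad_frac, n)
  nuc$planted_shift <- switch(
    config$shift_scheme,
    none = rep(0L, n),
    h1_coupled = as.integer(sign(nuc$h1_skew) *
                              sample(config$shift_magnitudes, n, replace = TRUE)),
    classes = sample(c(0L, 35L, -35L, 60L, -60L, 200L, -200L), n,
                     replace = TRUE))
  plan <- list(chrom_sizes = config$chrom_sizes, nucleosomes = nuc,
               genes = genes, seed = seed, config = config)
  class(plan) <- "genome_plan"
  validate_plan(plan)
  plan
}

plan_genes <- function(config) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      tss = integer(), tes = integer(), strand = character(),
                      fpkm = numeric(), nfr_width = integer(),
                      stringsAsFactors = FALSE)
  if (config$n_genes == 0L) return(empty)
  # genes distributed round-robin across chromosomes, one per slot
  chroms <- rep(names(config$chrom_sizes), length.out = config$n_genes)
  per_chrom <- table(chroms)
  out <- list()
  gid <- 0L
  for (ch in names(per_chrom)) {
    k <- per_chrom[[ch]]
    usable <- config$chrom_sizes[[ch]] - 2L * config$margin
    slot <- usable %/% k
    need <- config$gene_length + max(config$nfr_width_range) + 200L
    if (slot < need) {
      stop("chromosome ", ch, " too small for ", k, " genes of ",
           config$gene_length, " bp plus NFRs (slot ", slot, " < ", need,
           " bp)")
    }
    for (j in seq_len(k)) {
      gid <- gid + 1L
      gstart <- config$margin + (j - 1L) * slot +
        (slot - config$gene_length) %/% 2L
      strand <- sample(c("+", "-"), 1L)
      out[[gid]] <- data.frame(
        gene_id = sprintf("g%03d", gid), chrom = ch,
        tss = if (strand == "+") gstart else gstart + config$gene_length,
        tes = if (strand == "+") gstart + config$gene_length else gstart,
        strand = strand,
        fpkm = stats::rlnorm(1, config$fpkm_meanlog, config$fpkm_sdlog),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, out)
  # NFR width grows with FPKM rank (rank 1 = lowest expression)
  rk <- rank(genes$fpkm, ties.method = "first")
  frac <- if (nrow(genes) > 1L) (rk - 1) / (nrow(genes) - 1) else 1
  genes$nfr_width <- as.integer(round(config$nfr_width_range[1] +
    frac * diff(config$nfr_width_range)))
  rownames(genes) <- NULL
  genes
}

validate_plan <- function(plan) {
  nuc <- plan$nucleosomes
  for (ch in unique(nuc$chrom)) {
    d <- nuc$dyad[nuc$chrom == ch]
    len <- plan$chrom_sizes[[ch]]
    if (any(d < plan$config$margin) || any(d > len - plan$config$margin)) {
      stop("planted dyad outside margins on ", ch)
    }
    if (length(d) > 1L && any(diff(d) < 147L)) {
      stop("planted dyads closer than 147 bp on ", ch)
    }
  }
  stopifnot(all(abs(nuc$planted_shift) <= 200))
  invisible(plan)
}

#' Simulate MNase-seq reads from a genome plan
#'
#' Per nucleosome, a Poisson(\code{mean_reads × depth_factor}) number of
#' 49-bp single-end reads is emitted. Each read's implied dyad is
#' \code{round(Normal(dyad, fuzz_sigma))}; the strand is plus with
#' probability \code{plus_prob}; a plus-strand read starts at
#' implied_dyad − 73 and a minus-strand read's 5' end (its last base) is
#' implied_dyad + 73 — so the 73-bp interior shift applied downstream
#' recovers the implied dyad exactly. Reads that would extend past the
#' chromosome are discarded and counted in the \code{"discarded"}
#' attribute.
#'
#' @param plan A [build_plan()] result.
#' @param read_len Read length, bp (defaults to the plan's config).
#' @param depth_factor Multiplier on every nucleosome's mean read count.
#' @param seed Integer seed.
#' @param plus_prob Probability a read is plus-strand (default 0.5).
#' @return Read data frame (\code{chrom,start,end,strand}) with attribute
#'   \code{discarded}.
#' @export
simulate_mnase_reads <- function(plan, read_len = plan$config$read_len,
                                 depth_factor = 1, seed = plan$seed + 1L,
                                 plus_prob = 0.5) {
  set.seed(seed)
  nuc <- plan$nucleosomes
  counts <- stats::rpois(nrow(nuc), nuc$mean_reads * depth_factor)
  tot <- sum(counts)
  if (tot == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    attr(out, "discarded") <- 0L
    return(out)
  }
  idx <- rep.int(seq_len(nrow(nuc)), counts)
  implied <- as.integer(round(stats::rnorm(tot, nuc$dyad[idx],
                                           nuc$fuzz_sigma[idx])))
  plus <- stats::runif(tot) < plus_prob
  start <- ifelse(plus, implied - 73L, implied + 73L - (read_len - 1L))
  end <- start + read_len
  size <- plan$chrom_sizes[nuc$chrom[idx]]
  ok <- start >= 0L & end <= size
  out <- data.frame(chrom = nuc$chrom[idx][ok],
                    start = as.integer(start[ok]),
                    end = as.integer(end[ok]),
                    strand = ifelse(plus[ok], "+", "-"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "discarded") <- sum(!ok)
  out
}

#' Simulate H1 ChIP reads from a genome plan
#'
#' Per nucleosome, a Poisson(\code{h1_mean_reads × depth_factor}) number of
#' H1 read centers is drawn from a three-component mixture: left border
#' (dyad − 73), right border (dyad + 73) and dyad, with weights
#' \code{(1 − h1_dyad_frac) × (1 − h1_skew)/2},
#' \code{(1 − h1_dyad_frac) × (1 + h1_skew)/2} and \code{h1_dyad_frac};
#' each center is jittered Normal(0, \code{h1_jitter_sd}). Reads are
#' emitted centered on the drawn location, strand random. Out-of-bounds
#' reads are discarded and counted.
#'
#' @inheritParams simulate_mnase_reads
#' @return Read data frame with attribute \code{discarded}.
#' @export
simulate_h1_reads <- function(plan, read_len = plan$config$read_len,
                              depth_factor = 1, seed = plan$seed + 2L) {
  set.seed(seed)
  nuc <- plan$nucleosomes
  counts <- stats::rpois(nrow(nuc), nuc$h1_mean_reads * depth_factor)
  tot <- sum(counts)
  if (tot == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    attr(out, "discarded") <- 0L
    return(out)
  }
  idx <- rep.int(seq_len(nrow(nuc)), counts)
  f <- nuc$h1_dyad_frac[idx]
  s <- nuc$h1_skew[idx]
  u <- stats::runif(tot)
  p_left <- (1 - f) * (1 - s) / 2
  p_right <- (1 - f) * (1 + s) / 2
  comp_off <- ifelse(u < p_left, -73L,
                     ifelse(u < p_left + p_right, 73L, 0L))
  center <- nuc$dyad[idx] + comp_off +
    as.integer(round(stats::rnorm(tot, 0, plan$config$h1_jitter_sd)))
  start <- center - (read_len %/% 2L)
  end <- start + read_len
  size <- plan$chrom_sizes[nuc$chrom[idx]]
  ok <- start >= 0L & end <= size
  out <- data.frame(chrom = nuc$chrom[idx][ok],
                    start = as.integer(start[ok]),
                    end = as.integer(end[ok]),
                    strand = sample(c("+", "-"), sum(ok), replace = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "discarded") <- sum(!ok)
  out
}

#' Simulate a two-stage pair with planted repositioning
#'
#' Stage A reads come from the plan as laid out; stage B reads from the
#' same nucleosomes displaced by their \code{planted_shift}. The truth
#' table records each nucleosome's stage-A and stage-B dyads, shift and
#' class under the dynamics thresholds (≤10 bp fixed, ≥127 bp lost,
#' otherwise shifted).
#'
#' @param plan A [build_plan()] result (shifts come from its
#'   \code{shift_scheme}).
#' @param seed Integer seed; stage A uses \code{seed}, stage B
#'   \code{seed + 1}.
#' @param depth_factor Read-depth multiplier for both stages.
#' @return List: \code{reads_a}, \code{reads_b}, \code{truth} (data frame
#'   chrom, dyad_a, dyad_b, planted_shift, class, h1_skew).
#' @export
simulate_stage_pair <- function(plan, seed = plan$seed + 10L,
                                depth_factor = 1) {
  reads_a <- simulate_mnase_reads(plan, depth_factor = depth_factor,
                                  seed = seed)
  plan_b <- plan
  plan_b$nucleosomes$dyad <- plan$nucleosomes$dyad +
    plan$nucleosomes$planted_shift
  ord <- order(plan_b$nucleosomes$chrom, plan_b$nucleosomes$dyad)
  plan_b$nucleosomes <- plan_b$nucleosomes[ord, , drop = FALSE]
  reads_b <- simulate_mnase_reads(plan_b, depth_factor = depth_factor,
                                  seed = seed + 1L)
  nuc <- plan$nucleosomes
  mag <- abs(nuc$planted_shift)
  truth <- data.frame(
    chrom = nuc$chrom, dyad_a = nuc$dyad,
    dyad_b = nuc$dyad + nuc$planted_shift,
    planted_shift = nuc$planted_shift,
    class = ifelse(mag <= 10, "fixed", ifelse(mag >= 127, "lost", "shifted")),
    h1_skew = nuc$h1_skew, stringsAsFactors = FALSE)
  list(reads_a = reads_a, reads_b = reads_b, truth = truth)
}
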