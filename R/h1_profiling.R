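#' Read anchor points (centers) of mapped reads
#'
#' Each H1 ChIP read is taken to mark one bound H1. Its location is the
#' read-interval midpoint by default; a 5'-end mode is available.
#'
#' @param reads Read data frame (\code{chrom,start,end,strand}).
#' @param mode \code{"midpoint"} (default) or \code{"5prime"}.
#' @return Integer vector of per-read coordinates.
#' @export
read_centers <- function(reads, mode = c("midpoint", "5prime")) {
  mode <- match.arg(mode)
  if (mode == "midpoint") {
    as.integer((reads$start + reads$end - 1L) %/% 2L)
  } else {
    as.integer(ifelse(reads$strand == "+", reads$start, reads$end - 1L))
  }
}

#' Assign H1 ChIP reads to nucleosomes
#'
#' An H1 read is assigned to the nucleosome whose 147-bp core
#' (dyad ± 73 bp) it overlaps by at least 1 bp; a read overlapping two
#' cores goes to the one with the greater overlap, ties to the left. Each
#' read is assigned at most once. Per nucleosome the function returns the
#' H1 read count, RPNM-normalized H1 occupancy, H1 fuzziness (population SD
#' of assigned read centers), the read-center counts in the two border
#' windows (dyad ± 73 ± 20 bp) and the border-skew score
#' \code{(R − L)/(R + L)} (0 when both borders are empty).
#'
#' @param calls Nucleosome-call data frame, sorted by dyad within
#'   chromosome.
#' @param h1_reads H1 read data frame.
#' @param total_mapped H1 library size for RPNM; defaults to
#'   \code{nrow(h1_reads)}.
#' @param center_mode Read-location mode, see [read_centers()].
#' @param border Distance from dyad to border-window center, bp
#'   (default 73).
#' @param border_half_width Border-window half width, bp (default 20, so
#'   windows span dyad ± [53, 93]).
#' @return \code{calls} with columns \code{h1_count}, \code{h1_occupancy},
#'   \code{h1_fuzziness}, \code{left_border}, \code{right_border},
#'   \code{skew} added; attributes \code{assignment} (per-read call row or
#'   NA) and \code{unassigned} (count).
#' @export
assign_h1 <- function(calls, h1_reads, total_mapped = nrow(h1_reads),
                      center_mode = "midpoint", border = 73L,
                      border_half_width = 20L) {
  n_call <- nrow(calls)
  assignment <- rep(NA_integer_, nrow(h1_reads))
  centers <- read_centers(h1_reads, center_mode)
  for (ch in unique(calls$chrom)) {
    ic <- which(calls$chrom == ch)
    ir <- which(h1_reads$chrom == ch)
    if (!length(ir)) next
    dy <- calls$dyad[ic]
    if (is.unsorted(dy)) stop("calls must be sorted within chromosome")
    s <- h1_reads$start[ir]
    e <- h1_reads$end[ir]
    k <- findInterval(centers[ir], dy)
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(dy))
    # overlap of the read with each candidate 147-bp core [dyad-73, dyad+74)
    ov_l <- pmin(e, dy[left] + 74L) - pmax(s, dy[left] - 73L)
    ov_r <- pmin(e, dy[right] + 74L) - pmax(s, dy[right] - 73L)
    pick <- ifelse(ov_l >= ov_r, left, right) # tie -> left core
    ov <- pmax(ov_l, ov_r)
    assignment[ir] <- ifelse(ov >= 1L, ic[pick], NA_integer_)
  }
  groups <- split(centers, factor(assignment, levels = seq_len(n_call)))
  cnt <- lengths(groups)
  calls$h1_count <- as.integer(cnt)
  calls$h1_occupancy <- if (total_mapped > 0) cnt * 1e6 / total_mapped else 0
  calls$h1_fuzziness <- vapply(groups, function(x) {
    if (!length(x)) NA_real_ else sqrt(mean((x - mean(x))^2))
  }, 0)
  off <- mapply(function(x, d) x - d, groups, calls$dyad, SIMPLIFY = FALSE)
  lo <- border - border_half_width
  hi <- border + border_half_width
  calls$left_border <- vapply(off, function(o) sum(o >= -hi & o <= -lo), 0L)
  calls$right_border <- vapply(off, function(o) sum(o >= lo & o <= hi), 0L)
  calls$skew <- skew_score(calls$left_border, calls$right_border)
  attr(calls, "assignment") <- assignment
  attr(calls, "unassigned") <- sum(is.na(assignment))
  calls
}

#' Border-skew score
#'
#' Normalized left/right asymmetry of H1 signal at the two nucleosome core
#' edges: \code{(right − left)/(right + left)}, in [−1, 1]; 0 when both
#' sides are empty. Negative values mean H1 deviates to the left of the
#' dyad, positive to the right.
#'
#' @param left,right Non-negative border signals (counts or occupancies).
#' @return Numeric vector of skew scores.
#' @export
skew_score <- function(left, right) {
  tot <- left + right
  ifelse(tot > 0, (right - left) / tot, 0)
}

#' Composite profile of H1 around a set of anchors
#'
#' Aggregates H1 read locations relative to anchor points (nucleosome dyads
#' or TSSs): every read center within ± \code{window} of an anchor
#' contributes its offset (sign-flipped for minus-orientation anchors, so
#' profiles read 5' to 3'), offsets are accumulated into \code{bin_width}-bp
#' bins, counts are normalized to reads per million mapped and the binned
#' values are smoothed with a centered \code{smooth_bins}-bin moving average
#' (step 1, truncated at the profile edges).
#'
#' @param anchors Data frame with \code{chrom}, \code{pos} and optionally
#'   \code{orientation} (+1/−1; default +1).
#' @param h1_reads H1 read data frame.
#' @param window Profile half-width, bp (default 1000).
#' @param bin_width Bin width, bp (default 10).
#' @param smooth_bins Moving-average width in bins (default 5).
#' @param total_mapped H1 library size for normalization; defaults to
#'   \code{nrow(h1_reads)}.
#' @param center_mode Read-location mode, see [read_centers()].
#' @return Data frame \code{bin_center} (bp relative to anchor),
#'   \code{value} (smoothed reads-per-million), \code{raw_count},
#'   \code{n_anchors}.
#' @export
composite_profile <- function(anchors, h1_reads, window = 1000L,
                              bin_width = 10L, smooth_bins = 5L,
                              total_mapped = nrow(h1_reads),
                              center_mode = "midpoint") {
  if (!nrow(anchors)) stop("anchor list is empty")
  orient <- if ("orientation" %in% names(anchors)) anchors$orientation else rep(1L, nrow(anchors))
  centers <- read_centers(h1_reads, center_mode)
  n_bins <- as.integer(2L * window / bin_width)
  counts <- numeric(n_bins)
  for (ch in unique(anchors$chrom)) {
    ia <- which(anchors$chrom == ch)
    cc <- sort(centers[h1_reads$chrom == ch])
    if (!length(cc)) next
    for (j in ia) {
      p <- anchors$pos[j]
      lo <- findInterval(p - window - 1L, cc) + 1L
      hi <- findInterval(p + window, cc)
      if (lo > hi) next
      off <- (cc[lo:hi] - p) * orient[j]
      off <- off[off >= -window & off < window]
      if (!length(off)) next
      b <- (off + window) %/% bin_width + 1L
      tb <- tabulate(b, nbins = n_bins)
      counts <- counts + tb
    }
  }
  norm <- if (total_mapped > 0) counts * 1e6 / total_mapped else counts
  data.frame(
    bin_center = as.numeric(seq_len(n_bins) - 1L) * bin_width - window + bin_width / 2,
    value = moving_average(norm, smooth_bins),
    raw_count = counts,
    n_anchors = nrow(anchors))
}

#' Centered moving average with truncated edges
#'
#' At positions closer than half the window to an edge, the average is over
#' the available values only (no padding), keeping total mass
#' interpretable.
#'
#' @param x Numeric vector.
#' @param k Window width (odd; default 5).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, k = 5L) {
  if (k <= 1L) return(x)
  h <- k %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' H1:nucleosome occupancy ratio by group
#'
#' Per nucleosome the ratio of H1 occupancy to nucleosome occupancy (both
#' RPNM, so sequencing depth cancels); per group the mean ratio with a
#' percentile bootstrap confidence interval.
#'
#' @param calls Nucleosome calls with \code{occupancy} and
#'   \code{h1_occupancy} columns (from [assign_h1()]).
#' @param grouping Factor/vector of group labels, one per call (NA drops
#'   the call).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame \code{group}, \code{n}, \code{mean_ratio},
#'   \code{ci_lo}, \code{ci_hi}.
#' @export
ratio_profile <- function(calls, grouping, n_boot = 1000L, conf = 0.95,
                          seed = 1L) {
  ratio <- ifelse(calls$occupancy > 0, calls$h1_occupancy / calls$occupancy, NA)
  keep <- !is.na(grouping) & !is.na(ratio)
  ratio <- ratio[keep]
  grouping <- grouping[keep]
  set.seed(seed)
  alpha <- (1 - conf) / 2
  res <- lapply(split(ratio, grouping), function(r) {
    bm <- vapply(seq_len(n_boot), function(i) {
      mean(r[sample.int(length(r), replace = TRUE)])
    }, 0)
    c(n = length(r), mean_ratio = mean(r),
      ci_lo = unname(stats::quantile(bm, alpha)),
      ci_hi = unname(stats::quantile(bm, 1 - alpha)))
  })
  out <- data.frame(group = names(res), do.call(rbind, res),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Matched extreme sets within statistic-controlled groups
#'
#' Groups nucleosomes into intervals of one statistic (so that statistic is
#' near-constant within a group) and, within each group, selects the k
#' highest and k lowest nucleosomes by the complementary statistic. If a
#' group holds fewer than 2k members, k shrinks to half the group (median
#' split) with a warning, so the two sets stay disjoint.
#'
#' @param calls Nucleosome-call data frame.
#' @param key Column name to group on (\code{"fuzziness"} or
#'   \code{"occupancy"}).
#' @param interval Group interval width in the key's units (e.g. 5 for
#'   fuzziness, 0.4 for occupancy).
#' @param select_by Column to rank within groups (the complementary
#'   statistic).
#' @param k Target set size (default 10000).
#' @return Data frame \code{group} (interval label), \code{call} (row
#'   index), \code{set} (\code{"top"} or \code{"bottom"}).
#' @export
group_and_select <- function(calls, key, interval, select_by, k = 10000L) {
  v <- calls[[key]]
  g <- floor(v / interval)
  lab <- sprintf("[%g,%g)", g * interval, (g + 1) * interval)
  out <- lapply(split(seq_len(nrow(calls)), lab), function(idx) {
    n <- length(idx)
    kk <- k
    if (n < 2L * k) {
      kk <- n %/% 2L
      warning("group of ", n, " smaller than 2k; using median split (k = ",
              kk, ")", call. = FALSE)
    }
    if (kk == 0L) return(NULL)
    ord <- idx[order(calls[[select_by]][idx], idx)]
    data.frame(call = c(utils::tail(ord, kk), utils::head(ord, kk)),
               set = rep(c("top", "bottom"), each = kk),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(out, is.null, TRUE)
  labs <- rep(names(out)[keep], vapply(out[keep], nrow, 0L))
  out <- do.call(rbind, out[keep])
  if (is.null(out)) {
    return(data.frame(group = character(), call = integer(),
                      set = character()))
  }
  out <- data.frame(group = labs, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Split genes into expression classes
#'
#' Ranks genes by FPKM (descending; ties broken by gene id for
#' determinism) and splits them into equal-count classes; class 1 is the
#' top quantile. Genes absent from the expression table are excluded.
#'
#' @param genes Gene-model data frame.
#' @param fpkm Named FPKM vector (gene_id -> FPKM).
#' @param quantiles Number of classes (default 5).
#' @return Data frame of the covered genes with \code{fpkm} and
#'   \code{expr_class} (integer, 1 = most expressed) columns added.
#' @export
expression_classes <- function(genes, fpkm, quantiles = 5L) {
  g <- genes[genes$gene_id %in% names(fpkm), , drop = FALSE]
  if (nrow(g) < quantiles) {
    stop("need at least ", quantiles, " genes with expression, got ", nrow(g))
  }
  g$fpkm <- unname(fpkm[g$gene_id])
  ord <- order(-g$fpkm, g$gene_id)
  g <- g[ord, , drop = FALSE]
  g$expr_class <- as.integer(ceiling(seq_len(nrow(g)) / (nrow(g) / quantiles)))
  rownames(g) <- NULL
  g
}

#' Directed TSS-anchored H1 profiles per expression class
#'
#' Genes are split into expression classes ([expression_classes()]); for
#' each class a directed composite H1 profile is computed anchored at the
#' TSS with orientation following transcription (minus-strand genes are
#' flipped so the x axis reads 5' to 3').
#'
#' @param genes Gene-model data frame.
#' @param fpkm Named FPKM vector.
#' @param h1_reads H1 read data frame.
#' @param quantiles Number of expression classes (default 5).
#' @param ... Passed to [composite_profile()].
#' @return Named list of profile data frames, \code{"class1"} (top
#'   expression) through \code{"class<q>"}.
#' @export
tss_profiles_by_expression <- function(genes, fpkm, h1_reads, quantiles = 5L,
                                       ...) {
  g <- expression_classes(genes, fpkm, quantiles)
  out <- lapply(seq_len(quantiles), function(q) {
    gg <- g[g$expr_class == q, , drop = FALSE]
    anchors <- data.frame(chrom = gg$chrom, pos = gg$tss,
                          orientation = ifelse(gg$strand == "+", 1L, -1L),
                          stringsAsFactors = FALSE)
    composite_profile(anchors, h1_reads, ...)
  })
  names(out) <- paste0("class", seq_len(quantiles))
  out
}

#' Map genic nucleosome calls to their genes
#'
#' A call is genic for a gene when its dyad lies inside the gene span. The
#' oriented TSS distance is positive downstream of the TSS in the direction
#' of transcription (so for a minus-strand gene, positive means smaller
#' coordinates).
#'
#' @param calls Nucleosome-call data frame.
#' @param genes Gene-model data frame.
#' @return Data frame \code{call}, \code{gene_id}, \code{strand},
#'   \code{tss_distance} (oriented bp), \code{gene_length}; one row per
#'   (call, containing gene) pair.
#' @export
genic_calls <- function(calls, genes) {
  res <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- min(g$tss, g$tes)
    hi <- max(g$tss, g$tes)
    idx <- which(calls$chrom == g$chrom & calls$dyad >= lo & calls$dyad <= hi)
    if (!length(idx)) next
    dist <- if (g$strand == "+") calls$dyad[idx] - g$tss else g$tss - calls$dyad[idx]
    res[[length(res) + 1L]] <- data.frame(
      call = idx, gene_id = g$gene_id, strand = g$strand,
      tss_distance = dist, gene_length = abs(g$tes - g$tss),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(call = integer(), gene_id = character(),
                      strand = character(), tss_distance = numeric(),
                      gene_length = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Directed dyad-anchored H1 profiles of genic nucleosomes
#'
#' Genic calls inherit their gene's transcription direction; directed
#' composite H1 profiles anchored at the dyads are computed per group.
#' Grouping is either by oriented distance-to-TSS bins
#' (\code{by = "tss_distance"}, half-open \code{[lo, hi)} bins from
#' \code{tss_bins}) or by the short-gene/gene-start rule
#' (\code{by = "gene_length"}): genes shorter than 3 kb contribute all
#' their calls, genes of 3 kb or more only calls with oriented TSS distance
#' in [0, 3000).
#'
#' @param calls Nucleosome-call data frame.
#' @param genes Gene-model data frame.
#' @param h1_reads H1 read data frame.
#' @param by \code{"tss_distance"} or \code{"gene_length"}.
#' @param tss_bins Bin edges for \code{by = "tss_distance"}.
#' @param length_cutoff Gene-length cutoff in bp (default 3000).
#' @param ... Passed to [composite_profile()].
#' @return Named list of profile data frames (one per group); groups with
#'   no anchors are dropped.
#' @export
genic_nucleosome_profiles <- function(calls, genes, h1_reads,
                                      by = c("tss_distance", "gene_length"),
                                      tss_bins = c(0, 500, 1000, 2000, 3000),
                                      length_cutoff = 3000L, ...) {
  by <- match.arg(by)
  gc <- genic_calls(calls, genes)
  if (!nrow(gc)) return(list())
  if (by == "tss_distance") {
    b <- findInterval(gc$tss_distance, tss_bins, rightmost.closed = FALSE)
    ok <- b >= 1L & b < length(tss_bins)
    gc <- gc[ok, , drop = FALSE]
    grp <- sprintf("[%g,%g)", tss_bins[b[ok]], tss_bins[b[ok] + 1L])
  } else {
    ok <- gc$gene_length < length_cutoff |
      (gc$tss_distance >= 0 & gc$tss_distance < length_cutoff)
    gc <- gc[ok, , drop = FALSE]
    grp <- ifelse(gc$gene_length < length_cutoff, "short_gene", "gene_start")
  }
  out <- lapply(split(seq_len(nrow(gc)), grp), function(idx) {
    anchors <- data.frame(
      chrom = calls$chrom[gc$call[idx]],
      pos = calls$dyad[gc$call[idx]],
      orientation = ifelse(gc$strand[idx] == "+", 1L, -1L),
      stringsAsFactors = FALSE)
    composite_profile(anchors, h1_reads, ...)
  })
  out
}

#' Transcription-unit class and effective direction per call
#'
#' Calls inside exactly one gene (or several genes all on one strand) are
#' unidirectional with that strand; calls inside overlapping plus- and
#' minus-strand genes are bidirectional, taking the direction of the gene
#' with the higher FPKM. An FPKM tie between opposite strands excludes the
#' call (direction NA) with a warning.
#'
#' @param calls Nucleosome-call data frame.
#' @param genes Gene-model data frame.
#' @param fpkm Named FPKM vector.
#' @return Data frame, one row per call: \code{unit} (\code{"none"},
#'   \code{"unidirectional"}, \code{"bidirectional"}) and
#'   \code{direction} (\code{"+"}, \code{"-"}, or NA).
#' @export
transcription_units <- function(calls, genes, fpkm) {
  gc <- genic_calls(calls, genes)
  unit <- rep("none", nrow(calls))
  direction <- rep(NA_character_, nrow(calls))
  ties <- 0L
  for (grp in split(seq_len(nrow(gc)), gc$call)) {
    i <- gc$call[grp[1L]]
    strands <- unique(gc$strand[grp])
    if (length(strands) == 1L) {
      unit[i] <- "unidirectional"
      direction[i] <- strands
    } else {
      unit[i] <- "bidirectional"
      f <- fpkm[gc$gene_id[grp]]
      f[is.na(f)] <- 0
      best <- which(f == max(f))
      dirs <- unique(gc$strand[grp][best])
      if (length(dirs) == 1L) {
        direction[i] <- dirs
      } else {
        ties <- ties + 1L
      }
    }
  }
  if (ties > 0L) {
    warning(ties, " bidirectional call(s) excluded on FPKM tie",
            call. = FALSE)
  }
  data.frame(unit = unit, direction = direction, stringsAsFactors = FALSE)
}
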