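#' Shift single-end reads to nucleosome dyad estimates
#'
#' Each mapped read is moved 73 bp interior to its 5' end so that it points
#' at the dyad of the nucleosome that protected it: a plus-strand read's
#' dyad is \code{start + offset}; a minus-strand read's 5' end is its last
#' base (\code{end - 1}), so its dyad is \code{end - 1 - offset}.
#'
#' @param reads Read data frame (\code{chrom,start,end,strand}).
#' @param offset Interior shift in bp (default 73, half a 147-bp core).
#' @param chrom_sizes Optional named vector of chromosome lengths; dyads
#'   falling outside \code{[0, size)} are dropped and counted in the
#'   \code{"dropped"} attribute of the result.
#' @return Data frame \code{chrom, dyad}, one row per retained read, with
#'   attribute \code{dropped} (count of out-of-bounds dyads).
#' @export
shift_reads_to_dyads <- function(reads, offset = 73L, chrom_sizes = NULL) {
  dyad <- ifelse(reads$strand == "+",
                 reads$start + offset,
                 (reads$end - 1L) - offset)
  out <- data.frame(chrom = reads$chrom, dyad = as.integer(dyad),
                    stringsAsFactors = FALSE)
  dropped <- 0L
  if (!is.null(chrom_sizes)) {
    size <- chrom_sizes[out$chrom]
    ok <- out$dyad >= 0L & !is.na(size) & out$dyad < size
    dropped <- sum(!ok)
    out <- out[ok, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- dropped
  out
}

#' Gaussian-smoothed dyad density
#'
#' The per-base dyad density used for peak calling:
#' \code{density(x) = sum_d exp(-(x - d)^2 / (2 sigma^2))} over all dyads
#' \code{d}, with the kernel truncated at \code{±4 sigma}. The total density
#' is \code{n_dyads * sigma * sqrt(2*pi)} up to truncation error.
#'
#' @param dyads Integer vector of dyad coordinates (0-based) on one
#'   chromosome.
#' @param sigma Kernel SD in bp (> 0).
#' @param chrom_len Length of the returned vector; element \code{i} is the
#'   density at 0-based position \code{i - 1}.
#' @return Numeric vector of length \code{chrom_len}.
#' @export
smooth_dyad_signal <- function(dyads, sigma, chrom_len) {
  stopifnot(sigma > 0, chrom_len >= 1)
  counts <- tabulate(dyads + 1L, nbins = chrom_len)
  half <- as.integer(ceiling(4 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  # open convolution, then trim the kernel wings
  full <- convolve(counts, rev(kern), type = "open")
  full[(half + 1L):(half + chrom_len)]
}

#' Greedy exclusion-zone peak calling
#'
#' Repeatedly takes the highest remaining density position as a nucleosome
#' call, then removes all positions closer than \code{exclusion_width} to it
#' from further consideration, so called dyads on a chromosome end up at
#' least \code{exclusion_width} apart (non-overlapping 147-bp cores at the
#' default). Ties are broken toward the smaller coordinate; zero-density
#' positions are never called.
#'
#' @param density Per-base density vector (element i = position i-1).
#' @param exclusion_width Minimum spacing between calls in bp (default 147).
#' @return Sorted integer vector of called dyad coordinates (0-based).
#' @export
call_peaks <- function(density, exclusion_width = 147L) {
  stopifnot(all(is.finite(density)))
  n <- length(density)
  pos <- which(density > 0)
  if (!length(pos)) return(integer(0))
  pos <- pos[order(-density[pos], pos)]
  excluded <- logical(n)
  calls <- integer(0)
  w <- as.integer(exclusion_width) - 1L
  for (p in pos) {
    if (excluded[p]) next
    calls <- c(calls, p)
    excluded[max(1L, p - w):min(n, p + w)] <- TRUE
  }
  sort(calls) - 1L
}

#' Assign read dyads to nucleosome calls
#'
#' Each read dyad goes to the nearest called dyad, provided it lies within
#' \code{±half_window} bp of it (strictly more than \code{half_window} away
#' means unassigned). A dyad exactly equidistant between two calls goes to
#' the left one.
#'
#' @param calls Sorted integer vector of called dyads on one chromosome.
#' @param dyads Integer vector of read dyads on the same chromosome.
#' @param half_window Assignment half-window in bp (default 73).
#' @return Integer vector the length of \code{dyads}: the index into
#'   \code{calls} of each read's nucleosome, or \code{NA} if unassigned.
#' @export
assign_reads <- function(calls, dyads, half_window = 73L) {
  if (!length(calls)) return(rep(NA_integer_, length(dyads)))
  if (is.unsorted(calls)) stop("calls must be sorted")
  # nearest call: candidates are the calls flanking each dyad
  right <- findInterval(dyads, calls) # index of largest call <= dyad... see below
  # findInterval gives i with calls[i] <= dyad < calls[i+1]
  left_idx <- pmax(right, 1L)
  right_idx <- pmin(right + 1L, length(calls))
  dl <- abs(dyads - calls[left_idx])
  dr <- abs(dyads - calls[right_idx])
  # tie (dl == dr) -> left call
  nearest <- ifelse(dl <= dr, left_idx, right_idx)
  dist <- pmin(dl, dr)
  nearest[dist > half_window] <- NA_integer_
  as.integer(nearest)
}

#' Occupancy (RPNM) and fuzziness of one nucleosome
#'
#' Occupancy is reads per nucleosome per million mapped reads:
#' \code{count * 1e6 / total_mapped}. Fuzziness is the population standard
#' deviation (divide by n, no sample correction) of the read dyad
#' coordinates defining the nucleosome; a single read has fuzziness 0.
#'
#' @param read_dyads Integer vector of this nucleosome's read dyads.
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return List with \code{occupancy} and \code{fuzziness}.
#' @export
occupancy_and_fuzziness <- function(read_dyads, total_mapped) {
  stopifnot(total_mapped > 0)
  n <- length(read_dyads)
  occ <- n * 1e6 / total_mapped
  fuzz <- if (n == 0L) NA_real_ else sqrt(mean((read_dyads - mean(read_dyads))^2))
  list(occupancy = occ, fuzziness = fuzz)
}

#' Filter nucleosome calls by minimum occupancy
#'
#' Keeps calls whose RPNM is at least \code{min_rpnm} (inclusive: a call at
#' exactly the threshold is retained).
#'
#' @param calls Nucleosome-call data frame with an \code{occupancy} column.
#' @param min_rpnm Minimum RPNM (default 0.1).
#' @return Filtered data frame.
#' @export
filter_calls <- function(calls, min_rpnm = 0.1) {
  out <- calls[calls$occupancy >= min_rpnm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate calls as promoter / genic / intergenic
#'
#' Assignment is by the nucleosome midpoint (the dyad): inside the
#' strand-adjusted window \code{[TSS - promoter_window, TSS)} of any gene
#' (mirrored for minus-strand genes) it is \code{promoter}; otherwise inside
#' any gene span it is \code{genic}; otherwise \code{intergenic}. Promoter
#' takes precedence over genic on overlap.
#'
#' @param calls Nucleosome-call data frame (\code{chrom}, \code{dyad}).
#' @param genes Gene-model data frame.
#' @param promoter_window Upstream window size in bp (default 500).
#' @return \code{calls} with a \code{context} column added.
#' @export
annotate_context <- function(calls, genes, promoter_window = 500L) {
  context <- rep("intergenic", nrow(calls))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    on_chr <- calls$chrom == g$chrom
    if (!any(on_chr)) next
    d <- calls$dyad
    if (g$strand == "+") {
      prom <- on_chr & d >= g$tss - promoter_window & d < g$tss
      body <- on_chr & d >= g$tss & d < g$tes
    } else {
      prom <- on_chr & d > g$tss & d <= g$tss + promoter_window
      body <- on_chr & d > g$tes & d <= g$tss
    }
    context[body & context == "intergenic"] <- "genic"
    context[prom] <- "promoter"
  }
  calls$context <- context
  calls
}

#' Call nucleosomes from mapped MNase-seq reads
#'
#' The full per-chromosome calling pipeline: shift reads to dyads, smooth
#' with a Gaussian kernel, pick peaks greedily with an exclusion zone,
#' assign read dyads to calls, compute occupancy (RPNM) and fuzziness, drop
#' empty calls and apply the minimum-occupancy filter.
#'
#' @param reads Read data frame (\code{chrom,start,end,strand}).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param sigma Smoothing kernel SD in bp (default 20).
#' @param exclusion_width Minimum call spacing in bp (default 147).
#' @param shift_offset Read-to-dyad shift in bp (default 73).
#' @param half_window Read assignment half-window in bp (default 73).
#' @param min_rpnm Minimum occupancy to retain a call (default 0.1).
#' @param total_mapped Library size for RPNM; defaults to \code{nrow(reads)}.
#' @return Data frame with one row per retained nucleosome: \code{chrom},
#'   \code{dyad}, \code{n_reads}, \code{occupancy}, \code{fuzziness}. The
#'   attribute \code{read_dyads} holds the per-call read-dyad lists (in row
#'   order); \code{unassigned} holds the count of read dyads assigned to no
#'   call.
#' @export
call_nucleosomes <- function(reads, chrom_sizes, sigma = 20, exclusion_width = 147L,
                             shift_offset = 73L, half_window = 73L,
                             min_rpnm = 0.1, total_mapped = nrow(reads)) {
  dy <- shift_reads_to_dyads(reads, offset = shift_offset,
                             chrom_sizes = chrom_sizes)
  res <- list()
  rd_lists <- list()
  unassigned <- 0L
  for (ch in names(chrom_sizes)) {
    d <- dy$dyad[dy$chrom == ch]
    if (!length(d)) next
    dens <- smooth_dyad_signal(d, sigma, chrom_sizes[[ch]])
    peaks <- call_peaks(dens, exclusion_width)
    if (!length(peaks)) next
    idx <- assign_reads(peaks, d, half_window)
    unassigned <- unassigned + sum(is.na(idx))
    groups <- split(d, factor(idx, levels = seq_along(peaks)))
    n <- lengths(groups)
    keep <- n > 0L
    if (!any(keep)) next
    of <- lapply(groups[keep], occupancy_and_fuzziness, total_mapped = total_mapped)
    res[[ch]] <- data.frame(
      chrom = ch, dyad = peaks[keep], n_reads = n[keep],
      occupancy = vapply(of, `[[`, 0, "occupancy"),
      fuzziness = vapply(of, `[[`, 0, "fuzziness"),
      stringsAsFactors = FALSE)
    rd_lists[[ch]] <- groups[keep]
  }
  if (!length(res)) {
    out <- data.frame(chrom = character(), dyad = integer(),
                      n_reads = integer(), occupancy = numeric(),
                      fuzziness = numeric(), stringsAsFactors = FALSE)
    attr(out, "read_dyads") <- list()
    attr(out, "unassigned") <- unassigned
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  rd <- do.call(c, rd_lists)
  keep <- out$occupancy >= min_rpnm
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "read_dyads") <- unname(rd[keep])
  attr(out, "unassigned") <- unassigned
  out
}
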