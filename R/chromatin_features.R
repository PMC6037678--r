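# Nucleosome core width used for all linker arithmetic. A fixed constant
# (dyad +/- 73 bp), not a tunable: downstream windows (H1 borders, NFR
# definitions) assume it.
CORE_WIDTH <- 147L

#' Linkers between adjacent nucleosome calls
#'
#' One linker per adjacent pair of calls on the same chromosome, taking the
#' nucleosome core as dyad ± 73 bp: linker length = Δdyad − 147. Length 0
#' means touching cores; a negative length means the caller produced
#' overlapping cores, which is an error.
#'
#' @param calls Nucleosome-call data frame (\code{chrom}, \code{dyad}),
#'   sorted by dyad within each chromosome.
#' @return Data frame with one row per linker: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open gap between the cores), \code{length},
#'   \code{upstream}, \code{downstream} (row indices into \code{calls}).
#' @export
compute_linkers <- function(calls) {
  out <- lapply(split(seq_len(nrow(calls)), calls$chrom), function(idx) {
    if (length(idx) < 2L) return(NULL)
    d <- calls$dyad[idx]
    if (is.unsorted(d)) stop("calls must be sorted by dyad within chromosome")
    up <- idx[-length(idx)]
    down <- idx[-1L]
    len <- diff(d) - CORE_WIDTH
    if (any(len < 0L)) {
      stop("adjacent dyads closer than ", CORE_WIDTH,
           " bp (overlapping cores): caller bug")
    }
    data.frame(chrom = calls$chrom[up],
               start = calls$dyad[up] + 74L,
               end = calls$dyad[down] - 73L,
               length = len, upstream = up, downstream = down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), upstream = integer(),
                      downstream = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Nucleosome-free regions
#'
#' Linkers longer than 100 bp are NFRs (also called nucleosome-depleted
#' regions, NDRs). The default is the strict inequality > 100; setting
#' \code{inclusive = TRUE} uses >= 100 (a "100 bp or larger" variant).
#'
#' @param linkers Linker data frame from [compute_linkers()].
#' @param min_length NFR length threshold in bp (default 100).
#' @param inclusive Use \code{>=} instead of the default strict \code{>}.
#' @return Subset of \code{linkers} that qualify as NFRs.
#' @export
find_nfrs <- function(linkers, min_length = 100L, inclusive = FALSE) {
  keep <- if (inclusive) linkers$length >= min_length else linkers$length > min_length
  out <- linkers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nucleosome arrays
#'
#' Maximal runs of three or more consecutive nucleosomes none of whose
#' internal linkers exceeds 100 bp ("beads on a string" with short
#' linkers). A linker of exactly 100 bp does not break an array.
#'
#' @param calls Nucleosome-call data frame.
#' @param linkers Linker data frame from [compute_linkers()].
#' @param max_linker Largest linker allowed inside an array (default 100).
#' @param min_members Minimum run length (default 3).
#' @return List of integer vectors, each the row indices (into
#'   \code{calls}) of one array's members, in genomic order.
#' @export
find_arrays <- function(calls, linkers, max_linker = 100L, min_members = 3L) {
  arrays <- list()
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    if (length(idx) < min_members) next
    lk <- linkers[linkers$chrom == ch, , drop = FALSE]
    # linker i joins idx[i] and idx[i+1]; a long linker breaks the run
    breaks <- lk$length > max_linker
    run_id <- cumsum(c(0L, breaks))
    for (r in split(idx, run_id)) {
      if (length(r) >= min_members) arrays[[length(arrays) + 1L]] <- r
    }
  }
  arrays
}

#' Orphan nucleosomes
#'
#' Calls flanked by an NFR on each side: both adjacent linkers exist (so
#' chromosome-terminal nucleosomes are never orphans) and both are NFRs.
#' Such calls are provably in no array.
#'
#' @param calls Nucleosome-call data frame.
#' @param linkers Linker data frame.
#' @param nfrs NFR data frame from [find_nfrs()].
#' @return Integer vector of orphan row indices into \code{calls}.
#' @export
find_orphans <- function(calls, linkers, nfrs) {
  is_nfr_up <- calls_flank(nrow(calls), nfrs$downstream) # NFR upstream of call
  is_nfr_down <- calls_flank(nrow(calls), nfrs$upstream) # NFR downstream of call
  has_up <- calls_flank(nrow(calls), linkers$downstream)
  has_down <- calls_flank(nrow(calls), linkers$upstream)
  which(has_up & has_down & is_nfr_up & is_nfr_down)
}

calls_flank <- function(n, idx) {
  out <- logical(n)
  out[idx] <- TRUE
  out
}

#' Phasogram of adjacent dyad-to-dyad distances
#'
#' Histogram of the distance between adjacent called dyads within each
#' chromosome (no cross-chromosome pairs), normalized to sum 1 over the
#' range \code{[147, max_dist]}. The mode reveals the nucleosome repeat
#' length (core 147 bp + modal linker).
#'
#' @param calls Nucleosome-call data frame, sorted within chromosome.
#' @param max_dist Largest distance kept, in bp (default 1000).
#' @return Data frame \code{distance}, \code{count}, \code{frequency} with
#'   one row per observed distance in range.
#' @export
phasogram <- function(calls, max_dist = 1000L) {
  dists <- unlist(lapply(split(calls$dyad, calls$chrom), function(d) {
    if (length(d) < 2L) return(integer(0))
    diff(sort(d))
  }), use.names = FALSE)
  dists <- dists[dists >= CORE_WIDTH & dists <= max_dist]
  if (!length(dists)) {
    return(data.frame(distance = integer(), count = integer(),
                      frequency = numeric()))
  }
  tab <- table(dists)
  data.frame(distance = as.integer(names(tab)),
             count = as.integer(tab),
             frequency = as.integer(tab) / sum(tab))
}

#' Group orphan nucleosomes by total flanking linker length
#'
#' Orphans are grouped by the sum of their two flanking linker lengths
#' falling into configured bins (half-open \code{[lo, hi)}).
#'
#' @param orphans Integer vector of orphan row indices (from
#'   [find_orphans()]).
#' @param calls Nucleosome-call data frame.
#' @param linkers Linker data frame.
#' @param bin_edges Increasing numeric vector of bin edges.
#' @return Data frame \code{call}, \code{total_linker}, \code{group} (the
#'   bin label, \code{NA} if outside all bins).
#' @export
group_orphans_by_flanking <- function(orphans, calls, linkers, bin_edges) {
  if (!length(orphans)) {
    return(data.frame(call = integer(), total_linker = integer(),
                      group = character()))
  }
  up_len <- down_len <- rep(NA_integer_, nrow(calls))
  up_len[linkers$downstream] <- linkers$length  # linker upstream of call
  down_len[linkers$upstream] <- linkers$length  # linker downstream of call
  total <- up_len[orphans] + down_len[orphans]
  lab <- paste0("[", bin_edges[-length(bin_edges)], ",",
                bin_edges[-1L], ")")
  bin <- findInterval(total, bin_edges, rightmost.closed = FALSE)
  grp <- ifelse(bin >= 1L & bin < length(bin_edges), lab[bin], NA_character_)
  data.frame(call = orphans, total_linker = total, group = grp,
             stringsAsFactors = FALSE)
}
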