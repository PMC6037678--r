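#' Pair nucleosomes across two stages
#'
#' For every stage-A call, finds the nearest stage-B dyad on the same
#' chromosome and records the unsigned distance and the signed shift
#' (dyad_B − dyad_A). Equidistant B neighbors resolve to the leftward
#' (smaller-coordinate) one. A calls on chromosomes with no B calls get an
#' infinite distance (and so classify as lost). Classification and shift
#' bins are filled in by [classify_dynamics()] and [bin_shifts()].
#'
#' @param calls_a,calls_b Nucleosome-call data frames for the two stages,
#'   sorted by dyad within chromosome.
#' @param fixed_max Largest distance still "fixed", bp (default 10,
#'   inclusive).
#' @param lost_min Smallest distance already "lost", bp (default 127,
#'   inclusive).
#' @return Data frame with one row per A call: \code{call_a}, \code{chrom},
#'   \code{dyad_a}, \code{call_b} (NA if none), \code{dyad_b},
#'   \code{distance}, \code{signed_shift}, \code{klass}, \code{shift_bin},
#'   \code{direction}.
#' @export
match_nucleosomes <- function(calls_a, calls_b, fixed_max = 10, lost_min = 127) {
  n <- nrow(calls_a)
  call_b <- rep(NA_integer_, n)
  dyad_b <- rep(NA_integer_, n)
  for (ch in unique(calls_a$chrom)) {
    ia <- which(calls_a$chrom == ch)
    ib <- which(calls_b$chrom == ch)
    if (!length(ib)) next
    da <- calls_a$dyad[ia]
    db <- calls_b$dyad[ib]
    if (is.unsorted(db)) stop("calls_b must be sorted within chromosome")
    k <- findInterval(da, db)
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(db))
    dl <- abs(da - db[left])
    dr <- abs(da - db[right])
    nearest <- ifelse(dl <= dr, left, right) # tie -> leftward neighbor
    call_b[ia] <- ib[nearest]
    dyad_b[ia] <- db[nearest]
  }
  rec <- data.frame(
    call_a = seq_len(n), chrom = calls_a$chrom, dyad_a = calls_a$dyad,
    call_b = call_b, dyad_b = dyad_b,
    distance = ifelse(is.na(dyad_b), Inf, abs(dyad_b - calls_a$dyad)),
    signed_shift = ifelse(is.na(dyad_b), NA_real_, dyad_b - calls_a$dyad),
    stringsAsFactors = FALSE)
  rec$klass <- classify_dynamics(rec$distance, fixed_max, lost_min)
  bins <- bin_shifts(rec$signed_shift)
  rec$shift_bin <- bins$shift_bin
  rec$direction <- bins$direction
  rec
}

#' Classify a nucleosome's positioning dynamics
#'
#' Distance to the nearest other-stage dyad at most 10 bp means the
#' nucleosome is fixed; at least 127 bp means it was lost (disassembled or
#' reassembled); anything in between is shifted. Both thresholds are
#' inclusive and configurable.
#'
#' @param distance Numeric vector of unsigned midpoint distances (bp; may
#'   be \code{Inf} for unmatched calls).
#' @param fixed_max,lost_min Class thresholds in bp.
#' @return Character vector: \code{"fixed"}, \code{"shifted"} or
#'   \code{"lost"}.
#' @export
classify_dynamics <- function(distance, fixed_max = 10, lost_min = 127) {
  ifelse(distance <= fixed_max, "fixed",
         ifelse(distance >= lost_min, "lost", "shifted"))
}

#' Bin signed shifts into the fixed / intermediate / far groups
#'
#' Magnitude bins are closed: 0–10 bp is \code{fixed} (no direction),
#' 30–40 bp \code{intermediate}, 50–74 bp \code{far} (74 bp being half a
#' nucleosome, the largest shift still interpretable as repositioning).
#' Shifts in the gaps (10,30) and (40,50), or beyond 74, fall in
#' \code{other}. Direction is \code{left} for negative shifts and
#' \code{right} for positive ones.
#'
#' @param signed_shift Numeric vector of signed shifts (dyad_B − dyad_A;
#'   NA allowed for unmatched calls).
#' @return List of two character vectors \code{shift_bin} (\code{fixed},
#'   \code{intermediate}, \code{far}, \code{other}) and \code{direction}
#'   (\code{left}, \code{right}, or \code{NA} for the fixed bin and NAs).
#' @export
bin_shifts <- function(signed_shift) {
  mag <- abs(signed_shift)
  bin <- rep("other", length(signed_shift))
  bin[!is.na(mag) & mag <= 10] <- "fixed"
  bin[!is.na(mag) & mag >= 30 & mag <= 40] <- "intermediate"
  bin[!is.na(mag) & mag >= 50 & mag <= 74] <- "far"
  bin[is.na(mag)] <- NA_character_
  dir <- rep(NA_character_, length(signed_shift))
  dir[!is.na(signed_shift) & signed_shift < 0 & bin != "fixed"] <- "left"
  dir[!is.na(signed_shift) & signed_shift > 0 & bin != "fixed"] <- "right"
  list(shift_bin = bin, direction = dir)
}

#' Reassembled nucleosomes
#'
#' Stage-B calls with no stage-A dyad within \code{lost_min} bp: positions
#' newly occupied in the second stage. The mirror of "lost" A calls.
#'
#' @param calls_a,calls_b Nucleosome-call data frames.
#' @param lost_min Distance threshold in bp (default 127).
#' @return Integer vector of row indices into \code{calls_b}.
#' @export
find_reassembled <- function(calls_a, calls_b, lost_min = 127) {
  rec <- match_nucleosomes(calls_b, calls_a, lost_min = lost_min)
  which(rec$klass == "lost")
}
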