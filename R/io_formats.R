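#' Read mapped reads from a BED file
#'
#' Parses a (minimally 3-column) tab-separated BED file into a data frame of
#' mapped single-end reads. Coordinates are 0-based half-open throughout the
#' package. Header-like lines starting with \code{track}, \code{browser} or
#' \code{#} are skipped. A missing strand column defaults to \code{"+"}.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns \code{chrom} (character), \code{start},
#'   \code{end} (integer, 0-based half-open) and \code{strand} (\code{"+"} or
#'   \code{"-"}), one row per read, in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr2L\t1000\t1049\tr1\t0\t+", f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED parse error at line ", idx[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("BED parse error at line ", idx[bad[1]], ": non-numeric coordinate")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", idx[bad[1]],
         ": requires 0 <= start < end, got [", start[bad[1]], ", ",
         end[bad[1]], ")")
  }
  strand <- rep("+", length(fields))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop("BED parse error at line ", idx[bad[1]], ": unknown strand '",
         strand[bad[1]], "'")
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write mapped reads as 6-column BED
#'
#' @param reads Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (as returned by [read_bed()]).
#' @param path Output path.
#' @param name Optional read names; defaults to \code{r1, r2, ...}.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(reads, path, name = NULL) {
  if (is.null(name)) name <- paste0("r", seq_len(nrow(reads)))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$chrom,
                   as.integer(reads$start), as.integer(reads$end),
                   name, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-base value track as bedGraph
#'
#' Runs of adjacent equal values are merged into single intervals (UCSC
#' bedGraph dialect); intervals are emitted sorted and non-overlapping.
#' Zero-valued runs can be suppressed.
#'
#' @param values Numeric vector of per-base values; \code{values[i]} covers
#'   0-based position \code{offset + i - 1}.
#' @param chrom Chromosome name.
#' @param path Output path.
#' @param offset 0-based start position of \code{values[1]}.
#' @param suppress_zero Drop zero-valued intervals from the data section.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(values, chrom, path, offset = 0L,
                           suppress_zero = FALSE) {
  if (any(!is.finite(values))) stop("bedGraph values must be finite")
  n <- length(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (n == 0L) return(invisible(path))
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- if (suppress_zero) r$values != 0 else rep(TRUE, length(r$values))
  if (any(keep)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                       as.integer(offset + starts[keep]),
                       as.integer(offset + ends[keep]),
                       format(r$values[keep], trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a per-base vector
#'
#' Inverse of [write_bedgraph()] for a single chromosome: expands intervals
#' to per-base values. Positions not covered by any interval get
#' \code{fill}.
#'
#' @param path bedGraph path.
#' @param length Length of the returned vector (positions
#'   \code{offset ... offset+length-1}).
#' @param offset 0-based position of element 1.
#' @param fill Value for uncovered positions.
#' @return Numeric vector of length \code{length}.
#' @export
read_bedgraph <- function(path, length, offset = 0L, fill = 0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  out <- rep(fill, length)
  if (!length(lines)) return(out)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- as.integer(vapply(fields, `[[`, "", 2L)) - offset
  end <- as.integer(vapply(fields, `[[`, "", 3L)) - offset
  val <- as.numeric(vapply(fields, `[[`, "", 4L))
  for (i in seq_along(val)) {
    lo <- max(start[i] + 1L, 1L)
    hi <- min(end[i], length)
    if (lo <= hi) out[lo:hi] <- val[i]
  }
  out
}

TABLE_HEADER <- "#chromatosome-dynamics v1"

#' Write / read versioned TSV tables
#'
#' All tabular artifacts (nucleosome calls, linkers, dynamics records,
#' profiles, truth tables) are serialized as TSV with a one-line versioned
#' header so files self-identify. \code{read_table_tsv(write_table_tsv(x))}
#' round-trips column names, order and values.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return \code{path} invisibly (writer); the data frame (reader).
#' @export
write_table_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TABLE_HEADER, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, TABLE_HEADER)) {
    stop("not a chromatosome-dynamics table (missing version header): ", path)
  }
  utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                    stringsAsFactors = FALSE)
}

#' Read gene models from TSV
#'
#' Expects a tab-separated file with header columns \code{gene_id},
#' \code{chrom}, \code{tss}, \code{tes}, \code{strand} and optionally
#' \code{fpkm}. The TSS is strand-aware: for \code{-} genes it is the larger
#' coordinate (\code{tss > tes}).
#'
#' @param path Gene-model TSV path.
#' @return Data frame of gene models.
#' @export
read_gene_models <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         comment.char = "#")
  req <- c("gene_id", "chrom", "tss", "tes", "strand")
  miss <- setdiff(req, names(g))
  if (length(miss)) stop("gene model file missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id in gene models: ",
         g$gene_id[duplicated(g$gene_id)][1])
  }
  bad <- (g$strand == "+" & g$tss >= g$tes) |
         (g$strand == "-" & g$tss <= g$tes)
  if (any(bad)) {
    stop("gene ", g$gene_id[which(bad)[1]],
         ": tss/tes inconsistent with strand (for '-' genes tss > tes)")
  }
  g
}

#' Read a per-gene expression table
#'
#' Two-column TSV (header \code{gene_id}, \code{fpkm}). Genes present here
#' but absent from \code{genes} are dropped with a warning; genes lacking
#' expression are excluded from expression-grouped analyses downstream.
#'
#' @param path Expression TSV path.
#' @param genes Optional gene-model data frame used to validate ids.
#' @return Named numeric vector mapping gene_id to FPKM.
#' @export
read_expression <- function(path, genes = NULL) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "fpkm") %in% names(e))) {
    stop("expression file needs columns gene_id, fpkm")
  }
  if (anyDuplicated(e$gene_id)) stop("duplicate gene_id in expression table")
  fpkm <- stats::setNames(as.numeric(e$fpkm), e$gene_id)
  if (!is.null(genes)) {
    unknown <- setdiff(names(fpkm), genes$gene_id)
    if (length(unknown)) {
      warning(length(unknown),
              " expression entries with no gene model dropped")
      fpkm <- fpkm[setdiff(names(fpkm), unknown)]
    }
  }
  fpkm
}

#' Write gene models (TSV and BED6)
#'
#' @param genes Gene-model data frame (with \code{fpkm} column for the BED
#'   score field; missing FPKM written as 0).
#' @param tsv_path,bed_path Output paths; either may be \code{NULL} to skip.
#' @return Invisibly, the paths written.
#' @export
write_gene_models <- function(genes, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(genes, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    fpkm <- if ("fpkm" %in% names(genes)) genes$fpkm else 0
    start <- pmin(genes$tss, genes$tes)
    end <- pmax(genes$tss, genes$tes)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", genes$chrom,
                       as.integer(start), as.integer(end), genes$gene_id,
                       format(fpkm, trim = TRUE), genes$strand),
               bed_path)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}
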