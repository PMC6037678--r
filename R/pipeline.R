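#' Width of the H1-depleted region upstream of the TSS
#'
#' Measures, on a directed TSS-anchored profile, how far upstream the
#' H1-depleted region extends: starting from the bin just upstream of the
#' TSS, the maximal contiguous run of bins whose value is below
#' \code{threshold_frac} times the gene-body baseline (mean value over
#' bins 500–1000 bp downstream). Used to compare NFR footprints across
#' expression classes.
#'
#' The run is anchored at the first depleted bin within \code{start_slack}
#' bp of the TSS, tolerating border signal of the +1 nucleosome bleeding
#' across the TSS.
#'
#' @param profile A [composite_profile()] data frame.
#' @param threshold_frac Depletion threshold as a fraction of baseline
#'   (default 0.5).
#' @param start_slack How far upstream of the TSS the depleted run may
#'   begin, bp (default 100).
#' @return Depletion width in bp (0 if no depleted bin starts within
#'   \code{start_slack} of the TSS).
#' @export
upstream_depletion_width <- function(profile, threshold_frac = 0.5,
                                     start_slack = 100) {
  baseline <- mean(profile$value[profile$bin_center >= 500 &
                                   profile$bin_center <= 1000])
  if (!is.finite(baseline) || baseline <= 0) return(NA_real_)
  up <- profile[profile$bin_center < 0, , drop = FALSE]
  up <- up[order(-up$bin_center), , drop = FALSE] # TSS outward
  depleted <- up$value < threshold_frac * baseline
  first <- which(depleted)
  if (!length(first) || -up$bin_center[first[1]] > start_slack) return(0)
  i <- first[1]
  j <- i
  while (j < length(depleted) && depleted[j + 1L]) j <- j + 1L
  bw <- diff(profile$bin_center[1:2])
  (j - i + 1L) * bw
}

#' Run the full synthetic-to-statistics pipeline
#'
#' One call that exercises every stage on synthetic data: builds a genome
#' plan, simulates MNase (two stages) and H1 reads, calls nucleosomes per
#' stage, derives linkers / NFRs / arrays / orphans and the phasogram,
#' classifies two-stage dynamics, assigns H1 and computes dyad-anchored
#' and TSS-anchored profiles. Optionally writes every table under
#' \code{outdir}.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed driving all randomness.
#' @param outdir Optional output directory (created if needed).
#' @param sigma,exclusion_width,min_rpnm Caller settings (see
#'   [call_nucleosomes()]).
#' @return List: \code{plan}, \code{reads_a}, \code{reads_b},
#'   \code{h1_reads}, \code{truth}, \code{calls_a}, \code{calls_b} (both
#'   with H1 columns on stage A), \code{linkers}, \code{nfrs},
#'   \code{arrays}, \code{orphans}, \code{phasogram}, \code{dynamics},
#'   \code{dyad_profile}, \code{tss_profiles} (when genes exist).
#' @export
run_pipeline <- function(config, seed, outdir = NULL, sigma = 20,
                         exclusion_width = 147L, min_rpnm = 0.1) {
  plan <- build_plan(config, seed)
  pair <- simulate_stage_pair(plan)
  h1 <- simulate_h1_reads(plan)
  calls_a <- call_nucleosomes(pair$reads_a, plan$chrom_sizes, sigma = sigma,
                              exclusion_width = exclusion_width,
                              min_rpnm = min_rpnm)
  calls_b <- call_nucleosomes(pair$reads_b, plan$chrom_sizes, sigma = sigma,
                              exclusion_width = exclusion_width,
                              min_rpnm = min_rpnm)
  if (nrow(plan$genes)) {
    calls_a <- annotate_context(calls_a, plan$genes)
  }
  calls_a <- assign_h1(calls_a, h1)
  linkers <- compute_linkers(calls_a)
  nfrs <- find_nfrs(linkers)
  arrays <- find_arrays(calls_a, linkers)
  orphans <- find_orphans(calls_a, linkers, nfrs)
  phas <- phasogram(calls_a)
  dyn <- match_nucleosomes(calls_a, calls_b)
  anchors <- data.frame(chrom = calls_a$chrom, pos = calls_a$dyad,
                        stringsAsFactors = FALSE)
  dyad_profile <- composite_profile(anchors, h1)
  tss_profiles <- NULL
  if (nrow(plan$genes) >= 5L) {
    fpkm <- stats::setNames(plan$genes$fpkm, plan$genes$gene_id)
    tss_profiles <- tss_profiles_by_expression(plan$genes, fpkm, h1)
  }
  out <- list(plan = plan, reads_a = pair$reads_a, reads_b = pair$reads_b,
              h1_reads = h1, truth = pair$truth, calls_a = calls_a,
              calls_b = calls_b, linkers = linkers, nfrs = nfrs,
              arrays = arrays, orphans = orphans, phasogram = phas,
              dynamics = dyn, dyad_profile = dyad_profile,
              tss_profiles = tss_profiles)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_bed(pair$reads_a, file.path(outdir, "mnase_stageA.bed"))
    write_bed(pair$reads_b, file.path(outdir, "mnase_stageB.bed"))
    write_bed(h1, file.path(outdir, "h1.bed"))
    write_table_tsv(pair$truth, file.path(outdir, "truth.tsv"))
    write_table_tsv(calls_a, file.path(outdir, "calls_stageA.tsv"))
    write_table_tsv(calls_b, file.path(outdir, "calls_stageB.tsv"))
    write_table_tsv(linkers, file.path(outdir, "linkers.tsv"))
    write_table_tsv(nfrs, file.path(outdir, "nfrs.tsv"))
    write_table_tsv(dyn, file.path(outdir, "dynamics.tsv"))
    write_table_tsv(phas, file.path(outdir, "phasogram.tsv"))
    write_table_tsv(dyad_profile, file.path(outdir, "h1_dyad_profile.tsv"))
    if (nrow(plan$genes)) {
      write_gene_models(plan$genes, tsv_path = file.path(outdir, "genes.tsv"))
    }
  }
  out
}

#' Match planted dyads to called dyads
#'
#' For each planted nucleosome, the distance to the nearest called dyad on
#' the same chromosome — the recovery measurement used to validate the
#' caller on synthetic data.
#'
#' @param planted Data frame with \code{chrom}, \code{dyad} (e.g.
#'   \code{plan$nucleosomes}).
#' @param calls Nucleosome-call data frame.
#' @return Numeric vector of distances (bp; \code{Inf} when the chromosome
#'   has no calls), one per planted nucleosome.
#' @export
dyad_recovery <- function(planted, calls) {
  out <- rep(Inf, nrow(planted))
  for (ch in unique(planted$chrom)) {
    ip <- which(planted$chrom == ch)
    d <- sort(calls$dyad[calls$chrom == ch])
    if (!length(d)) next
    k <- findInterval(planted$dyad[ip], d)
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(d))
    out[ip] <- pmin(abs(planted$dyad[ip] - d[left]),
                    abs(planted$dyad[ip] - d[right]))
  }
  out
}
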