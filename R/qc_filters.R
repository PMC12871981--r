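# Post-boundary quality filters, telomere metrics, restriction-site
# scanning, mutant repeat statistics, and cluster-prep trimming.
#
# All thresholds are strict inequalities: reads fail on "more than 20%",
# "less than 60%", "more than 10%" — values exactly at a threshold pass.

#' Proximal truncation filter
#'
#' Reads that begin inside the repeat array lack the complete telomere
#' and would bias length distributions downward. A read fails when the
#' telomere+1N coverage of its first `span` bases (the subtelomeric end
#' of an oriented read) exceeds `max_pct`.
#'
#' @param seq oriented read sequence.
#' @param motifs a [telomere_motifs()] object.
#' @param span prefix length examined (default 300 bases).
#' @param max_pct failure threshold, percent (default 20; strictly
#'   greater fails).
#' @param include_mutant score mutant motifs as telomeric.
#' @return `TRUE` (pass) or `FALSE` (fail, read proximally truncated).
#' @export
truncation_filter <- function(seq, motifs, span = 300, max_pct = 20,
                              include_mutant = FALSE) {
  pct <- interval_coverage(seq, motifs, 1L, span,
                          include_mutant = include_mutant)
  is.na(pct) || pct <= max_pct
}

#' Telomere content filter
#'
#' The called telomere `[vrr_start, probe_start)` must be composed of at
#' least `min_pct` telomere+1N repeats; genuine telomeres run well above
#' this, while subtelomeric or interstitial mimics fall below.
#'
#' @param seq oriented read sequence.
#' @param motifs a [telomere_motifs()] object.
#' @param vrr_start,probe_start 1-based boundary and probe positions.
#' @param min_pct failure threshold, percent (default 60; strictly less
#'   fails).
#' @param include_mutant score mutant motifs as telomeric.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
telomere_content_filter <- function(seq, motifs, vrr_start, probe_start,
                                    min_pct = 60, include_mutant = FALSE) {
  pct <- interval_coverage(seq, motifs, vrr_start, probe_start - 1L,
                          include_mutant = include_mutant)
  !is.na(pct) && pct >= min_pct
}

#' Upstream context filter
#'
#' Validates the called boundary by requiring the `span` bases upstream
#' of it to be mostly non-telomeric: more than `max_pct` telomere+1N
#' content there indicates either a mis-placed boundary (e.g. displaced
#' by an internal basecalling artifact) or unusually repeat-rich
#' subtelomeric structure. When fewer than `span` bases exist upstream,
#' the available prefix is evaluated instead.
#'
#' @param seq oriented read sequence.
#' @param motifs a [telomere_motifs()] object.
#' @param vrr_start 1-based called boundary.
#' @param span upstream context length (default 2000 bases).
#' @param max_pct failure threshold, percent (default 10; strictly
#'   greater fails).
#' @param include_mutant score mutant motifs as telomeric.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
upstream_filter <- function(seq, motifs, vrr_start, span = 2000,
                            max_pct = 10, include_mutant = FALSE) {
  if (vrr_start <= 1L) return(TRUE)
  pct <- interval_coverage(seq, motifs, max(1L, vrr_start - span),
                          vrr_start - 1L, include_mutant = include_mutant)
  is.na(pct) || pct <= max_pct
}

#' Per-read telomere metrics
#'
#' @param seq oriented read sequence.
#' @param qual Phred+33 quality string for `seq`.
#' @param motifs a [telomere_motifs()] object.
#' @param vrr_start,probe_start 1-based boundary and probe positions.
#' @param include_mutant score mutant motifs as telomeric.
#' @return list with `telomere_length` (`probe_start - vrr_start`),
#'   `telomere_mean_quality` (arithmetic mean Phred over the telomere),
#'   `wt_repeat_bases` (bases covered by canonical hits only, the basis
#'   of the wild-type-content length statistic), and `vrr_span_estimate`
#'   (span from the boundary to the end of the last variant hit).
#' @export
telomere_metrics <- function(seq, qual, motifs, vrr_start, probe_start,
                             include_mutant = FALSE) {
  stopifnot(probe_start >= vrr_start)
  telo_len <- probe_start - vrr_start
  interval <- if (telo_len > 0) vrr_start:(probe_start - 1L) else integer(0)
  q <- phred_scores(qual)
  hits <- scan_motifs(seq, motifs, include_mutant = include_mutant)
  mask_all <- .hit_mask(hits, nchar(seq))
  canon <- hits[hits$kind == "canonical", , drop = FALSE]
  mask_wt <- .hit_mask(canon, nchar(seq))
  var_hits <- hits[hits$kind != "canonical" &
                     hits$start >= vrr_start & hits$end < probe_start, ,
                   drop = FALSE]
  list(
    telomere_length = telo_len,
    telomere_mean_quality = if (length(interval)) mean(q[interval])
                            else NA_real_,
    wt_repeat_bases = sum(mask_wt[interval]),
    telo1n_bases = sum(mask_all[interval]),
    vrr_span_estimate = if (nrow(var_hits))
      max(var_hits$end) - vrr_start + 1L else 0L
  )
}

#' Count telomeric reads containing restriction sites
#'
#' Read-level counts: a read is counted once per site it contains, on
#' either strand, regardless of copy number.
#'
#' @param seq character vector of read sequences.
#' @param sites character vector of recognition sites (e.g.
#'   `c("GATATC")` for EcoRV).
#' @return named integer vector, reads containing each site.
#' @export
restriction_site_counts <- function(seq, sites) {
  vapply(sites, function(s) {
    .check_dna(s, "restriction site")
    sum(grepl(s, seq, fixed = TRUE) | grepl(revcomp(s), seq, fixed = TRUE))
  }, integer(1))
}

#' Mutant versus wild-type repeat statistics
#'
#' Tallies mutant and canonical repeat hits inside the called telomere.
#' Only meaningful in mutant mode (a motif set built with `mutant`
#' motifs); without mutant motifs the fraction is `NA` since mutant
#' repeats are then indistinguishable from chance variants.
#'
#' @param seq oriented read sequence.
#' @param motifs a [telomere_motifs()] object (with `mutant` set).
#' @param vrr_start,probe_start 1-based boundary and probe positions.
#' @return list with `mutant_repeat_count`, `wt_repeat_count`, and
#'   `mutant_fraction` (mutant / (mutant + wild type)).
#' @export
mutant_stats <- function(seq, motifs, vrr_start, probe_start) {
  if (is.null(motifs$mutant))
    return(list(mutant_repeat_count = NA_integer_,
                wt_repeat_count = NA_integer_,
                mutant_fraction = NA_real_))
  hits <- scan_motifs(seq, motifs, include_mutant = TRUE)
  hits <- hits[hits$start >= vrr_start & hits$end < probe_start, ,
               drop = FALSE]
  mut <- sum(hits$kind == "mutant")
  wt <- sum(hits$kind == "canonical")
  list(mutant_repeat_count = mut, wt_repeat_count = wt,
       mutant_fraction = if (mut + wt > 0) mut / (mut + wt) else NA_real_)
}

#' Trim a read around its boundary for external clustering
#'
#' Returns `seq[vrr_start - before, vrr_start + after)` clipped to the
#' read, so downstream de novo clustering can focus on the VRR region
#' plus enough flanking subtelomere to anchor chromosome-arm identity.
#'
#' @param seq oriented read sequence.
#' @param vrr_start 1-based called boundary.
#' @param before,after bases kept up- and downstream of the boundary.
#' @return the trimmed sequence string.
#' @export
trim_for_clustering <- function(seq, vrr_start, before = 1000,
                                after = 3000) {
  substr(seq, max(1L, vrr_start - before), min(nchar(seq),
                                               vrr_start + after - 1L))
}

#' Write trimmed sequences as FASTA for clustering tools
#'
#' @param trimmed named character vector (names become FASTA ids).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_trimmed_fasta <- function(trimmed, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(trimmed), path)
  invisible(path)
}
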