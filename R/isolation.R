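# First-pass telomeric read isolation, strand classification, chimera
# removal, and orientation normalization.

#' First-pass telomeric read isolation
#'
#' A read is kept when it contains at least `min_repeats` non-consecutive
#' occurrences of the canonical repeat, counting both strand motifs under
#' the greedy non-overlapping scan. Occurrences may lie anywhere in the
#' read; no adjacency is required. Variant repeats do not count at this
#' stage.
#'
#' @param seq character vector of read sequences.
#' @param motifs a [telomere_motifs()] object.
#' @param min_repeats minimum canonical repeat count (default 10).
#' @param include_mutant count mutant motifs as telomeric (mutant mode).
#' @return logical vector, `TRUE` for reads passing isolation.
#' @export
first_pass_isolate <- function(seq, motifs, min_repeats = 10,
                               include_mutant = FALSE) {
  vapply(seq, function(s) {
    h <- scan_motifs(s, motifs, include_variants = FALSE,
                     include_mutant = include_mutant)
    sum(h$kind %in% c("canonical", "mutant")) >= min_repeats
  }, logical(1), USE.NAMES = FALSE)
}

#' Classify read strand from canonical repeat content
#'
#' The G-strand fraction is the share of canonical repeat hits matching
#' the G-strand motif. In duplex mode, reads below 20% are C-strand,
#' above 80% G-strand, and anything in the closed interval `[0.20, 0.80]`
#' is flagged chimeric and removed. In C-strand-only mode (splint
#' enrichment) any read with more than 20% G-strand repeats is removed.
#'
#' @param seq character vector of read sequences.
#' @param motifs a [telomere_motifs()] object.
#' @param c_strand_only `TRUE` for C-strand-only (splint) libraries.
#' @param lower,upper G-fraction thresholds (defaults 0.20 / 0.80).
#' @param include_mutant count mutant motifs as telomeric (mutant mode).
#' @return data.frame with `g_count`, `c_count`, `g_fraction`, `verdict`
#'   (`"C"`, `"G"`, `"chimeric"`, `"non_telomeric"`) and `keep`.
#' @export
classify_strand <- function(seq, motifs, c_strand_only = FALSE,
                            lower = 0.20, upper = 0.80,
                            include_mutant = FALSE) {
  res <- lapply(seq, function(s) {
    h <- scan_motifs(s, motifs, include_variants = FALSE,
                     include_mutant = include_mutant)
    h <- h[h$kind %in% c("canonical", "mutant"), , drop = FALSE]
    c(g = sum(h$strand == "G"), c = sum(h$strand == "C"))
  })
  g_count <- vapply(res, `[[`, integer(1), "g")
  c_count <- vapply(res, `[[`, integer(1), "c")
  total <- g_count + c_count
  g_fraction <- ifelse(total > 0, g_count / total, NA_real_)
  verdict <- rep("non_telomeric", length(seq))
  if (c_strand_only) {
    verdict[total > 0 & g_fraction <= lower] <- "C"
    verdict[total > 0 & g_fraction > lower] <- "G"
    keep <- verdict == "C"
  } else {
    verdict[total > 0 & g_fraction < lower] <- "C"
    verdict[total > 0 & g_fraction > upper] <- "G"
    verdict[total > 0 & g_fraction >= lower & g_fraction <= upper] <-
      "chimeric"
    keep <- verdict %in% c("C", "G")
  }
  data.frame(g_count = g_count, c_count = c_count,
             g_fraction = g_fraction, verdict = verdict, keep = keep,
             stringsAsFactors = FALSE)
}

#' Normalize reads into G-strand orientation
#'
#' C-strand reads are reverse-complemented (qualities reversed); G-strand
#' reads pass through untouched. After normalization the subtelomere lies
#' toward the 5' end and the telomere/capture probe toward the 3' end of
#' every read. The original strand identity is kept in `strand_tag`.
#'
#' @param reads a `telo_reads` data.frame.
#' @param verdict character vector of strand verdicts (`"C"` or `"G"`),
#'   one per read.
#' @return the reads with `seq`/`qual` normalized, `strand_tag` set, and
#'   `oriented = TRUE`.
#' @export
normalize_orientation <- function(reads, verdict) {
  if (!all(verdict %in% c("C", "G")))
    stop("only reads with a C or G strand verdict can be oriented")
  flip <- verdict == "C"
  reads$seq[flip] <- revcomp(reads$seq[flip])
  reads$qual[flip] <- .reverse_string(reads$qual[flip])
  reads$strand_tag <- verdict
  reads$oriented <- TRUE
  reads
}
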