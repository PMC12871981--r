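# Telomeric motif alphabet and scanning primitives.
#
# The boundary and filtering machinery all run on "telomere+1N" content:
# the canonical repeat plus every string within one edit (substitution,
# single-base insertion or deletion) of it, on either strand.

#' Reverse complement of plain character DNA
#'
#' Operates on plain uppercase character vectors (A/C/G/T/N). Used
#' throughout for strand normalization; per-base qualities are reversed
#' separately by the caller.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GGTTAG")  # "CTAACC"
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

.check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT characters: ", x, call. = FALSE)
  invisible(x)
}

# All distinct strings within edit distance 1 of `canonical`:
# the string itself, substitutions, deletions, and insertions
# (all four bases at every gap position, including both ends).
.edit1_neighborhood <- function(canonical) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(canonical, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- canonical
  for (i in seq_len(L)) {
    for (b in bases) {
      if (b != ch[i]) {
        s <- ch; s[i] <- b
        out <- c(out, paste(s, collapse = ""))
      }
    }
    out <- c(out, paste(ch[-i], collapse = ""))
  }
  for (i in 0:L) {
    for (b in bases) {
      s <- append(ch, b, after = i)
      out <- c(out, paste(s, collapse = ""))
    }
  }
  unique(out)
}

#' Build the telomeric motif set
#'
#' Constructs the full telomere+1N alphabet for a canonical repeat: the
#' repeat itself, its reverse complement, and every distinct string within
#' Levenshtein distance 1 of each (substitutions, single-base insertions,
#' single-base deletions), plus optional mutant repeat motifs kept in a
#' separate class.
#'
#' @param canonical canonical G-strand repeat (default `"GGTTAG"`, the
#'   vertebrate telomeric repeat).
#' @param mutant optional character vector of mutant repeat motifs (e.g. a
#'   telomerase RNA template mutation product); scored as telomeric only
#'   when mutant mode is switched on in downstream calls.
#' @return An object of class `telomere_motifs` with components
#'   `canonical`, `complement`, `variants_g`, `variants_c`, `mutant`,
#'   `mutant_c`, and a precomputed scan `table`.
#' @examples
#' m <- telomere_motifs()
#' m$canonical
#' length(m$variants_g)
#' @export
telomere_motifs <- function(canonical = "GGTTAG", mutant = NULL) {
  .check_dna(canonical, "canonical motif")
  if (!is.null(mutant)) {
    for (mu in mutant) .check_dna(mu, "mutant motif")
    mutant <- unique(mutant)
  }
  variants_g <- .edit1_neighborhood(canonical)
  variants_c <- revcomp(variants_g)
  complement <- revcomp(canonical)
  mutant_c <- if (is.null(mutant)) NULL else revcomp(mutant)

  # kind: 0 canonical, 1 variant, 2 mutant; strand: 0 G, 1 C.
  tab <- data.frame(
    motif = c(canonical, complement,
              variants_g, variants_c,
              mutant, mutant_c),
    kind = c(0L, 0L,
             rep(1L, length(variants_g)), rep(1L, length(variants_c)),
             rep(2L, length(mutant)), rep(2L, length(mutant_c))),
    strand = c(0L, 1L,
               rep(0L, length(variants_g)), rep(1L, length(variants_c)),
               rep(0L, length(mutant)), rep(1L, length(mutant_c))),
    stringsAsFactors = FALSE
  )
  structure(
    list(canonical = canonical, complement = complement,
         variants_g = variants_g, variants_c = variants_c,
         mutant = mutant, mutant_c = mutant_c, table = tab),
    class = "telomere_motifs"
  )
}

#' @export
print.telomere_motifs <- function(x, ...) {
  cat("telomere_motifs:", x$canonical, "/", x$complement, "\n")
  cat("  telomere+1N variants per strand:", length(x$variants_g), "\n")
  if (!is.null(x$mutant))
    cat("  mutant motifs:", paste(x$mutant, collapse = ","), "\n")
  invisible(x)
}

.motif_table <- function(motifs, include_variants = TRUE,
                         include_mutant = FALSE) {
  tab <- motifs$table
  keep <- tab$kind == 0L
  if (include_variants) keep <- keep | tab$kind == 1L
  if (include_mutant) keep <- keep | tab$kind == 2L
  tab[keep, , drop = FALSE]
}

#' Scan a sequence for telomeric motifs
#'
#' Greedy left-to-right non-overlapping scan. At each position an exact
#' canonical repeat (either strand) wins outright; otherwise the longest
#' matching motif wins, with variants beating mutant motifs on a length
#' tie. Canonical precedence matters inside pure repeat arrays, where
#' every canonical repeat is also the prefix of a one-base-insertion
#' variant. `N` bases never match.
#'
#' @param seq single uppercase DNA string (may contain `N`).
#' @param motifs a [telomere_motifs()] object.
#' @param include_variants score telomere+1N variants (default `TRUE`).
#' @param include_mutant score mutant motifs as telomeric (default `FALSE`).
#' @return data.frame with columns `start` (1-based), `width`, `end`,
#'   `kind` (`"canonical"`, `"variant"`, `"mutant"`) and `strand`
#'   (`"G"`/`"C"`), sorted by `start`, pairwise disjoint.
#' @examples
#' m <- telomere_motifs()
#' scan_motifs(strrep("GGTTAG", 3), m)
#' @export
scan_motifs <- function(seq, motifs, include_variants = TRUE,
                        include_mutant = FALSE) {
  stopifnot(inherits(motifs, "telomere_motifs"))
  if (length(seq) != 1L || is.na(seq)) stop("seq must be a single string")
  tab <- .motif_table(motifs, include_variants, include_mutant)
  hits <- cpp_scan_motifs(seq, tab$motif, tab$kind, tab$strand)
  data.frame(
    start = hits$start,
    width = hits$width,
    end = hits$start + hits$width - 1L,
    kind = c("canonical", "variant", "mutant")[hits$kind + 1L],
    strand = c("G", "C")[hits$strand + 1L],
    stringsAsFactors = FALSE
  )
}

# 0/1 per-base coverage mask of hit spans over a sequence of length n.
.hit_mask <- function(hits, n) {
  mask <- logical(n)
  if (nrow(hits))
    mask[sequence(hits$width, from = hits$start)] <- TRUE
  mask
}

#' Windowed telomere+1N coverage profile
#'
#' Percentage of window bases covered by telomere+1N motif hits, in a
#' jumping window advanced by `step`. Hits straddling a window edge
#' contribute only their in-window bases. Windows that would extend past
#' the end of the scanned region are dropped; a sequence shorter than one
#' window yields a single truncated window flagged in the result.
#'
#' @param seq DNA string.
#' @param motifs a [telomere_motifs()] object.
#' @param window_size window width in bases (default 100).
#' @param step window increment in bases (default 15).
#' @param include_variants,include_mutant motif classes to score.
#' @param region_end optional 1-based position limiting the scan (e.g. the
#'   capture-probe start); windows must fit within `[1, region_end - 1]`.
#' @return data.frame with `window_start` (1-based) and `coverage_pct`;
#'   attribute `truncated` is `TRUE` when the sequence (or region) was
#'   shorter than `window_size`.
#' @export
coverage_profile <- function(seq, motifs, window_size = 100, step = 15,
                             include_variants = TRUE, include_mutant = FALSE,
                             region_end = NULL) {
  if (window_size < nchar(motifs$canonical))
    stop("window_size must be at least the canonical motif length")
  if (step < 1) stop("step must be >= 1")
  n <- nchar(seq)
  lim <- if (is.null(region_end)) n else min(n, region_end - 1L)
  hits <- scan_motifs(seq, motifs, include_variants, include_mutant)
  mask <- .hit_mask(hits, n)
  if (lim < window_size) {
    pct <- if (lim > 0) 100 * sum(mask[seq_len(lim)]) / lim else NA_real_
    out <- data.frame(window_start = 1L, coverage_pct = pct)
    attr(out, "truncated") <- TRUE
    return(out)
  }
  starts <- seq.int(1L, lim - window_size + 1L, by = step)
  cs <- c(0L, cumsum(mask))
  pct <- 100 * (cs[starts + window_size] - cs[starts]) / window_size
  out <- data.frame(window_start = starts, coverage_pct = pct)
  attr(out, "truncated") <- FALSE
  out
}

#' Telomere+1N coverage of an interval
#'
#' Fraction (as a percentage) of `[start, end]` covered by telomere+1N
#' hits, counting only in-interval bases of straddling hits. The filters
#' (truncation, telomere content, upstream context) are all thin wrappers
#' around this quantity.
#'
#' @param seq DNA string.
#' @param motifs a [telomere_motifs()] object.
#' @param start,end 1-based closed interval bounds (clipped to the read).
#' @param include_variants,include_mutant motif classes to score.
#' @return percentage in `[0, 100]`, or `NA` for an empty interval.
#' @export
interval_coverage <- function(seq, motifs, start, end,
                              include_variants = TRUE,
                              include_mutant = FALSE) {
  n <- nchar(seq)
  start <- max(1L, as.integer(start))
  end <- min(n, as.integer(end))
  if (end < start) return(NA_real_)
  hits <- scan_motifs(seq, motifs, include_variants, include_mutant)
  mask <- .hit_mask(hits, n)
  100 * sum(mask[start:end]) / (end - start + 1L)
}
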