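# Capture-probe location and barcode demultiplexing.
#
# The capture probe is ligated to the distal telomere end during
# enrichment; finding it certifies that the full telomere was sequenced
# and fixes the distal boundary used for length calculation. Matching is
# bounded-error Hamming (substitutions only), two errors by default for
# the usual 12-nt probe; longer probes warrant a proportionally higher
# allowance.

#' Find all bounded-error matches of a pattern
#'
#' Every window of length `nchar(pattern)` whose Hamming distance to the
#' pattern is at most `max_errors`, sorted by start. With `max_errors = 0`
#' this is exact substring search; the hit set is non-decreasing in
#' `max_errors`.
#'
#' @param seq DNA string to search.
#' @param pattern DNA pattern (>= 6 bases).
#' @param max_errors maximum substitutions tolerated.
#' @return data.frame with `start` (1-based) and `errors`.
#' @export
fuzzy_find_all <- function(seq, pattern, max_errors) {
  if (nchar(pattern) < 6) stop("pattern must be at least 6 bases")
  if (max_errors < 0) stop("max_errors must be >= 0")
  cpp_hamming_find(seq, pattern, as.integer(max_errors))
}

#' Locate the capture probe on an oriented read
#'
#' Scanning 5' to 3', canonical telomeric repeats (both strand motifs)
#' are counted; the first bounded-error probe match starting after the
#' end of the `min_repeats_before`-th repeat is accepted. This positional
#' constraint eliminates probe-like subtelomeric sequence. Immediately
#' adjacent further matches (abnormal tandem probe ligation products) are
#' folded into `tandem_count`; the telomere's distal end is the first
#' probe's start.
#'
#' @param seq oriented read sequence (G orientation, probe toward 3' end).
#' @param probe capture-probe sequence.
#' @param motifs a [telomere_motifs()] object.
#' @param max_errors substitutions tolerated in the probe (default 2).
#' @param min_repeats_before telomeric repeats required upstream of an
#'   acceptable match (default 20).
#' @param include_mutant count mutant motifs as telomeric repeats.
#' @return list with `start` (1-based), `errors`, `tandem_count`,
#'   `distance_to_read_end` (bases from probe start to read end), or
#'   `NULL` when no acceptable match exists.
#' @export
locate_capture_probe <- function(seq, probe, motifs, max_errors = 2,
                                 min_repeats_before = 20,
                                 include_mutant = FALSE) {
  hits <- scan_motifs(seq, motifs, include_variants = FALSE,
                      include_mutant = include_mutant)
  hits <- hits[hits$kind %in% c("canonical", "mutant"), , drop = FALSE]
  if (nrow(hits) < min_repeats_before) return(NULL)
  gate <- hits$end[min_repeats_before]  # end of the 20th repeat
  m <- fuzzy_find_all(seq, probe, max_errors)
  m <- m[m$start > gate, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  first <- m[1, ]
  plen <- nchar(probe)
  tandem <- 0L
  last_end <- first$start + plen - 1L
  for (i in seq_len(nrow(m))[-1]) {
    if (m$start[i] <= last_end + plen && m$start[i] > last_end) {
      tandem <- tandem + 1L
      last_end <- m$start[i] + plen - 1L
    } else if (m$start[i] > last_end + plen) break
  }
  list(start = first$start, errors = first$errors, tandem_count = tandem,
       distance_to_read_end = nchar(seq) - first$start + 1L)
}

#' Load and validate a barcode sample sheet
#'
#' Tab- or comma-delimited file with columns `sample_id` and `barcode`.
#' Sample ids and barcodes must be unique, and barcodes pairwise Hamming
#' distance more than `2 * barcode_max_errors` apart so bounded-error
#' assignment cannot be ambiguous between true barcodes.
#'
#' @param path sample sheet file.
#' @param barcode_max_errors substitutions tolerated per barcode.
#' @return a `telo_sample_sheet` list with `entries` and
#'   `barcode_max_errors`.
#' @export
read_sample_sheet <- function(path, barcode_max_errors = 2) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  sample_sheet(df$sample_id, df$barcode, barcode_max_errors)
}

#' @rdname read_sample_sheet
#' @param sample_id,barcode vectors defining the sheet directly.
#' @export
sample_sheet <- function(sample_id, barcode, barcode_max_errors = 2) {
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  if (anyDuplicated(barcode)) stop("barcodes must be unique")
  for (b in barcode) .check_dna(b, "barcode")
  if (length(unique(nchar(barcode))) > 1)
    stop("barcodes must share a common length")
  n <- length(barcode)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sum(strsplit(barcode[i], "")[[1]] != strsplit(barcode[j], "")[[1]])
      if (d <= 2 * barcode_max_errors)
        stop("barcodes ", sample_id[i], " and ", sample_id[j],
             " are only ", d, " substitutions apart; need more than ",
             2 * barcode_max_errors)
    }
  }
  structure(list(entries = data.frame(sample_id = sample_id,
                                      barcode = barcode,
                                      stringsAsFactors = FALSE),
                 barcode_max_errors = barcode_max_errors),
            class = "telo_sample_sheet")
}

#' Assign a read to a sample by its barcode
#'
#' With a probe hit, the `window` bases 3' of the probe are searched for
#' each barcode; the unique barcode with the fewest errors assigns the
#' sample, and ties or no match leave the read unassigned. Without a
#' probe hit the whole read downstream of the 20th telomeric repeat is
#' searched and the best barcode match additionally defines the distal
#' telomere end.
#'
#' @param seq oriented read sequence.
#' @param probe_hit result of [locate_capture_probe()] (or `NULL`).
#' @param sheet a `telo_sample_sheet`.
#' @param window bases searched 3' of the probe (default 100).
#' @param probe_length length of the probe used for `probe_hit`.
#' @param motifs a [telomere_motifs()] object, needed in probe-free mode.
#' @return list with `sample_id` (`"unassigned"` when ambiguous or
#'   absent), `barcode_start` (1-based, `NA` if unassigned), and
#'   `distal_end` (1-based telomere end position, `NA` unless defined by
#'   the barcode in probe-free mode).
#' @export
demultiplex <- function(seq, probe_hit, sheet, window = 100,
                        probe_length = NULL, motifs = NULL) {
  stopifnot(inherits(sheet, "telo_sample_sheet"))
  n <- nchar(seq)
  if (!is.null(probe_hit)) {
    if (is.null(probe_length))
      stop("probe_length is required when a probe hit is given")
    from <- probe_hit$start + probe_length
    to <- min(n, from + window - 1L)
    if (from > n)
      return(list(sample_id = "unassigned", barcode_start = NA_integer_,
                  distal_end = NA_integer_))
    region <- substr(seq, from, to)
    offset <- from - 1L
    gate <- 0L
  } else {
    if (is.null(motifs))
      stop("motifs are required for probe-free demultiplexing")
    hits <- scan_motifs(seq, motifs, include_variants = FALSE)
    if (nrow(hits) < 20)
      return(list(sample_id = "unassigned", barcode_start = NA_integer_,
                  distal_end = NA_integer_))
    gate <- hits$end[20]
    region <- seq
    offset <- 0L
  }
  best <- lapply(seq_len(nrow(sheet$entries)), function(i) {
    m <- fuzzy_find_all(region, sheet$entries$barcode[i],
                        sheet$barcode_max_errors)
    m <- m[m$start + offset > gate, , drop = FALSE]
    if (!nrow(m)) return(NULL)
    j <- which.min(m$errors)
    list(sample_id = sheet$entries$sample_id[i],
         start = m$start[j] + offset, errors = m$errors[j])
  })
  best <- best[!vapply(best, is.null, logical(1))]
  if (!length(best))
    return(list(sample_id = "unassigned", barcode_start = NA_integer_,
                distal_end = NA_integer_))
  errs <- vapply(best, `[[`, numeric(1), "errors")
  if (sum(errs == min(errs)) > 1)
    return(list(sample_id = "unassigned", barcode_start = NA_integer_,
                distal_end = NA_integer_))
  hit <- best[[which.min(errs)]]
  list(sample_id = hit$sample_id, barcode_start = hit$start,
       distal_end = if (is.null(probe_hit)) hit$start else NA_integer_)
}
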