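# Read/write of sequencing reads and per-read annotations.
#
# Reads are held as a plain data.frame (class "telo_reads") with one row per
# read: read_id, seq, qual (Phred+33 string), strand_tag, oriented,
# sample_id. All on-disk coordinates are 0-based half-open; in-memory
# positions are 1-based, as usual in R.

.new_reads <- function(read_id, seq, qual,
                       strand_tag = NA_character_,
                       oriented = FALSE,
                       sample_id = NA_character_) {
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality lengths differ for read(s): ",
         paste(read_id[nchar(seq) != nchar(qual)], collapse = ", "))
  structure(
    data.frame(read_id = as.character(read_id), seq = as.character(seq),
               qual = as.character(qual),
               strand_tag = strand_tag, oriented = oriented,
               sample_id = sample_id, stringsAsFactors = FALSE),
    class = c("telo_reads", "data.frame")
  )
}

#' Construct a read table
#'
#' @param read_id,seq,qual character vectors of equal length; `qual` is the
#'   Phred+33 encoded quality string, same length as `seq` per read.
#' @return a `telo_reads` data.frame.
#' @export
telo_reads <- function(read_id, seq, qual) .new_reads(read_id, seq, qual)

#' Decode a Phred+33 quality string to numeric scores
#' @param qual quality string.
#' @return integer vector of Phred scores.
#' @export
phred_scores <- function(qual) utf8ToInt(qual) - 33L

.reverse_string <- function(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))

#' Read nanopore reads from FASTQ, gzipped FASTQ, or BAM
#'
#' Format is auto-detected from the file extension unless given. BAM input
#' may be unaligned; only name, sequence, and base qualities are used.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"fastq"`, `"bam"`; `"auto"` maps
#'   `.bam`/`.sam` to BAM and anything else to FASTQ (gzip handled
#'   transparently).
#' @return a `telo_reads` data.frame.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (tolower(tools::file_ext(path)) %in% c("bam", "sam") ||
                  ext %in% c("bam", "sam")) "bam" else "fastq"
  }
  if (format == "fastq") {
    # Biostrings warns about dropped mcols on plain FASTQ input
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    .new_reads(
      read_id = sub("\\s.*$", "", names(x)),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x))
    )
  } else {
    p <- path
    if (tolower(tools::file_ext(path)) == "sam")
      p <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    param <- Rsamtools::ScanBamParam(what = c("qname", "seq", "qual"))
    b <- Rsamtools::scanBam(p, param = param)[[1]]
    .new_reads(read_id = b$qname, seq = as.character(b$seq),
               qual = as.character(b$qual))
  }
}

#' Write reads as FASTQ (optionally gzipped)
#'
#' @param reads a `telo_reads` data.frame.
#' @param path output path; a `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(structure(reads$seq, names = reads$read_id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

# The per-read annotation schema shared by the TSV writer and the SAM tags.
# Coordinates on disk are 0-based half-open; telomere_length is
# probe_start - vrr_start in either convention.
.call_columns <- c("read_id", "sample_id", "strand_tag", "vrr_start",
                   "probe_start", "telomere_length",
                   "telomere_mean_quality", "failure_stage")

#' Write per-read telomere calls as TSV
#'
#' One row per input read, passing or not; failing reads carry the first
#' pipeline stage that removed them in `failure_stage`. Coordinates are
#' written 0-based half-open (documented in a header comment line).
#'
#' @param calls data.frame of per-read results (1-based in memory).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls
  for (col in setdiff(.call_columns, names(out))) out[[col]] <- NA
  out <- out[, .call_columns]
  out$vrr_start <- out$vrr_start - 1L
  out$probe_start <- out$probe_start - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# telotide per-read calls;",
                   "coordinates 0-based half-open;",
                   "telomere_length = probe_start - vrr_start"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a per-read calls TSV back into memory
#' @param path TSV written by [write_calls_tsv()].
#' @return data.frame with 1-based coordinates.
#' @export
read_calls_tsv <- function(path) {
  out <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  out$vrr_start <- out$vrr_start + 1L
  out$probe_start <- out$probe_start + 1L
  out
}

#' Write annotated reads as tagged SAM/BAM plus per-read TSV
#'
#' Emits every read as an unaligned record carrying its call as tags:
#' `XS:A` original strand, `XV:i` VRR start (0-based), `XP:i` probe start
#' (0-based), `XL:i` telomere length, `XQ:f` mean telomere quality,
#' `XF:Z` failure stage, `XB:Z` sample id. A sibling TSV with the same
#' fields is always written.
#'
#' @param reads a `telo_reads` data.frame (oriented or not).
#' @param calls per-read call data.frame; every `read_id` must be present
#'   in `reads`, and coordinates must lie within the read.
#' @param path output path ending in `.sam` or `.bam`; the TSV is written
#'   alongside with extension `.tsv`.
#' @return list with elements `alignment` and `tsv` (paths), invisibly.
#' @export
write_annotated <- function(reads, calls, path) {
  idx <- match(calls$read_id, reads$read_id)
  if (anyNA(idx))
    stop("calls refer to unknown read(s): ",
         paste(calls$read_id[is.na(idx)], collapse = ", "))
  len <- nchar(reads$seq)[idx]
  bad <- (!is.na(calls$vrr_start) & calls$vrr_start > len) |
    (!is.na(calls$probe_start) & calls$probe_start > len + 1L)
  if (any(bad))
    stop("call coordinates outside read for: ",
         paste(calls$read_id[bad], collapse = ", "))

  tag <- function(name, type, v) ifelse(is.na(v), "",
                                        paste0("\t", name, ":", type, ":", v))
  r <- reads[idx, ]
  lines <- paste0(
    r$read_id, "\t4\t*\t0\t0\t*\t*\t0\t0\t", r$seq, "\t", r$qual,
    tag("XS", "A", calls$strand_tag),
    tag("XV", "i", calls$vrr_start - 1L),
    tag("XP", "i", calls$probe_start - 1L),
    tag("XL", "i", calls$telomere_length),
    tag("XQ", "f", round(calls$telomere_mean_quality, 3)),
    tag("XF", "Z", calls$failure_stage),
    tag("XB", "Z", calls$sample_id)
  )
  sam <- if (grepl("\\.bam$", path)) sub("\\.bam$", ".sam", path) else path
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@PG\tID:telotide\tPN:telotide"), sam)
  cat(lines, file = sam, sep = "\n", append = TRUE)
  out_aln <- sam
  if (grepl("\\.bam$", path)) {
    out_aln <- Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                                overwrite = TRUE, indexDestination = FALSE)
    unlink(sam)
  }
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  write_calls_tsv(calls, tsv)
  invisible(list(alignment = out_aln, tsv = tsv))
}

#' Write a simulator ground-truth sidecar TSV
#'
#' Columns: `read_id`, `strand`, `vrr_start`, `probe_start`, `barcode`;
#' positions are 0-based in G-strand orientation.
#'
#' @param truth data.frame with 1-based `vrr_start`/`probe_start`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- data.frame(read_id = truth$read_id, strand = truth$strand,
                    vrr_start = truth$vrr_start - 1L,
                    probe_start = truth$probe_start - 1L,
                    barcode = if ("barcode" %in% names(truth))
                      truth$barcode else NA_character_)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a ground-truth sidecar TSV
#' @param path TSV written by [write_ground_truth()].
#' @return data.frame with 1-based coordinates.
#' @export
read_ground_truth <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  out$vrr_start <- out$vrr_start + 1L
  out$probe_start <- out$probe_start + 1L
  out
}
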