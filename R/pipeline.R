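# Pipeline orchestration, stage ledger, summaries, and report output.
#
# Fixed stage order: isolation -> strand -> probe -> truncation ->
# boundary -> content -> upstream. The capture probe is located before
# boundary detection because it certifies that the entire telomere was
# sequenced and bounds the window scan.

.stages <- c("isolation", "strand", "probe", "truncation", "boundary",
             "content", "upstream")

#' Expected per-arm share under a uniform telomere-read distribution
#'
#' With no enrichment bias, telomeric reads should spread evenly over all
#' chromosome arms; for a diploid human cell that is 100/92 percent per
#' arm. The exact value is returned so that `arms * value == 100`
#' exactly; use [format_arm_expectation()] for the conventional 2-decimal
#' display.
#'
#' @param arms number of chromosome arms (default [diploid_arm_count()]).
#' @return expected percentage per arm.
#' @export
uniform_arm_expectation <- function(arms = diploid_arm_count()) 100 / arms

#' @rdname uniform_arm_expectation
#' @param x a percentage to format.
#' @return `format_arm_expectation`: the percentage truncated to two
#'   decimals, as conventionally quoted (e.g. `1.08` for 92 arms).
#' @export
format_arm_expectation <- function(x = uniform_arm_expectation())
  trunc(x * 100) / 100

#' Chromosome arm count for a diploid human cell
#'
#' Reference constant for cluster-count and per-arm expectations: 46
#' chromosomes, two arms each.
#'
#' @return 92L
#' @export
diploid_arm_count <- function() 92L

#' Run the full telomere-calling pipeline
#'
#' Every input read appears exactly once in the returned per-read table,
#' either with final metrics or with the first stage that removed it.
#'
#' @param reads a `telo_reads` data.frame or a path readable by
#'   [read_reads()].
#' @param motifs a [telomere_motifs()] object; mutant mode is on whenever
#'   the motif set carries mutant motifs.
#' @param probe capture-probe sequence, or `NULL` for probe-free mode (the
#'   distal end then comes from the barcode, or falls back to the read
#'   end, flagged in `distal_end_source`).
#' @param probe_errors substitutions tolerated in the probe (default 2).
#' @param sheet optional `telo_sample_sheet` for demultiplexing.
#' @param c_strand_only expect a C-strand-only (splint) library.
#' @param min_repeats first-pass isolation threshold (default 10).
#' @param boundary_strategy `"dual"`, `"single"`, or `"consecutive"`.
#' @param window_size,step,primary_pct,secondary_pct,rescue_windows
#'   boundary detector parameters (see [detect_vrr_start()]).
#' @param restriction_sites optional recognition sites counted over the
#'   isolated telomeric reads.
#' @param out_dir optional output directory; when given, per-read TSV,
#'   ledger TSV, summary TSV, and an HTML report are written.
#' @return list of class `telo_result`: `calls` (per-read table,
#'   1-based coordinates), `ledger` (stage counts), `summary` (per-sample
#'   statistics), `restriction` (site counts or `NULL`), and `params`.
#' @export
run_pipeline <- function(reads, motifs = telomere_motifs(),
                         probe = NULL, probe_errors = 2, sheet = NULL,
                         c_strand_only = FALSE, min_repeats = 10,
                         boundary_strategy = c("dual", "single",
                                               "consecutive"),
                         window_size = 100, step = 15, primary_pct = 60,
                         secondary_pct = 5, rescue_windows = 15,
                         restriction_sites = NULL, out_dir = NULL) {
  boundary_strategy <- match.arg(boundary_strategy)
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_reads(reads)
  mut <- !is.null(motifs$mutant)
  n <- nrow(reads)
  calls <- data.frame(
    read_id = reads$read_id, sample_id = NA_character_,
    strand_tag = NA_character_, g_count = NA_integer_,
    c_count = NA_integer_, g_fraction = NA_real_,
    probe_start = NA_integer_, probe_errors = NA_integer_,
    tandem_count = NA_integer_, distal_end_source = NA_character_,
    vrr_start = NA_integer_, telomere_length = NA_integer_,
    telomere_mean_quality = NA_real_, wt_repeat_bases = NA_integer_,
    telomere_content_pct = NA_real_, mutant_fraction = NA_real_,
    failure_stage = NA_character_, stringsAsFactors = FALSE)
  alive <- rep(TRUE, n)
  ledger <- data.frame(stage = .stages, entered = NA_integer_,
                       passed = NA_integer_, failed = NA_integer_,
                       stringsAsFactors = FALSE)
  fail <- function(idx, stage) {
    calls$failure_stage[idx & is.na(calls$failure_stage)] <<- stage
    alive[idx] <<- FALSE
  }
  book <- function(stage, entered, failed_n) {
    i <- match(stage, ledger$stage)
    ledger$entered[i] <<- entered
    ledger$failed[i] <<- failed_n
    ledger$passed[i] <<- entered - failed_n
  }

  # -- isolation ------------------------------------------------------
  entered <- sum(alive)
  keep <- first_pass_isolate(reads$seq, motifs, min_repeats,
                             include_mutant = mut)
  fail(alive & !keep, "isolation")
  book("isolation", entered, entered - sum(alive))

  if (!is.null(restriction_sites)) {
    restriction <- restriction_site_counts(reads$seq[alive],
                                           restriction_sites)
  } else restriction <- NULL

  # -- strand ---------------------------------------------------------
  entered <- sum(alive)
  if (entered > 0) {
    sc <- classify_strand(reads$seq[alive], motifs,
                          c_strand_only = c_strand_only,
                          include_mutant = mut)
    idx <- which(alive)
    calls$g_count[idx] <- sc$g_count
    calls$c_count[idx] <- sc$c_count
    calls$g_fraction[idx] <- sc$g_fraction
    drop <- idx[!sc$keep]
    fail(seq_len(n) %in% drop, "strand")
    ok <- idx[sc$keep]
    if (length(ok)) {
      reads[ok, c("seq", "qual", "strand_tag", "oriented")] <-
        normalize_orientation(reads[ok, ], sc$verdict[sc$keep])[
          , c("seq", "qual", "strand_tag", "oriented")]
      calls$strand_tag[ok] <- sc$verdict[sc$keep]
    }
  }
  book("strand", entered, entered - sum(alive))

  # -- probe / demultiplex -------------------------------------------
  entered <- sum(alive)
  for (i in which(alive)) {
    s <- reads$seq[i]
    if (!is.null(probe)) {
      hit <- locate_capture_probe(s, probe, motifs,
                                  max_errors = probe_errors,
                                  include_mutant = mut)
      if (is.null(hit)) { fail(seq_len(n) == i, "probe"); next }
      calls$probe_start[i] <- hit$start
      calls$probe_errors[i] <- hit$errors
      calls$tandem_count[i] <- hit$tandem_count
      calls$distal_end_source[i] <- "probe"
      if (!is.null(sheet)) {
        dm <- demultiplex(s, hit, sheet, probe_length = nchar(probe))
        calls$sample_id[i] <- dm$sample_id
      }
    } else if (!is.null(sheet)) {
      dm <- demultiplex(s, NULL, sheet, motifs = motifs)
      if (is.na(dm$distal_end)) { fail(seq_len(n) == i, "probe"); next }
      calls$probe_start[i] <- dm$distal_end
      calls$sample_id[i] <- dm$sample_id
      calls$distal_end_source[i] <- "barcode"
    } else {
      calls$probe_start[i] <- nchar(s) + 1L
      calls$distal_end_source[i] <- "read_end"
    }
  }
  book("probe", entered, entered - sum(alive))
  if (is.null(sheet)) calls$sample_id[alive] <- "sample_1"

  # -- truncation -----------------------------------------------------
  entered <- sum(alive)
  for (i in which(alive))
    if (!truncation_filter(reads$seq[i], motifs, include_mutant = mut))
      fail(seq_len(n) == i, "truncation")
  book("truncation", entered, entered - sum(alive))

  # -- boundary -------------------------------------------------------
  entered <- sum(alive)
  for (i in which(alive)) {
    s <- reads$seq[i]
    ps <- calls$probe_start[i]
    bc <- switch(boundary_strategy,
      dual = detect_vrr_start(s, motifs, window_size, step, primary_pct,
                              secondary_pct, rescue_windows,
                              probe_start = ps, include_mutant = mut),
      single = detect_vrr_start_single(s, motifs, window_size, step,
                                       primary_pct, probe_start = ps,
                                       include_mutant = mut),
      consecutive = detect_vrr_start_consecutive(s, motifs,
                                                 probe_start = ps,
                                                 include_mutant = mut))
    if (is.na(bc$vrr_start)) { fail(seq_len(n) == i, "boundary"); next }
    calls$vrr_start[i] <- bc$vrr_start
  }
  book("boundary", entered, entered - sum(alive))

  # -- content --------------------------------------------------------
  entered <- sum(alive)
  for (i in which(alive)) {
    pct <- interval_coverage(reads$seq[i], motifs, calls$vrr_start[i],
                            calls$probe_start[i] - 1L,
                            include_mutant = mut)
    calls$telomere_content_pct[i] <- pct
    if (is.na(pct) || pct < 60) fail(seq_len(n) == i, "content")
  }
  book("content", entered, entered - sum(alive))

  # -- upstream -------------------------------------------------------
  entered <- sum(alive)
  for (i in which(alive))
    if (!upstream_filter(reads$seq[i], motifs, calls$vrr_start[i],
                         include_mutant = mut))
      fail(seq_len(n) == i, "upstream")
  book("upstream", entered, entered - sum(alive))

  # -- metrics for survivors -----------------------------------------
  for (i in which(alive)) {
    m <- telomere_metrics(reads$seq[i], reads$qual[i], motifs,
                          calls$vrr_start[i], calls$probe_start[i],
                          include_mutant = mut)
    calls$telomere_length[i] <- m$telomere_length
    calls$telomere_mean_quality[i] <- m$telomere_mean_quality
    calls$wt_repeat_bases[i] <- m$wt_repeat_bases
    if (mut) {
      ms <- mutant_stats(reads$seq[i], motifs, calls$vrr_start[i],
                         calls$probe_start[i])
      calls$mutant_fraction[i] <- ms$mutant_fraction
    }
  }
  if (sum(alive) == 0)
    warning("no reads passed all pipeline stages")

  res <- structure(
    list(calls = calls, ledger = ledger,
         summary = summarize_calls(calls),
         restriction = restriction, reads = reads,
         params = list(probe = probe, probe_errors = probe_errors,
                       c_strand_only = c_strand_only,
                       min_repeats = min_repeats,
                       boundary_strategy = boundary_strategy,
                       window_size = window_size, step = step,
                       primary_pct = primary_pct,
                       secondary_pct = secondary_pct,
                       rescue_windows = rescue_windows)),
    class = "telo_result")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' Per-sample summary statistics of passing reads
#'
#' @param calls per-read call table from [run_pipeline()].
#' @return data.frame with per-sample read counts, telomere length
#'   mean/median/sd and quartiles, mean telomere quality, and strand
#'   counts; reference constants `arm_count` and `uniform_arm_pct` are
#'   attached as attributes.
#' @export
summarize_calls <- function(calls) {
  ok <- calls[is.na(calls$failure_stage) & !is.na(calls$telomere_length), ,
              drop = FALSE]
  if (!nrow(ok)) {
    out <- data.frame(sample_id = character(0), n = integer(0))
  } else {
    out <- do.call(rbind, lapply(split(ok, ok$sample_id), function(d) {
      q <- quantile(d$telomere_length, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(sample_id = d$sample_id[1], n = nrow(d),
                 mean_length = mean(d$telomere_length),
                 median_length = q[2], sd_length = sd(d$telomere_length),
                 q25_length = q[1], q75_length = q[3],
                 mean_quality = mean(d$telomere_mean_quality),
                 n_c_strand = sum(d$strand_tag == "C"),
                 n_g_strand = sum(d$strand_tag == "G"),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  attr(out, "arm_count") <- diploid_arm_count()
  attr(out, "uniform_arm_pct") <- uniform_arm_expectation()
  out
}

#' Strand-specific ledgers and length distributions
#'
#' Splits the per-read results by original strand; the strand ledgers
#' partition the combined post-strand-stage counts, and per-strand probe
#' detection rates mirror enrichment-specific probe presence.
#'
#' @param result a `telo_result` from [run_pipeline()].
#' @return list with one element per strand (`C`, `G`): each a list of
#'   `n`, `probe_detection_rate`, `lengths`, and `ledger` (stage
#'   pass/fail counts for reads of that strand).
#' @export
strand_comparison_report <- function(result) {
  calls <- result$calls
  out <- lapply(c("C", "G"), function(st) {
    d <- calls[!is.na(calls$strand_tag) & calls$strand_tag == st, ,
               drop = FALSE]
    stages <- .stages[-(1:2)]
    ledger <- data.frame(
      stage = stages,
      failed = vapply(stages, function(sg)
        sum(d$failure_stage == sg, na.rm = TRUE), integer(1)),
      stringsAsFactors = FALSE)
    list(n = nrow(d),
         probe_detection_rate = if (nrow(d))
           mean(!is.na(d$probe_start)) else NA_real_,
         lengths = d$telomere_length[!is.na(d$telomere_length)],
         ledger = ledger)
  })
  names(out) <- c("C", "G")
  out
}

#' @export
print.telo_result <- function(x, ...) {
  cat("telotide pipeline result\n")
  print(x$ledger)
  cat("\nPassing reads:", sum(is.na(x$calls$failure_stage)), "of",
      nrow(x$calls), "\n")
  invisible(x)
}

.html_table <- function(df) {
  esc <- function(v) gsub("&", "&amp;", as.character(v), fixed = TRUE)
  head_row <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' cellpadding='4'>", head_row,
         paste(body, collapse = ""), "</table>")
}

#' Write pipeline outputs to a directory
#'
#' Emits `calls.tsv` (per-read, 0-based coordinates), `ledger.tsv`,
#' `summary.tsv`, and a static `report.html` assembling the tables.
#'
#' @param result a `telo_result`.
#' @param dir output directory (created if needed).
#' @return list of paths, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls_tsv <- file.path(dir, "calls.tsv")
  write_calls_tsv(result$calls, calls_tsv)
  ledger_tsv <- file.path(dir, "ledger.tsv")
  write.table(result$ledger, ledger_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary_tsv <- file.path(dir, "summary.tsv")
  write.table(result$summary, summary_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  html <- file.path(dir, "report.html")
  n_pass <- sum(is.na(result$calls$failure_stage))
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>telotide report</title></head><body>",
    "<h1>telotide pipeline report</h1>",
    sprintf("<p>%d of %d reads passed all stages.</p>",
            n_pass, nrow(result$calls)),
    "<h2>Stage ledger</h2>", .html_table(result$ledger),
    "<h2>Per-sample summary</h2>",
    if (nrow(result$summary)) .html_table(result$summary) else
      "<p>No passing reads.</p>",
    sprintf("<p>Reference: %d chromosome arms; uniform per-arm share %.2f%%.</p>",
            diploid_arm_count(),
            format_arm_expectation()),
    "</body></html>"), html)
  invisible(list(calls = calls_tsv, ledger = ledger_tsv,
                 summary = summary_tsv, html = html))
}
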