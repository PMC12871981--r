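# Synthetic telomere-enriched nanopore-like reads with ground truth.
#
# Reads follow the enrichment library structure
#   [subtelomere][VRR region][invariant telomere][capture probe][barcode]
# on either strand, with per-base substitution/indel noise and optional
# artifact classes (proximally truncated reads, tandem probes,
# probe-absent reads, mid-telomere low-quality blocks, subtelomeric
# telomere-like islands, chimeric reads). The subtelomere is scrubbed of
# telomere+1N matches before noise is applied, so the recorded boundary
# is exact by construction and any upstream signal comes from noise
# alone. Ground-truth coordinates are reported in the final (noised)
# read, in G-strand orientation.

.random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Remove all telomere+1N matches from a sequence
#'
#' Iteratively rescans the sequence and destroys every motif hit
#' (canonical, variant, or mutant, either strand) by substituting two
#' in-hit bases with their complements; spans still matching after
#' several passes are overwritten with a strongly non-telomeric `CG`
#' filler. The result contains zero telomere+1N matches and the function
#' is idempotent. Deterministic (no RNG).
#'
#' @param seq DNA string.
#' @param motifs a [telomere_motifs()] object.
#' @return scrubbed sequence of identical length.
#' @export
scrub_subtelomere <- function(seq, motifs) {
  if (!nzchar(seq)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (pass in seq_len(12)) {
    hits <- scan_motifs(paste(ch, collapse = ""), motifs,
                        include_mutant = TRUE)
    if (!nrow(hits)) break
    if (pass <= 8) {
      idx <- unique(c(hits$start + 1L, hits$start + 3L))
      idx <- idx[idx <= length(ch)]
      ch[idx] <- comp[ch[idx]]
    } else {
      # stubborn spans: overwrite with CG filler
      for (i in seq_len(nrow(hits))) {
        span <- hits$start[i]:hits$end[i]
        ch[span] <- rep(c("C", "G"), length.out = length(span))
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulation parameters
#'
#' Defaults describe a telomerase-positive human splint/duplex enrichment
#' run at nanopore-like error rates: subtelomeres of 2-5 kb, VRR regions
#' of 0.3-3 kb at 80-100% telomere+1N coverage, invariant telomeres of
#' 1-8 kb, a 12-nt capture probe, 1% substitutions and 0.2% indels.
#'
#' @param n_reads number of reads.
#' @param seed optional RNG seed fixed at cohort generation.
#' @param subtel_len_range,vrr_len_range,tel_len_range length ranges in
#'   bases (uniform draws per read).
#' @param vrr_density_range target telomere+1N coverage fraction of the
#'   VRR region.
#' @param tel_len_dist optional list(`family`, ...) overriding
#'   `tel_len_range`; supported family: `"lognormal"` with `meanlog`,
#'   `sdlog` (bases).
#' @param probe capture-probe sequence appended to each read (a synthetic
#'   12-mer by default; real runs use the enrichment oligo). `NULL`
#'   simulates probe-free libraries.
#' @param sheet optional `telo_sample_sheet`; barcodes are appended after
#'   the probe, cycling over samples.
#' @param strand_mix fraction of reads left in G orientation (the rest
#'   are reverse-complemented to C strand).
#' @param error_rates named vector: `substitution`, `insertion`,
#'   `deletion` per-base probabilities.
#' @param artifact_rates named vector of per-read artifact class
#'   probabilities: `truncated`, `tandem_probe`, `probe_absent`,
#'   `low_quality_block`, `telomere_island`, `chimeric`.
#' @param qual_range per-read baseline Phred range.
#' @param artifact_qual_range Phred range inside injected low-quality
#'   blocks.
#' @param tail_len_range scrubbed random tail appended after probe or
#'   barcode (adapter remnant).
#' @return a `telo_sim_spec` list.
#' @export
sim_spec <- function(n_reads = 400,
                     seed = NULL,
                     subtel_len_range = c(2000, 5000),
                     vrr_len_range = c(300, 3000),
                     vrr_density_range = c(0.8, 1.0),
                     tel_len_range = c(1000, 8000),
                     tel_len_dist = NULL,
                     probe = "TACGACTGCAGT",
                     sheet = NULL,
                     strand_mix = 0.5,
                     error_rates = c(substitution = 0.01,
                                     insertion = 0.001,
                                     deletion = 0.001),
                     artifact_rates = c(truncated = 0, tandem_probe = 0,
                                        probe_absent = 0,
                                        low_quality_block = 0,
                                        telomere_island = 0,
                                        chimeric = 0),
                     qual_range = c(12, 20),
                     artifact_qual_range = c(3, 9),
                     tail_len_range = c(0, 30)) {
  stopifnot(n_reads >= 1,
            all(error_rates >= 0 & error_rates <= 1),
            all(artifact_rates >= 0 & artifact_rates <= 1),
            strand_mix >= 0, strand_mix <= 1,
            diff(range(subtel_len_range)) >= 0,
            vrr_len_range[1] > 0, tel_len_range[1] > 0)
  if (!is.null(probe)) .check_dna(probe, "probe")
  ar <- c(truncated = 0, tandem_probe = 0, probe_absent = 0,
          low_quality_block = 0, telomere_island = 0, chimeric = 0)
  ar[names(artifact_rates)] <- artifact_rates
  er <- c(substitution = 0, insertion = 0, deletion = 0)
  er[names(error_rates)] <- error_rates
  structure(list(n_reads = n_reads, seed = seed,
                 subtel_len_range = subtel_len_range,
                 vrr_len_range = vrr_len_range,
                 vrr_density_range = vrr_density_range,
                 tel_len_range = tel_len_range,
                 tel_len_dist = tel_len_dist,
                 probe = probe, sheet = sheet, strand_mix = strand_mix,
                 error_rates = er, artifact_rates = ar,
                 qual_range = qual_range,
                 artifact_qual_range = artifact_qual_range,
                 tail_len_range = tail_len_range),
            class = "telo_sim_spec")
}

.runif_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  as.integer(floor(runif(1, range[1], range[2] + 1)))
}

# VRR block: canonical/variant repeat units separated by short random
# spacers sized so motif bases make up roughly `density` of the block.
.make_vrr <- function(motifs, len, density) {
  units <- character(0)
  total <- 0L
  variants <- setdiff(motifs$variants_g, motifs$canonical)
  lambda <- 6 * (1 - density) / density
  while (total < len) {
    u <- if (runif(1) < 0.5) motifs$canonical else sample(variants, 1)
    units <- c(units, u)
    total <- total + nchar(u)
    sp <- stats::rpois(1, lambda)
    if (sp > 0) {
      units <- c(units, .random_dna(sp))
      total <- total + sp
    }
  }
  substr(paste(units, collapse = ""), 1, len)
}

.draw_tel_len <- function(spec) {
  d <- spec$tel_len_dist
  if (is.null(d)) return(.runif_int(spec$tel_len_range))
  if (identical(d$family, "lognormal"))
    return(max(60L, as.integer(stats::rlnorm(1, d$meanlog, d$sdlog))))
  stop("unsupported telomere length distribution: ", d$family)
}

# Inject substitution/indel noise; `track` holds 1-based positions whose
# post-noise coordinates are needed (boundary, probe start). Inserted
# bases inherit the local quality.
.inject_errors <- function(ch, qv, er, track) {
  n <- length(ch)
  if (n == 0L) return(list(ch = ch, qv = qv, track = track))
  del <- runif(n) < er[["deletion"]]
  sub <- !del & runif(n) < er[["substitution"]]
  ins <- runif(n) < er[["insertion"]]
  if (any(sub)) {
    code <- c(A = 0L, C = 1L, G = 2L, T = 3L)[ch[sub]]
    ch[sub] <- c("A", "C", "G", "T")[
      ((code + sample(1:3, sum(sub), replace = TRUE)) %% 4L) + 1L]
  }
  emitted <- as.integer(!del) + as.integer(ins)
  before <- c(0L, cumsum(emitted))[seq_len(n)]
  new_track <- vapply(track, function(p) {
    if (is.na(p)) NA_integer_ else if (p > n) before[n] + emitted[n] + 1L
    else before[p] + 1L
  }, integer(1))
  ins_ch <- character(n)
  if (any(ins)) ins_ch[ins] <- sample(c("A", "C", "G", "T"), sum(ins),
                                      replace = TRUE)
  p1 <- ifelse(del, "", ch)
  p2 <- ifelse(ins, ins_ch, "")
  q1 <- ifelse(del, "", qv)
  q2 <- ifelse(ins, qv, "")
  out_ch <- strsplit(paste0(paste0(p1, p2), collapse = ""), "")[[1]]
  out_qv <- strsplit(paste0(paste0(q1, q2), collapse = ""), "")[[1]]
  list(ch = out_ch, qv = out_qv, track = new_track)
}

#' Generate one synthetic read with ground truth
#'
#' Uses the current RNG state; see [simulate_cohort()] for seeded
#' cohorts.
#'
#' @param spec a [sim_spec()] object.
#' @param motifs a [telomere_motifs()] object.
#' @param read_id identifier for the read.
#' @return list with `read` (one-row `telo_reads`) and `truth` (one-row
#'   data.frame: `read_id`, `strand`, `vrr_start`, `probe_start`,
#'   `barcode`, `artifact`; 1-based G-orientation coordinates in the
#'   final read, `NA` where an artifact removes the landmark).
#' @export
simulate_read <- function(spec, motifs, read_id = "read_1") {
  ar <- spec$artifact_rates
  art <- names(ar)[runif(length(ar)) < ar]
  # mutually exclusive structural artifacts: keep the first drawn
  structural <- intersect(art, c("chimeric", "truncated"))
  if (length(structural) > 1) art <- setdiff(art, structural[-1])

  base_q <- .runif_int(spec$qual_range)
  subtel <- scrub_subtelomere(.random_dna(.runif_int(spec$subtel_len_range)),
                              motifs)
  if ("telomere_island" %in% art && nchar(subtel) > 600) {
    island <- strrep(motifs$canonical, 30)  # 180 bp telomere-like island
    at <- .runif_int(c(200, nchar(subtel) - 400 - nchar(island)))
    subtel <- paste0(substr(subtel, 1, at), island,
                     substr(subtel, at + nchar(island) + 1, nchar(subtel)))
  }
  vrr <- .make_vrr(motifs, .runif_int(spec$vrr_len_range),
                   runif(1, spec$vrr_density_range[1],
                         spec$vrr_density_range[2]))
  tel_len <- .draw_tel_len(spec)
  tel <- substr(strrep(motifs$canonical,
                       ceiling(tel_len / nchar(motifs$canonical))),
                1, tel_len)
  qpieces <- list(c(len = nchar(subtel) + nchar(vrr) + nchar(tel),
                    q = base_q))

  if ("low_quality_block" %in% art && nchar(tel) > 1500) {
    block <- scrub_subtelomere(.random_dna(.runif_int(c(400, 800))), motifs)
    at <- .runif_int(c(500, nchar(tel) - 500 - nchar(block)))
    tel <- paste0(substr(tel, 1, at), block,
                  substr(tel, at + nchar(block) + 1, nchar(tel)))
    lowq <- .runif_int(spec$artifact_qual_range)
    pre <- nchar(subtel) + nchar(vrr) + at
    qpieces <- list(c(len = pre, q = base_q),
                    c(len = nchar(block), q = lowq),
                    c(len = nchar(tel) - at - nchar(block), q = base_q))
  }

  probe <- if (is.null(spec$probe) || "probe_absent" %in% art) "" else
    spec$probe
  if (nzchar(probe) && "tandem_probe" %in% art)
    probe <- strrep(spec$probe, 2)
  barcode <- NA_character_
  if (!is.null(spec$sheet)) {
    i <- .runif_int(c(1, nrow(spec$sheet$entries)))
    barcode <- spec$sheet$entries$barcode[i]
  }
  tail_seq <- scrub_subtelomere(.random_dna(.runif_int(spec$tail_len_range)),
                                motifs)

  core <- paste0(subtel, vrr, tel)
  vrr_start <- nchar(subtel) + 1L
  probe_start <- nchar(core) + 1L
  suffix <- paste0(probe, if (!is.na(barcode)) barcode else "", tail_seq)

  if ("chimeric" %in% art) {
    # two ligated molecules with opposite strand telomeres of similar size
    other <- revcomp(substr(strrep(motifs$canonical,
                                   ceiling(nchar(tel) / 6)), 1, nchar(tel)))
    core <- paste0(subtel, tel, other)
    vrr_start <- NA_integer_
    probe_start <- NA_integer_
    suffix <- ""
    qpieces <- list(c(len = nchar(core), q = base_q))
  } else if ("truncated" %in% art) {
    # read begins inside the VRR region: no complete subtelomere
    cut <- nchar(subtel) + .runif_int(c(1, max(1, nchar(vrr) - 50)))
    core <- substr(core, cut + 1L, nchar(core))
    vrr_start <- NA_integer_
    probe_start <- probe_start - cut
    qpieces <- list(c(len = nchar(core), q = base_q))
  }

  full <- paste0(core, suffix)
  qv <- unlist(lapply(qpieces, function(p)
    rep(intToUtf8(p[["q"]] + 33L), p[["len"]])))
  qv <- c(qv, rep(intToUtf8(base_q + 33L), nchar(suffix)))
  ch <- strsplit(full, "", fixed = TRUE)[[1]]

  noised <- .inject_errors(ch, qv, spec$error_rates,
                           c(vrr_start, probe_start))
  seq_g <- paste(noised$ch, collapse = "")
  qual_g <- paste(noised$qv, collapse = "")
  vrr_start <- noised$track[1]
  # the distal landmark is the probe start, or the barcode start in
  # probe-free multiplexed libraries
  probe_start <- if (nzchar(probe) || !is.na(barcode))
    noised$track[2] else NA_integer_

  strand <- if (runif(1) < spec$strand_mix) "G" else "C"
  if ("chimeric" %in% art) strand <- "chimeric"
  seq_out <- seq_g
  qual_out <- qual_g
  if (strand == "C") {
    seq_out <- revcomp(seq_g)
    qual_out <- .reverse_string(qual_g)
  }
  read <- .new_reads(read_id, seq_out, qual_out)
  truth <- data.frame(read_id = read_id, strand = strand,
                      vrr_start = vrr_start, probe_start = probe_start,
                      barcode = barcode,
                      artifact = if (length(art))
                        paste(art, collapse = ",") else "none",
                      stringsAsFactors = FALSE)
  list(read = read, truth = truth)
}

#' Generate a cohort of synthetic reads
#'
#' With `spec$seed` set the cohort is fully reproducible (and
#' [write_cohort()] outputs are byte-identical across runs).
#'
#' @param spec a [sim_spec()] object.
#' @param motifs a [telomere_motifs()] object (default canonical
#'   vertebrate repeat).
#' @return list with `reads` (a `telo_reads` data.frame) and `truth`
#'   (ground-truth data.frame, one row per read).
#' @export
simulate_cohort <- function(spec, motifs = telomere_motifs()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  out <- lapply(seq_len(spec$n_reads), function(i)
    simulate_read(spec, motifs, sprintf("read_%04d", i)))
  reads <- do.call(rbind, lapply(out, `[[`, "read"))
  class(reads) <- c("telo_reads", "data.frame")
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  list(reads = reads, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' @param spec a [sim_spec()] object.
#' @param dir output directory (created if needed); writes
#'   `reads.fastq.gz` and `truth.tsv`.
#' @param motifs a [telomere_motifs()] object.
#' @return list of output paths, invisibly.
#' @export
write_cohort <- function(spec, dir, motifs = telomere_motifs()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(spec, motifs)
  fq <- file.path(dir, "reads.fastq.gz")
  tsv <- file.path(dir, "truth.tsv")
  write_reads(cohort$reads, fq)
  write_ground_truth(cohort$truth, tsv)
  invisible(list(fastq = fq, truth = tsv))
}
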