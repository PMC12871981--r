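# Synthetic read generator: scrubbing, structure, error model, and
# ground-truth bookkeeping.

test_that("scrubbing removes every telomere+1N match and is idempotent", {
  m <- telomere_motifs()
  set.seed(81)
  for (i in 1:5) {
    raw <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 collapse = "")
    # seed some real motifs so scrubbing has work to do
    raw <- paste0(strrep("GGTTAG", 3), raw, "CTAACC", raw)
    s <- scrub_subtelomere(raw, m)
    expect_identical(nrow(scan_motifs(s, m)), 0L)
    expect_identical(nchar(s), nchar(raw))
    expect_identical(scrub_subtelomere(s, m), s)
    # edits are bounded by the number of bases the pass touched
    h <- brute_scan(raw, m)
    expect_lte(lev(s, raw), max(2 * nrow(h) * 4, 2))
  }
})

test_that("clean simulation recovers truth exactly through the pipeline", {
  m <- telomere_motifs()
  spec <- sim_spec(n_reads = 12, seed = 82,
                   subtel_len_range = c(1500, 2500),
                   vrr_len_range = c(300, 800),
                   tel_len_range = c(800, 1500),
                   error_rates = c(substitution = 0, insertion = 0,
                                   deletion = 0))
  co <- simulate_cohort(spec)
  expect_identical(nrow(co$reads), 12L)

  res <- run_pipeline(co$reads, m, probe = spec$probe)
  expect_true(all(is.na(res$calls$failure_stage)))
  ev <- evaluate_mae(res$calls, co$truth)
  expect_identical(ev$n_called, 12L)
  # noise-free calls sit on the recorded junction up to the one-base
  # ambiguity of junction-straddling insertion variants
  expect_lte(ev$mae, 1)
  expect_true(all(ev$errors <= 0))

  # probe positions recovered exactly on the G-oriented reads
  probe_calls <- res$calls$probe_start
  expect_identical(probe_calls, co$truth$probe_start)
})

test_that("ground truth tracks coordinates through indel noise", {
  # indel-only noise shifts downstream coordinates; the recorded truth
  # must point at the probe's actual post-noise position. A probe hit
  # can only be absent when an indel landed inside the probe itself.
  m <- telomere_motifs()
  spec <- sim_spec(n_reads = 10, seed = 83,
                   error_rates = c(substitution = 0, insertion = 0.004,
                                   deletion = 0.004))
  co <- simulate_cohort(spec)
  found <- 0L
  for (i in seq_len(10)) {
    s <- co$reads$seq[i]
    if (co$truth$strand[i] == "C") s <- revcomp(s)
    ps <- co$truth$probe_start[i]
    hits <- fuzzy_find_all(s, spec$probe, 0)
    # any terminal-region hit must sit exactly on the recorded truth
    near_end <- hits$start[hits$start > nchar(s) - 100]
    if (length(near_end)) {
      expect_identical(near_end, ps)
      found <- found + 1L
    }
  }
  expect_gte(found, 8L)
})

test_that("artifact classes are produced and removed at their stages", {
  m <- telomere_motifs()

  # truncated reads start inside the VRR and fail the truncation filter
  spec_t <- sim_spec(n_reads = 10, seed = 84,
                     error_rates = c(substitution = 0, insertion = 0,
                                     deletion = 0),
                     artifact_rates = c(truncated = 1))
  co_t <- simulate_cohort(spec_t)
  expect_true(all(is.na(co_t$truth$vrr_start)))
  for (i in 1:10) {
    s <- co_t$reads$seq[i]
    if (co_t$truth$strand[i] == "C") s <- revcomp(s)
    expect_false(truncation_filter(s, m))
  }

  # probe-absent reads yield no probe hit
  spec_p <- sim_spec(n_reads = 6, seed = 85,
                     error_rates = c(substitution = 0, insertion = 0,
                                     deletion = 0),
                     artifact_rates = c(probe_absent = 1))
  co_p <- simulate_cohort(spec_p)
  for (i in 1:6) {
    s <- co_p$reads$seq[i]
    if (co_p$truth$strand[i] == "C") s <- revcomp(s)
    expect_null(locate_capture_probe(s, spec_p$probe, m))
  }

  # tandem probes fold into tandem_count
  spec_d <- sim_spec(n_reads = 6, seed = 86,
                     error_rates = c(substitution = 0, insertion = 0,
                                     deletion = 0),
                     artifact_rates = c(tandem_probe = 1))
  co_d <- simulate_cohort(spec_d)
  for (i in 1:6) {
    s <- co_d$reads$seq[i]
    if (co_d$truth$strand[i] == "C") s <- revcomp(s)
    hit <- locate_capture_probe(s, spec_d$probe, m)
    expect_identical(hit$tandem_count, 1L)
  }

  # chimeric reads carry both strand orientations and are flagged
  spec_c <- sim_spec(n_reads = 6, seed = 87,
                     artifact_rates = c(chimeric = 1))
  co_c <- simulate_cohort(spec_c)
  sc <- classify_strand(co_c$reads$seq, m)
  expect_true(all(sc$verdict == "chimeric"))
})

test_that("cohort writing is deterministic and complete", {
  spec <- sim_spec(n_reads = 15, seed = 88)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  p1 <- write_cohort(spec, d1)
  p2 <- write_cohort(spec, d2)

  r1 <- read_reads(p1$fastq)
  r2 <- read_reads(p2$fastq)
  expect_identical(r1, r2)
  expect_identical(readLines(p1$truth), readLines(p2$truth))
  expect_identical(nrow(r1), 15L)
  expect_identical(nrow(read_ground_truth(p1$truth)), 15L)
})

test_that("strand mix and length distribution match the generator", {
  spec <- sim_spec(n_reads = 300, seed = 89, strand_mix = 0.5,
                   subtel_len_range = c(500, 800),
                   vrr_len_range = c(200, 300),
                   tel_len_range = c(500, 1000))
  co <- simulate_cohort(spec)
  n_g <- sum(co$truth$strand == "G")
  # binomial 99% interval around 0.5
  bounds <- qbinom(c(0.005, 0.995), 300, 0.5)
  expect_gte(n_g, bounds[1])
  expect_lte(n_g, bounds[2])

  # recovered telomere length (probe minus boundary) is centred on the
  # generating distribution: tel + vrr mean within Monte-Carlo error
  res <- run_pipeline(co$reads, telomere_motifs(), probe = spec$probe)
  ok <- !is.na(res$calls$telomere_length)
  expect_gt(mean(ok), 0.8)
  got_mean <- mean(res$calls$telomere_length[ok])
  want_mean <- mean(c(500, 1000)) + mean(c(200, 300))
  expect_lt(abs(got_mean - want_mean) / want_mean, 0.1)
})
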