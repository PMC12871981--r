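# Post-boundary filters, telomere metrics, and auxiliary statistics.

test_that("truncation filter removes reads starting in repeats", {
  m <- telomere_motifs()

  # read beginning in pure repeats: ~100% telomere+1N in the prefix
  expect_false(truncation_filter(strrep("GGTTAG", 100), m))
  # scrubbed subtelomeric start passes
  cons <- make_construct(subtel_n = 1000, tel_n = 600, seed = 71)
  expect_true(truncation_filter(cons$seq, m))

  # exactly 20.0% coverage passes (strict inequality), and one more
  # repeat tips it over; C homopolymer filler carries no motif
  at20 <- paste0(strrep("GGTTAG", 10), strrep("C", 240),
                 scrubbed_bg(500, 72))
  expect_equal(interval_coverage(at20, m, 1, 300), 20)
  expect_true(truncation_filter(at20, m))
  over <- paste0(strrep("GGTTAG", 11), strrep("C", 234),
                 scrubbed_bg(500, 72))
  expect_false(truncation_filter(over, m))
})

test_that("telomere content filter separates true telomeres from mimics", {
  m <- telomere_motifs()
  cons <- make_construct(subtel_n = 800, tel_n = 1200, seed = 73)

  # simulated true telomere is well above 60% telomere+1N
  expect_gt(interval_coverage(cons$seq, m, cons$vrr_start,
                              cons$probe_start - 1), 80)
  expect_true(telomere_content_filter(cons$seq, m, cons$vrr_start,
                                      cons$probe_start))

  # interstitial mimic at ~40% content fails
  mimic_tel <- paste(rep(c("GGTTAG", "ACGGATTCG"), 60), collapse = "")
  mimic <- paste0(substr(cons$seq, 1, cons$vrr_start - 1), mimic_tel)
  ps <- cons$vrr_start + nchar(mimic_tel)
  expect_lt(interval_coverage(mimic, m, cons$vrr_start, ps - 1), 60)
  expect_false(telomere_content_filter(mimic, m, cons$vrr_start, ps))

  # a long-VRR read at ~65% content is retained
  loose_tel <- paste(rep(c("GGTTAGGCTTAG", "ACGGAT"), 60), collapse = "")
  loose <- paste0(substr(cons$seq, 1, cons$vrr_start - 1), loose_tel)
  ps <- cons$vrr_start + nchar(loose_tel)
  got <- interval_coverage(loose, m, cons$vrr_start, ps - 1)
  expect_gt(got, 60)
  expect_lt(got, 80)
  expect_true(telomere_content_filter(loose, m, cons$vrr_start, ps))
})

test_that("upstream filter catches repeat-rich context before the boundary", {
  m <- telomere_motifs()
  cons <- make_construct(subtel_n = 2500, tel_n = 800, seed = 74)
  expect_true(upstream_filter(cons$seq, m, cons$vrr_start))

  # displaced boundary with telomeric sequence upstream fails
  mid_tel <- cons$probe_start - 400L
  expect_false(upstream_filter(cons$seq, m, mid_tel))

  # genuine repeat-rich subtelomere (~30% content upstream) also fails
  rich <- paste0(scrubbed_bg(1000, 75),
                 paste(rep(c("GGTTAG", "ACGGATTCGAAGCA"), 100),
                       collapse = ""))
  vs <- nchar(rich) + 1L
  rich <- paste0(rich, strrep("GGTTAG", 100))
  expect_gt(interval_coverage(rich, m, vs - 2000, vs - 1), 10)
  expect_false(upstream_filter(rich, m, vs))

  # a boundary at the very start of the read has no upstream context
  expect_true(upstream_filter(cons$seq, m, 1L))
})

test_that("telomere metrics follow interval arithmetic", {
  m <- telomere_motifs()
  seq <- paste0(scrubbed_bg(1000, 76), strrep("GGTTAG", 500))
  qual <- paste0(phred_string(12, 1000), phred_string(20, 3000))
  res <- telomere_metrics(seq, qual, m, 1001L, 4001L)
  expect_identical(res$telomere_length, 3000L)
  expect_equal(res$telomere_mean_quality, 20)

  # wild-type covered bases never exceed telomere+1N bases or length
  cons <- make_construct(subtel_n = 600, tel_n = 900, seed = 77)
  q <- phred_string(15, nchar(cons$seq))
  met <- telomere_metrics(cons$seq, q, m, cons$vrr_start, cons$probe_start)
  expect_lte(met$wt_repeat_bases, met$telo1n_bases)
  expect_lte(met$telo1n_bases, met$telomere_length)
  # brute-force canonical coverage mask agrees
  mask <- brute_mask(cons$seq, m)
  iv <- cons$vrr_start:(cons$probe_start - 1)
  expect_identical(met$telo1n_bases, sum(mask[iv]))
})

test_that("restriction sites are counted once per read, either strand", {
  set.seed(78)
  # backgrounds are random apart from telomeric scrubbing, so compare
  # against a direct per-read search oracle (forward or reverse strand,
  # counted at most once per read)
  oracle <- function(reads, site)
    sum(grepl(site, reads, fixed = TRUE) |
          grepl(site, vapply(reads, revcomp, character(1)),
                fixed = TRUE))
  bgs <- vapply(1:10, function(i) scrubbed_bg(400, 780 + i), character(1))
  reads <- bgs
  reads[1] <- paste0(substr(bgs[1], 1, 100), "GATATC", bgs[1])
  reads[2] <- paste0("GATATC", substr(bgs[2], 1, 50), "GATATC", bgs[2])
  reads[3] <- paste0(bgs[3], "GATATC")
  reads[4] <- paste0(bgs[4], revcomp("GGATCC"))
  sites <- c("GATATC", "GGATCC", "TTCGAA")
  counts <- restriction_site_counts(reads, sites)
  for (s in sites)
    expect_identical(counts[[s]], oracle(reads, s))
  # planted reads are certainly included; duplicates count once
  expect_gte(counts[["GATATC"]], 3L)
  expect_gte(counts[["GGATCC"]], 1L)
  # a site absent from every read (checked by the oracle) counts zero
  absent <- "TTAATTAACGCGAT"
  stopifnot(oracle(reads, absent) == 0)
  expect_identical(restriction_site_counts(reads, absent)[[1]], 0L)
})

test_that("mutant statistics require mutant mode and tally repeats", {
  mwt <- telomere_motifs()
  mmu <- telomere_motifs(mutant = "GTGTAG")

  tel <- strrep(paste0("GTGTAG", "GGTTAG"), 100)
  seq <- paste0(scrubbed_bg(300, 79), tel)
  vs <- nchar(seq) - nchar(tel) + 1L
  ps <- nchar(seq) + 1L

  st <- mutant_stats(seq, mmu, vs, ps)
  expect_equal(st$mutant_fraction, 0.5)
  expect_identical(st$mutant_repeat_count, st$wt_repeat_count)

  # without mutant motifs the fraction is undefined
  st0 <- mutant_stats(seq, mwt, vs, ps)
  expect_true(is.na(st0$mutant_fraction))

  # a distal mutant-only telomere passes the content filter only in
  # mutant mode
  mut_tel <- strrep("GTGTAG", 200)
  mseq <- paste0(scrubbed_bg(600, 80), mut_tel)
  vs <- nchar(mseq) - nchar(mut_tel) + 1L
  ps <- nchar(mseq) + 1L
  expect_true(telomere_content_filter(mseq, mmu, vs, ps,
                                      include_mutant = TRUE))
  expect_false(telomere_content_filter(mseq, mwt, vs, ps))
})

test_that("cluster-prep trimming clips at read bounds", {
  seq <- paste(rep(c("ACGT"), 2500), collapse = "")  # 10 kb

  t1 <- trim_for_clustering(seq, 5001L, before = 1000, after = 3000)
  expect_identical(nchar(t1), 4000L)
  expect_identical(substr(t1, 1001, 1004), substr(seq, 5001, 5004))

  # clipping at the front
  t2 <- trim_for_clustering(seq, 500L, before = 1000, after = 3000)
  expect_identical(nchar(t2), 500L - 1L + 3000L)
  expect_identical(substr(t2, 1, 4), substr(seq, 1, 4))

  # clipping at the back: 1000 bases before plus boundary-to-read-end
  t3 <- trim_for_clustering(seq, 9000L, before = 1000, after = 3000)
  expect_identical(nchar(t3), 1000L + (10000L - 9000L + 1L))

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_trimmed_fasta(c(r1 = t1, r2 = t2), fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back[["r1"]]), t1)
})
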