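# Independent brute-force oracles used to check the scanning kernels.

# Levenshtein distance via base R's generalized edit distance.
lev <- function(a, b) drop(utils::adist(a, b))

# All motif occurrences by direct substring comparison (no hashing),
# then greedy left-to-right selection under the documented precedence:
# canonical outranks everything at a position, then longest, then
# variant over mutant.
brute_scan <- function(seq, motifs, include_variants = TRUE,
                       include_mutant = FALSE) {
  tab <- telotide:::.motif_table(motifs, include_variants, include_mutant)
  n <- nchar(seq)
  cand <- list()
  for (r in seq_len(nrow(tab))) {
    m <- tab$motif[r]
    L <- nchar(m)
    if (L > n) next
    for (i in seq_len(n - L + 1)) {
      if (substr(seq, i, i + L - 1) == m)
        cand[[length(cand) + 1]] <- data.frame(
          start = i, width = L, kind = tab$kind[r], strand = tab$strand[r])
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), width = integer(0),
                      kind = integer(0), strand = integer(0)))
  cand <- do.call(rbind, cand)
  # collapse duplicate strings under kind priority
  cand <- cand[order(cand$start, cand$kind), ]
  cand <- cand[!duplicated(cand[, c("start", "width")]), ]
  # precedence at a position: canonical first, then longest, then kind
  cand <- cand[order(cand$start, cand$kind != 0, -cand$width, cand$kind), ]
  out <- list()
  pos <- 1L
  repeat {
    nxt <- cand[cand$start >= pos, , drop = FALSE]
    if (!nrow(nxt)) break
    pick <- nxt[nxt$start == min(nxt$start), , drop = FALSE][1, ]
    out[[length(out) + 1]] <- pick
    pos <- pick$start + pick$width
  }
  do.call(rbind, out)
}

# Per-base telomere+1N coverage mask from the brute-force scan.
brute_mask <- function(seq, motifs, ...) {
  h <- brute_scan(seq, motifs, ...)
  m <- logical(nchar(seq))
  for (i in seq_len(nrow(h)))
    m[h$start[i]:(h$start[i] + h$width[i] - 1)] <- TRUE
  m
}

# Naive exact substring search (all, possibly overlapping, occurrences).
naive_exact_find <- function(seq, pattern) {
  n <- nchar(seq)
  L <- nchar(pattern)
  if (L > n) return(integer(0))
  which(vapply(seq_len(n - L + 1),
               function(i) substr(seq, i, i + L - 1) == pattern,
               logical(1)))
}

# First run of k chained telomere+1N hits (each starting where the
# previous ended), by direct inspection of the brute-force hit list.
brute_first_run <- function(seq, motifs, k) {
  h <- brute_scan(seq, motifs)
  n <- nrow(h)
  if (n < k) return(NA_integer_)
  for (i in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k - 1)) {
      if (h$start[i + j] != h$start[i + j - 1] + h$width[i + j - 1]) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(h$start[i])
  }
  NA_integer_
}

# Deterministic scrubbed background for planting constructs.
scrubbed_bg <- function(n, seed) {
  set.seed(seed)
  scrub_subtelomere(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = ""), telomere_motifs())
}

# A read construct [subtelomere][VRR][telomere][probe][tail], noise-free,
# with a substitution-variant first VRR unit so the junction is clean.
make_construct <- function(subtel_n = 1200, vrr = NULL, tel_n = 1200,
                           probe = "TACGACTGCAGT", seed = 1,
                           tail = "") {
  m <- telomere_motifs()
  subtel <- scrubbed_bg(subtel_n, seed)
  if (is.null(vrr))
    vrr <- paste0("AGTTAG", strrep(paste0("GGTTAG", "GCTTAG"), 40))
  # scrubbing guarantees a motif-free subtelomere, but windows straddling
  # the junction can still match (any base extends a canonical repeat to
  # a front-insertion variant); trim until the junction itself is clean
  subtel <- clean_junction(subtel, vrr)
  tel <- strrep("GGTTAG", ceiling(tel_n / 6))
  list(seq = paste0(subtel, vrr, tel, probe, tail),
       vrr_start = nchar(subtel) + 1L,
       probe_start = nchar(subtel) + nchar(vrr) + nchar(tel) + 1L,
       motifs = m, probe = probe)
}

phred_string <- function(q, n) strrep(intToUtf8(q + 33), n)

# Trim a scrubbed background so that no telomere+1N match straddles its
# junction with the following telomeric block.
clean_junction <- function(subtel, nxt) {
  m <- telomere_motifs()
  repeat {
    n <- nchar(subtel)
    sub_len <- min(12, n)
    region <- paste0(substr(subtel, n - sub_len + 1, n),
                     substr(nxt, 1, 7))
    h <- scan_motifs(region, m)
    if (!any(h$start <= sub_len)) return(subtel)
    subtel <- substr(subtel, 1, n - 1)
  }
}
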