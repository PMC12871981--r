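# Subtelomere-to-telomere boundary (VRR-region start) detection.
#
# The transition into the telomere is marked by a sharp rise in
# telomere+1N repeat content. The production detector uses a dual
# threshold on a jumping window: a primary trigger at 60% coverage, after
# which content may dip but must not stay below a secondary 5% threshold
# for a long run of consecutive windows. Two simpler strategies (single
# threshold, first run of consecutive repeats) are retained for
# benchmarking.

.no_call <- function(algorithm, params, reason) {
  list(vrr_start = NA_integer_, trigger_window_start = NA_integer_,
       algorithm = algorithm, params = params, reason = reason)
}

#' Detect the VRR-region start with the dual-threshold jumping window
#'
#' Windows are scanned 5' to 3'. The first window whose telomere+1N
#' coverage reaches `primary_pct` proposes a candidate start: the first
#' telomere+1N hit beginning at or after that window's start. The
#' candidate is invalidated only when at least `rescue_windows`
#' consecutive later windows all fall below `secondary_pct`; shorter
#' sub-threshold dips (basecalling wobble, diffuse variant blocks) are
#' tolerated. After an invalidating run the scan resumes beyond it, so a
#' genuine boundary downstream of an artifact can still be found. When a
#' capture probe position is known, windows are evaluated only up to the
#' probe.
#'
#' @param seq oriented read sequence (G orientation).
#' @param motifs a [telomere_motifs()] object.
#' @param window_size jumping-window width in bases (default 100).
#' @param step window increment in bases (default 15).
#' @param primary_pct trigger threshold, percent coverage (default 60).
#' @param secondary_pct floor threshold, percent coverage (default 5).
#' @param rescue_windows consecutive sub-`secondary_pct` windows needed to
#'   reject a candidate (default 15; about 225 bp at defaults).
#' @param probe_start optional 1-based probe start limiting the scan.
#' @param include_mutant score mutant motifs as telomeric.
#' @return list with `vrr_start` (1-based or `NA`),
#'   `trigger_window_start`, `algorithm`, `params`, and `reason` when no
#'   call was made.
#' @export
detect_vrr_start <- function(seq, motifs, window_size = 100, step = 15,
                             primary_pct = 60, secondary_pct = 5,
                             rescue_windows = 15, probe_start = NULL,
                             include_mutant = FALSE) {
  params <- list(window_size = window_size, step = step,
                 primary_pct = primary_pct, secondary_pct = secondary_pct,
                 rescue_windows = rescue_windows)
  prof <- coverage_profile(seq, motifs, window_size, step,
                           include_mutant = include_mutant,
                           region_end = probe_start)
  if (attr(prof, "truncated"))
    return(.no_call("dual_threshold", params, "read shorter than window"))
  hits <- scan_motifs(seq, motifs, include_mutant = include_mutant)
  cov <- prof$coverage_pct
  ws <- prof$window_start
  K <- length(cov)
  k <- 1L
  while (k <= K) {
    if (cov[k] >= primary_pct) {
      cand <- hits$start[hits$start >= ws[k]]
      cand <- if (length(cand)) cand[1] else NA_integer_
      run <- 0L
      invalid <- FALSE
      j <- k + 1L
      while (j <= K) {
        if (cov[j] < secondary_pct) {
          run <- run + 1L
          if (run >= rescue_windows) {
            invalid <- TRUE
            while (j + 1L <= K && cov[j + 1L] < secondary_pct) j <- j + 1L
            break
          }
        } else {
          run <- 0L
        }
        j <- j + 1L
      }
      if (!invalid && !is.na(cand))
        return(list(vrr_start = cand, trigger_window_start = ws[k],
                    algorithm = "dual_threshold", params = params,
                    reason = NA_character_))
      k <- j + 1L
    } else {
      k <- k + 1L
    }
  }
  .no_call("dual_threshold", params, "no window reached primary threshold")
}

#' Detect the VRR-region start with a single maintained threshold
#'
#' Benchmarking strategy: the candidate window must reach `primary_pct`
#' and every later window (up to the probe when known) must stay at or
#' above it. Telomere-like islands in the subtelomere therefore cannot
#' trigger a premature call, but any genuine dip after the boundary
#' rejects the read's earlier trigger and pushes the call downstream.
#'
#' @inheritParams detect_vrr_start
#' @return as [detect_vrr_start()], with `algorithm = "single_threshold"`.
#' @export
detect_vrr_start_single <- function(seq, motifs, window_size = 100,
                                    step = 15, primary_pct = 60,
                                    probe_start = NULL,
                                    include_mutant = FALSE) {
  params <- list(window_size = window_size, step = step,
                 primary_pct = primary_pct)
  prof <- coverage_profile(seq, motifs, window_size, step,
                           include_mutant = include_mutant,
                           region_end = probe_start)
  if (attr(prof, "truncated"))
    return(.no_call("single_threshold", params, "read shorter than window"))
  cov <- prof$coverage_pct
  ws <- prof$window_start
  K <- length(cov)
  below <- which(cov < primary_pct)
  k <- if (length(below)) max(below) + 1L else 1L
  if (k > K)
    return(.no_call("single_threshold", params,
                    "threshold not maintained to read end"))
  hits <- scan_motifs(seq, motifs, include_mutant = include_mutant)
  cand <- hits$start[hits$start >= ws[k]]
  if (!length(cand))
    return(.no_call("single_threshold", params, "no hit after trigger"))
  list(vrr_start = cand[1], trigger_window_start = ws[k],
       algorithm = "single_threshold", params = params,
       reason = NA_character_)
}

#' Detect the VRR-region start as the first run of consecutive repeats
#'
#' Baseline strategy: the boundary is the start of the first run of
#' `run_length` back-to-back telomere+1N hits, each beginning exactly
#' where the previous one ended.
#'
#' @inheritParams detect_vrr_start
#' @param run_length number of chained repeats required (default 8).
#' @return as [detect_vrr_start()], with `algorithm =
#'   "consecutive_repeats"`.
#' @export
detect_vrr_start_consecutive <- function(seq, motifs, run_length = 8,
                                         probe_start = NULL,
                                         include_mutant = FALSE) {
  params <- list(run_length = run_length)
  hits <- scan_motifs(seq, motifs, include_mutant = include_mutant)
  if (!is.null(probe_start))
    hits <- hits[hits$end < probe_start, , drop = FALSE]
  n <- nrow(hits)
  if (n >= run_length) {
    chained <- c(FALSE, hits$start[-1] == hits$end[-n] + 1L)
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (chained[i]) run + 1L else 0L
      if (run == run_length - 1L) {
        j <- i - run_length + 1L
        return(list(vrr_start = hits$start[j],
                    trigger_window_start = hits$start[j],
                    algorithm = "consecutive_repeats", params = params,
                    reason = NA_character_))
      }
    }
  }
  .no_call("consecutive_repeats", params,
           paste0("no run of ", run_length, " chained repeats"))
}

#' Mean absolute error of boundary calls against ground truth
#'
#' @param calls data.frame with `read_id` and called `vrr_start`.
#' @param truth data.frame with `read_id` and true `vrr_start` (the
#'   simulator's sidecar, or a manual annotation set).
#' @return list with `mae` (nucleotides, over reads where both call and
#'   truth exist), `n_called`, `n_truth`, and `errors` (signed,
#'   called - true).
#' @export
evaluate_mae <- function(calls, truth) {
  m <- merge(calls[, c("read_id", "vrr_start")],
             truth[, c("read_id", "vrr_start")],
             by = "read_id", suffixes = c("_call", "_true"))
  ok <- !is.na(m$vrr_start_call) & !is.na(m$vrr_start_true)
  err <- m$vrr_start_call[ok] - m$vrr_start_true[ok]
  list(mae = if (length(err)) mean(abs(err)) else NA_real_,
       n_called = sum(ok), n_truth = sum(!is.na(m$vrr_start_true)),
       errors = err)
}
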