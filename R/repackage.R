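#' Automatic syllable segmentation from the amplitude envelope
#'
#' Stand-in for manual syllable marking: computes a smoothed RMS energy
#' envelope (10 ms window), finds runs of syllabic activity above a fraction
#' of the peak envelope, places boundaries at the envelope minima between
#' syllabic peaks, and snaps every boundary to the nearest zero crossing so
#' that later splicing introduces no artificial transients. If
#' `expected_count` is given, the partition is merged at the shallowest
#' valleys (or split at the deepest internal valleys) until that many
#' syllables remain.
#'
#' @param signal an `audio_signal`.
#' @param expected_count known syllable count, or `NULL` (unknown).
#' @param window_ms RMS smoothing window in ms (default 10).
#' @param threshold activity threshold as a fraction of the peak envelope
#'   (default 0.05).
#' @return a `syllable_segmentation`.
#' @export
segment_syllables <- function(signal, expected_count = NULL,
                              window_ms = 10, threshold = 0.05) {
  assert_audio(signal)
  x <- signal$samples
  fs <- signal$sample_rate
  if (!length(x)) stop("empty signal")
  w <- max(3L, round(window_ms / 1000 * fs))
  env <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  peak <- max(env)
  if (peak < 1e-6 || (stats::sd(env) / peak) < 0.05)
    stop("unsegmentable input: no detectable syllabic structure in the envelope")

  active <- env > threshold * peak
  r <- rle(active)
  ends_r <- cumsum(r$lengths)
  starts_r <- ends_r - r$lengths + 1L
  runs <- data.frame(start = starts_r[r$values], end = ends_r[r$values])
  # discard spurious blips shorter than 15 ms
  runs <- runs[(runs$end - runs$start + 1L) >= round(0.015 * fs), , drop = FALSE]
  if (nrow(runs) == 0L)
    stop("unsegmentable input: no syllabic activity above threshold")
  coverage <- sum(runs$end - runs$start + 1L) / length(x)
  if (is.null(expected_count) && nrow(runs) == 1L && coverage > 0.95)
    stop("unsegmentable input: envelope is active throughout (no syllabic ",
         "structure)")

  if (!is.null(expected_count)) {
    # merge adjacent runs across the shallowest valleys until count matches
    while (nrow(runs) > expected_count) {
      valleys <- vapply(seq_len(nrow(runs) - 1L), function(i) {
        min(env[runs$end[i]:runs$start[i + 1L]])
      }, numeric(1))
      i <- which.max(valleys)           # shallowest valley merged first
      runs$end[i] <- runs$end[i + 1L]
      runs <- runs[-(i + 1L), , drop = FALSE]
    }
    while (nrow(runs) < expected_count) {
      len <- runs$end - runs$start
      i <- which.max(len)
      seg_env <- env[runs$start[i]:runs$end[i]]
      inner <- seq(round(length(seg_env) * 0.2), round(length(seg_env) * 0.8))
      if (length(inner) < 2L) stop("cannot split runs to reach expected_count")
      cut <- runs$start[i] + inner[which.min(seg_env[inner])] - 1L
      runs <- rbind(runs[seq_len(i - 1L), , drop = FALSE],
                    data.frame(start = runs$start[i], end = cut),
                    data.frame(start = cut + 1L, end = runs$end[i]),
                    runs[-seq_len(i), , drop = FALSE][-1L, , drop = FALSE])
      runs <- runs[order(runs$start), , drop = FALSE]
    }
  }
  starts <- vapply(runs$start, function(i) snap_to_zero_crossing(x, i, fs),
                   numeric(1))
  ends <- vapply(pmin(runs$end + 1L, length(x)),
                 function(i) snap_to_zero_crossing(x, i, fs), numeric(1))
  syllable_segmentation(starts - 1L, ends - 1L + 1L, n_samples = length(x))
}

# Nearest sample (1-based) to `i` with |amplitude| below the snap tolerance
# within +/- 5 ms; if none, the nearest sign-change sample; else `i` itself.
snap_to_zero_crossing <- function(x, i, fs, tol = 1e-4, radius_ms = 5) {
  n <- length(x)
  i <- min(max(i, 1L), n)
  r <- round(radius_ms / 1000 * fs)
  lo <- max(1L, i - r); hi <- min(n, i + r)
  win <- x[lo:hi]
  small <- which(abs(win) < tol)
  if (length(small)) {
    return(lo + small[which.min(abs(small + lo - 1L - i))] - 1L)
  }
  sgn <- sign(win)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips)) {
    cand <- flips + ifelse(abs(win[flips]) <= abs(win[flips + 1L]), 0L, 1L)
    return(lo + cand[which.min(abs(cand + lo - 1L - i))] - 1L)
  }
  i
}

#' Insert fixed silences after each syllable ("repackaging")
#'
#' Extracts the syllable intervals, appends `round(silence * sample_rate)`
#' zero-valued samples after each, and concatenates them in the original
#' order. Material between intervals is dropped. Restores the syllabic
#' rhythm of time-compressed speech without changing the speech segments
#' themselves.
#'
#' @param signal an `audio_signal`.
#' @param seg a `syllable_segmentation` valid for `signal`.
#' @param silence silence duration in seconds (>= 0) appended per syllable;
#'   the study value is 0.1 s.
#' @return a list with `audio` (the repackaged `audio_signal`, length exactly
#'   `sum(interval lengths) + n_syllables * round(silence * fs)`) and
#'   `segmentation` (updated syllable intervals in the output).
#' @examples
#' x <- audio_signal(rep(c(rep(0.3, 200), rep(0, 100)), 3), 16000)
#' seg <- syllable_segmentation(c(0, 300, 600), c(200, 500, 800))
#' out <- insert_silences(x, seg, 0.01)
#' length(out$audio$samples)
#' @export
insert_silences <- function(signal, seg, silence = 0.1) {
  assert_audio(signal)
  seg <- assert_segmentation(seg, n_samples = length(signal$samples))
  if (silence < 0) stop("`silence` must be >= 0 seconds")
  fs <- signal$sample_rate
  gap_n <- round(silence * fs)
  pieces <- vector("list", nrow(seg))
  starts <- integer(nrow(seg)); ends <- integer(nrow(seg))
  pos <- 0L
  for (i in seq_len(nrow(seg))) {
    syl <- signal$samples[(seg$start[i] + 1L):seg$end[i]]
    pieces[[i]] <- c(syl, numeric(gap_n))
    starts[i] <- pos
    ends[i] <- pos + length(syl)
    pos <- pos + length(syl) + gap_n
  }
  audio <- audio_signal(unlist(pieces, use.names = FALSE), fs)
  list(audio = audio,
       segmentation = syllable_segmentation(starts, ends,
                                            n_samples = length(audio$samples)))
}

#' Extend syllable intervals so they tile the signal
#'
#' Manual syllable segmentation of connected speech assigns every sample to
#' some syllable: consecutive syllables abut and nothing is discarded. This
#' helper converts a segmentation that marks only the voiced cores (as the
#' synthetic generator's ground truth does) into that tiling form, extending
#' each interval to the start of the next and the first/last intervals to
#' the signal edges. With a tiling segmentation, inserting `silence` seconds
#' per syllable changes the syllabic rate exactly as
#' [repackaged_rate()] predicts.
#'
#' @param seg a `syllable_segmentation`.
#' @param n_samples signal length in samples.
#' @return a `syllable_segmentation` whose intervals partition
#'   `[0, n_samples)`.
#' @export
tile_segmentation <- function(seg, n_samples) {
  seg <- assert_segmentation(seg, n_samples = n_samples)
  if (nrow(seg) == 0L) return(seg)
  starts <- seg$start
  ends <- seg$end
  starts[1] <- 0L
  if (nrow(seg) > 1L) {
    mid <- as.integer(round((ends[-nrow(seg)] + starts[-1]) / 2))
    starts[-1] <- mid
    ends[-nrow(seg)] <- mid
  }
  ends[nrow(seg)] <- n_samples
  syllable_segmentation(starts, ends, n_samples = n_samples)
}

#' Syllabic rate after inserting silences
#'
#' Closed-form bookkeeping: if speech runs at `rate_in` sps, appending
#' `silence` seconds after each syllable stretches each syllabic period from
#' `1/rate_in` to `1/rate_in + silence`, giving `1 / (1/rate_in + silence)`
#' sps. With the study values (15.6 sps, 0.1 s) this is 6.09... ~ 6.1 sps.
#'
#' @param rate_in input syllabic rate in sps (> 0).
#' @param silence inserted silence per syllable in seconds (>= 0).
#' @return the repackaged syllabic rate in sps.
#' @examples
#' repackaged_rate(15.6, 0.1)
#' @export
repackaged_rate <- function(rate_in, silence = 0.1) {
  if (any(rate_in <= 0)) stop("`rate_in` must be positive")
  if (any(silence < 0)) stop("`silence` must be >= 0")
  1 / (1 / rate_in + silence)
}
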