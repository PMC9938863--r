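#' Validate a time-compression ratio
#'
#' The compression ratio (CR) is output duration divided by input duration;
#' this toolkit handles compression only, so it must lie in (0, 1]. The two
#' study settings of interest are CR 0.4 (control, ~6.6 sps) and CR 0.166
#' (fast, ~15.6 sps).
#'
#' @param cr compression ratio scalar.
#' @return `cr`, invisibly, after validation.
#' @export
compression_ratio <- function(cr) {
  if (length(cr) != 1L || !is.finite(cr) || cr <= 0 || cr > 1)
    stop("compression ratio must be a scalar in (0, 1]")
  invisible(cr)
}

#' Uniform time compression by waveform-similarity overlap-add
#'
#' Shortens a signal to `cr` times its duration without transposing pitch or
#' formants, using a WSOLA time-scale modifier: fixed synthesis hop, Hann
#' windows, and a cross-correlation search that aligns each analysis frame
#' with the natural continuation of the previously selected frame. The
#' long-term magnitude spectrum is preserved while the modulation spectrum
#' shifts up by a factor 1/cr.
#'
#' @param signal an `audio_signal`.
#' @param cr compression ratio in (0, 1] (output/input duration).
#' @param frame_ms analysis/synthesis frame length in ms (default 25).
#' @param search_ms half-width of the alignment search region in ms
#'   (default 10).
#' @return an `audio_signal` of exactly `round(length(input) * cr)` samples.
#' @examples
#' x <- audio_signal(sin(2 * pi * 200 * seq(0, 0.5, by = 1 / 16000)), 16000)
#' y <- time_compress(x, 0.4)
#' duration(y) / duration(x)
#' @export
time_compress <- function(signal, cr, frame_ms = 25, search_ms = 10) {
  assert_audio(signal)
  compression_ratio(cr)
  fs <- signal$sample_rate
  x <- signal$samples
  N <- round(frame_ms / 1000 * fs)
  if (N %% 2L == 1L) N <- N + 1L
  Hs <- N %/% 2L
  if (length(x) < 2L * N)
    stop("signal too short to time-compress (need at least two frames)")
  target_len <- round(length(x) * cr)
  search <- round(search_ms / 1000 * fs)

  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N)  # periodic Hann (COLA at 50%)
  n_frames <- max(1L, ceiling((target_len - N) / Hs) + 1L)
  # zero-pad the input so every candidate window is in range
  xp <- c(x, numeric(N + search + Hs))
  max_start <- length(x)  # candidate starts are clamped to the real signal

  out <- numeric(n_frames * Hs + N)
  wsum <- numeric(length(out))
  prev_start <- NA_integer_
  for (k in seq_len(n_frames) - 1L) {
    syn <- k * Hs + 1L
    nominal <- round(k * Hs / cr) + 1L
    nominal <- min(max(nominal, 1L), max_start)
    if (k == 0L) {
      sel <- nominal
    } else {
      template <- xp[(prev_start + Hs):(prev_start + Hs + N - 1L)]
      lo <- max(1L, nominal - search)
      hi <- min(max_start, nominal + search)
      region <- xp[lo:(hi + N - 1L)]
      sel <- lo + best_alignment(region, template)
    }
    frame <- xp[sel:(sel + N - 1L)] * win
    idx <- syn:(syn + N - 1L)
    out[idx] <- out[idx] + frame
    wsum[idx] <- wsum[idx] + win
    prev_start <- sel
  }
  out <- out / pmax(wsum, 1e-3)
  out <- out[seq_len(target_len)]
  audio_signal(pmax(-1, pmin(1, out)), fs)
}

# Offset (0-based) of the candidate window inside `region` that maximizes the
# normalized cross-correlation with `template`. FFT cross-correlation for the
# numerator, cumulative sums for the candidate energies.
best_alignment <- function(region, template) {
  N <- length(template)
  n_cand <- length(region) - N + 1L
  if (n_cand <= 1L) return(0L)
  # full linear cross-correlation (convolve with conj = TRUE correlates)
  cc <- stats::convolve(region, template, conj = TRUE, type = "open")
  num <- cc[N:(N + n_cand - 1L)]
  csum <- cumsum(c(0, region^2))
  energy <- csum[(N + 1L):(N + n_cand)] - csum[seq_len(n_cand)]
  ncc <- num / sqrt(pmax(energy, 1e-12) * max(sum(template^2), 1e-12))
  which.max(ncc) - 1L
}

#' Rescale a syllable segmentation after time compression
#'
#' Carries ground-truth syllable boundaries through uniform compression:
#' every boundary index is multiplied by `cr` and rounded, keeping the
#' intervals sorted, disjoint, and non-empty.
#'
#' @param seg a `syllable_segmentation` valid for the uncompressed signal.
#' @param cr compression ratio in (0, 1].
#' @return a `syllable_segmentation` for the compressed signal.
#' @export
scale_segmentation <- function(seg, cr) {
  seg <- assert_segmentation(seg)
  compression_ratio(cr)
  starts <- as.integer(round(seg$start * cr))
  ends <- as.integer(round(seg$end * cr))
  ends <- pmax(ends, starts + 1L)      # keep intervals non-empty after rounding
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      starts[i] <- max(starts[i], ends[i - 1L])
      ends[i] <- max(ends[i], starts[i] + 1L)
    }
  }
  syllable_segmentation(starts, ends)
}

#' Syllabic rate of a segmented utterance
#'
#' Syllable count divided by utterance duration, in syllables per second
#' (sps).
#'
#' @param seg a `syllable_segmentation`.
#' @param duration utterance duration in seconds (> 0).
#' @return rate in sps; 0 (with a warning) for an empty segmentation.
#' @examples
#' seg <- syllable_segmentation(c(0, 500), c(400, 900))
#' syllabic_rate(seg, 0.8)
#' @export
syllabic_rate <- function(seg, duration) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a positive scalar (seconds)")
  if (!is_segmentation(seg)) seg <- assert_segmentation(seg)
  n <- nrow(seg)
  if (n == 0L) {
    warning("empty segmentation: syllabic rate is 0")
    return(0)
  }
  n / duration
}
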