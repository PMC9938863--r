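#' Construct an audio signal
#'
#' The basic container all DSP stages consume and produce: a mono sampled
#' waveform with its sample rate. Samples are amplitudes nominally in
#' \[-1, 1\]; all stages keep the peak within full scale unless documented
#' otherwise.
#'
#' @param samples numeric vector of finite amplitude values.
#' @param sample_rate sampling rate in Hz (positive integer-valued scalar).
#' @return an object of class `audio_signal` (a list with elements
#'   `samples` and `sample_rate`).
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
#' duration(x)
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar (Hz)")
  if (any(!is.finite(samples)))
    stop("all samples must be finite")
  structure(list(samples = samples, sample_rate = as.integer(round(sample_rate))),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %d Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$sample_rate, duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

is_audio_signal <- function(x) inherits(x, "audio_signal")

assert_audio <- function(x, arg = "signal") {
  if (!is_audio_signal(x)) stop(sprintf("`%s` must be an audio_signal", arg))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return duration in seconds.
#' @export
duration <- function(x) {
  assert_audio(x, "x")
  length(x$samples) / x$sample_rate
}

#' Root-mean-square amplitude
#' @param x an `audio_signal` or numeric vector.
#' @return linear RMS amplitude.
#' @export
rms <- function(x) {
  v <- if (is_audio_signal(x)) x$samples else as.numeric(x)
  sqrt(mean(v^2))
}

#' Convert a linear amplitude ratio to decibels
#' @param ratio positive amplitude ratio.
#' @return `20 * log10(ratio)`.
#' @export
db <- function(ratio) 20 * log10(ratio)

#' RMS level in dB re full scale
#'
#' Full scale is an amplitude of 1.0, so a full-scale DC signal reads
#' 0 dB FS and a full-scale sine reads about -3.01 dB FS.
#'
#' @param x an `audio_signal` or numeric vector.
#' @return level in dB FS.
#' @export
dbfs <- function(x) db(rms(x))

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the formats this package writes:
#' 16-bit PCM (format code 1) and 32-bit IEEE float (format code 3),
#' single channel.
#'
#' @param path file path.
#' @return an `audio_signal`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NA_integer_; n_channels <- NA_integer_
  sample_rate <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", size)
      fmt_code <- sum(as.integer(fmt[1:2]) * c(1, 256))
      n_channels <- sum(as.integer(fmt[3:4]) * c(1, 256))
      sample_rate <- sum(as.integer(fmt[5:8]) * c(1, 256, 65536, 16777216))
      bits <- sum(as.integer(fmt[15:16]) * c(1, 256))
    } else if (identical(id, "data")) {
      if (is.na(fmt_code)) stop("malformed WAV: data before fmt chunk")
      if (fmt_code == 1L && bits == 16L) {
        raw_s <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                         endian = "little")
        samples <- raw_s / 32768
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "double", size / 4, size = 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV format: code %d, %d bits", fmt_code, bits))
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(samples) && !is.na(fmt_code)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (n_channels != 1L) stop("only mono WAV supported (got ", n_channels, " channels)")
  audio_signal(samples, sample_rate)
}

#' Write a mono WAV file
#'
#' @param x an `audio_signal`.
#' @param path output file path.
#' @param format `"pcm16"` (16-bit integer) or `"float32"` (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "float32")) {
  assert_audio(x, "x")
  format <- match.arg(format)
  n <- length(x$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt_code <- if (format == "pcm16") 1L else 3L
  bits <- if (format == "pcm16") 16L else 32L
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(x$sample_rate, con, size = 4, endian = "little")
  writeBin(as.integer(x$sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")   # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(x$samples * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

# Seed-isolated evaluation: runs `expr` under set.seed(seed) and restores the
# caller's RNG state, so package functions are deterministic per seed without
# disturbing the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
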