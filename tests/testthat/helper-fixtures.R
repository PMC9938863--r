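# Shared fixtures. All DSP tests run at 16 kHz: the lowest rate that keeps
# the 7937.5 Hz top band edge below Nyquist, an order of magnitude cheaper
# than 44.1 kHz.
FS <- 16000

tone <- function(freq, dur = 1, amp = 0.4, fs = FS) {
  audio_signal(amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 1) / fs), fs)
}

white_noise <- function(dur = 1, amp = 0.05, fs = FS, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(round(dur * fs)) * amp
  audio_signal(pmax(-1, pmin(1, x)), fs)
}

# cache moderately expensive fixtures across tests
.fixture_cache <- new.env(parent = emptyenv())

cached_sentence <- function(n_syl = 7, rate = 2.5, seed = 3) {
  key <- paste0("s", n_syl, "_", rate, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_sentence(n_syl, rate, seed = seed,
                                               sample_rate = FS)
  .fixture_cache[[key]]
}

spectral_centroid <- function(x) {
  sp <- Mod(stats::fft(x$samples))^2
  n <- length(sp)
  f <- (seq_len(n) - 1) / n * x$sample_rate
  h <- seq_len(n %/% 2)
  sum(f[h] * sp[h]) / sum(sp[h])
}
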