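#' Generate one synthetic sentence with known syllable ground truth
#'
#' Builds a corpus-like sentence as a train of syllable units. Each syllable
#' is a harmonic source (fundamental drawn from 100-140 Hz) shaped by two
#' randomly drawn formant-like resonances and a raised-cosine on/off ramp,
#' separated by low-level noise gaps about 60 dB below the syllable peak (so
#' automatic segmentation is exercised on non-trivial material, while the
#' exact boundaries are stored as ground truth). The signal is broadband and
#' envelope-structured — everything the downstream compression, repackaging,
#' and vocoding stages operate on — without being intelligible speech.
#'
#' @param n_syllables number of syllables (>= 1).
#' @param nominal_rate target syllabic rate in syllables per second.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   audio.
#' @param sample_rate sampling rate in Hz (>= 16000, to keep the 7937.5 Hz
#'   vocoder band edge below Nyquist).
#' @param n_keywords number of keyword tokens to attach to the sentence.
#' @return a `synthetic_sentence`: list with `audio` (an `audio_signal`),
#'   `syllables` (a `syllable_segmentation` of the voiced portions),
#'   `keywords` (character tokens), and `nominal_rate`.
#' @examples
#' s <- generate_sentence(9, 2.5, seed = 1, sample_rate = 16000)
#' duration(s$audio)
#' n_syllables(s$syllables)
#' @export
generate_sentence <- function(n_syllables, nominal_rate = 2.5, seed = 1,
                              sample_rate = 44100, n_keywords = 3) {
  if (n_syllables < 1) stop("`n_syllables` must be >= 1")
  if (nominal_rate <= 0) stop("`nominal_rate` must be positive (sps)")
  if (sample_rate < 16000) stop("`sample_rate` must be >= 16000 Hz")
  fs <- sample_rate
  period_s <- 1 / nominal_rate                # one syllable + its gap
  gap_frac <- 0.25
  syl_s <- period_s * (1 - gap_frac)
  # a syllable must hold at least 4 pitch periods of the lowest fundamental
  if (syl_s < 4 / 100)
    stop("infeasible synthesis: syllables shorter than 4 pitch periods ",
         "at this rate/sample-rate combination")
  n_per <- round(period_s * fs)
  n_syl <- round(syl_s * fs)
  n_gap <- n_per - n_syl

  with_seed(seed, {
    total <- n_per * n_syllables
    x <- numeric(total)
    starts <- integer(n_syllables)
    ends <- integer(n_syllables)
    for (i in seq_len(n_syllables)) {
      s0 <- (i - 1L) * n_per
      syl <- synth_syllable(n_syl, fs)
      x[(s0 + 1L):(s0 + n_syl)] <- syl
      starts[i] <- s0
      ends[i] <- s0 + n_syl
    }
    peak <- max(abs(x))
    x <- x / peak * 0.5                        # headroom for later stages
    # gaps: low-level noise ~60 dB below syllable peak, never digital zero
    gap_level <- 0.5 * 10^(-60 / 20)
    in_gap <- rep(TRUE, total)
    for (i in seq_len(n_syllables)) in_gap[(starts[i] + 1L):ends[i]] <- FALSE
    x[in_gap] <- stats::rnorm(sum(in_gap)) * gap_level / 3

    kw <- sprintf("kw%02d_s%d", seq_len(max(0L, n_keywords)), seed %% 10000L)
    structure(list(audio = audio_signal(x, fs),
                   syllables = syllable_segmentation(starts, ends,
                                                     n_samples = total),
                   keywords = kw,
                   nominal_rate = nominal_rate),
              class = "synthetic_sentence")
  })
}

# One voiced syllable: harmonic complex shaped by two formant resonances
# with -6 dB/oct source tilt plus an aspiration-like high-frequency plateau
# (~-30 dB re the formant peak, keeping the long-term tilt speech-like),
# raised-cosine attack/decay ramps.
synth_syllable <- function(n, fs) {
  f0 <- stats::runif(1, 100, 140)
  f1 <- stats::runif(1, 300, 800)
  f2 <- stats::runif(1, 1000, 2500)
  bw1 <- 90; bw2 <- 120
  t <- (seq_len(n) - 1) / fs
  n_harm <- floor((fs / 2 - 100) / f0)
  k <- seq_len(n_harm)
  fk <- k * f0
  lorentz <- function(f, fc, bw) 1 / sqrt(1 + ((f - fc) / bw)^2)
  amp <- (1 / k) * (lorentz(fk, f1, bw1) + lorentz(fk, f2, bw2) + 0.05) + 0.03
  phase <- stats::runif(n_harm, 0, 2 * pi)
  syl <- as.numeric(cos(outer(t, 2 * pi * fk) +
                          matrix(phase, n, n_harm, byrow = TRUE)) %*% amp)
  ramp_n <- min(round(0.025 * fs), floor(n / 3))
  env <- rep(1, n)
  if (ramp_n > 0) {
    r <- sin(pi / 2 * seq_len(ramp_n) / ramp_n)^2
    env[seq_len(ramp_n)] <- r
    env[(n - ramp_n + 1L):n] <- rev(r)
  }
  syl * env
}

#' Draw a sentence length from the corpus syllable-count distribution
#'
#' Discretized normal with mean 9 and SD 2.2, truncated to the corpus range
#' 4-15 syllables per sentence.
#'
#' @param n number of draws.
#' @return integer vector of syllable counts.
#' @export
draw_n_syllables <- function(n = 1) {
  out <- integer(0)
  while (length(out) < n) {
    cand <- round(stats::rnorm(n, mean = 9, sd = 2.2))
    out <- c(out, cand[cand >= 4 & cand <= 15])
  }
  out[seq_len(n)]
}

#' Generate a list of synthetic sentences with a keyword budget
#'
#' Emulates the structure of a sentence-test list: `n_sentences` sentences
#' whose keyword counts sum exactly to `keyword_target` (the corpus uses
#' lists of 10 sentences carrying 32 or 33 keywords), each sentence carrying
#' at least one keyword.
#'
#' @param n_sentences number of sentences (>= 1).
#' @param keyword_target total keywords across the list (>= `n_sentences`).
#' @param seed integer seed.
#' @param nominal_rate syllabic rate in sps for every sentence.
#' @param sample_rate sampling rate in Hz.
#' @return a list of `synthetic_sentence` objects; the per-sentence keyword
#'   vectors sum to `keyword_target` tokens.
#' @export
generate_list <- function(n_sentences = 10, keyword_target = 33, seed = 1,
                          nominal_rate = 2.5, sample_rate = 44100) {
  if (n_sentences < 1) stop("`n_sentences` must be >= 1")
  if (keyword_target < n_sentences)
    stop("`keyword_target` must be >= `n_sentences` (each sentence carries >= 1 keyword)")
  plan <- with_seed(seed, {
    counts <- draw_n_syllables(n_sentences)
    extra <- keyword_target - n_sentences
    kw <- rep(1L, n_sentences)
    if (extra > 0) {
      add <- table(factor(sample.int(n_sentences, extra, replace = TRUE),
                          levels = seq_len(n_sentences)))
      kw <- kw + as.integer(add)
    }
    list(counts = counts, kw = kw, seeds = sample.int(.Machine$integer.max %/% 2,
                                                      n_sentences))
  })
  lapply(seq_len(n_sentences), function(i) {
    generate_sentence(plan$counts[i], nominal_rate = nominal_rate,
                      seed = plan$seeds[i], sample_rate = sample_rate,
                      n_keywords = plan$kw[i])
  })
}

#' Simulated-listener psychometric model
#'
#' A logistic model of per-keyword recall probability standing in for human
#' listeners. The linear predictor is
#' `intercept + rate_slope * rate + channel_effect[spectral] +
#'  repackaging_gain[spectral] * silence_added + subject_intercept`,
#' where `rate` is the articulation rate of the (compressed) speech in sps —
#' silence insertion restores rhythm without slowing articulation, so its
#' effect enters only through `repackaging_gain`.
#'
#' The default magnitudes are calibrated to the group means of the study
#' this toolkit models: ~100% for uncompressed and mildly compressed clear
#' speech, ~42% at 15.6 sps with original spectral content, and repackaging
#' benefits that grow with available temporal fine structure
#' (8-channel < 16-channel < original).
#'
#' @param intercept baseline logit.
#' @param rate_slope logit change per sps; must be <= 0 (intelligibility is
#'   non-increasing in rate).
#' @param channel_effect named logit offsets for spectral content
#'   (`original`, `16ch`, `8ch`).
#' @param repackaging_gain named logit offsets added when silences are
#'   inserted, per spectral content.
#' @param subject_sd SD of the per-subject normal intercept (logit units).
#' @return a `psychometric_model` list.
#' @export
psychometric_model <- function(intercept = 11.0,
                               rate_slope = -0.726,
                               channel_effect = c(original = 0,
                                                  `16ch` = -0.773,
                                                  `8ch` = -2.613),
                               repackaging_gain = c(original = 0.959,
                                                    `16ch` = 0.757,
                                                    `8ch` = 0.740),
                               subject_sd = 0.35) {
  if (rate_slope > 0) stop("`rate_slope` must be <= 0")
  if (subject_sd < 0) stop("`subject_sd` must be >= 0")
  needed <- c("original", "16ch", "8ch")
  if (!all(needed %in% names(channel_effect)) ||
      !all(needed %in% names(repackaging_gain)))
    stop("channel_effect and repackaging_gain need entries for original, 16ch, 8ch")
  structure(list(intercept = intercept, rate_slope = rate_slope,
                 channel_effect = channel_effect,
                 repackaging_gain = repackaging_gain,
                 subject_sd = subject_sd),
            class = "psychometric_model")
}

#' A null listener model (all condition effects zero)
#'
#' Every condition has a 50% keyword-recall probability; useful for type-I
#' error studies of the downstream statistics.
#'
#' @param subject_sd per-subject intercept SD in logit units (default 0).
#' @return a `psychometric_model`.
#' @export
null_psychometric_model <- function(subject_sd = 0) {
  psychometric_model(intercept = 0, rate_slope = 0,
                     channel_effect = c(original = 0, `16ch` = 0, `8ch` = 0),
                     repackaging_gain = c(original = 0, `16ch` = 0, `8ch` = 0),
                     subject_sd = subject_sd)
}

# Articulation rate (sps) implied by a condition row: the TC rate set by the
# compression ratio, regardless of inserted silences.
condition_rate <- function(speech_rate) {
  unname(c(original = 2.5, `0.4` = 6.6, `0.166` = 15.6)[as.character(speech_rate)])
}

#' Predicted keyword-recall probability for conditions
#'
#' @param model a `psychometric_model`.
#' @param design data.frame of conditions with columns `speech_rate`
#'   (`"original"`, `"0.4"`, `"0.166"`), `spectral_content` (`"original"`,
#'   `"8ch"`, `"16ch"`), `silence_added` (logical).
#' @param subject_intercept optional per-row logit offset (default 0).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_psychometric <- function(model, design, subject_intercept = 0) {
  if (!inherits(model, "psychometric_model")) stop("`model` must be a psychometric_model")
  rate <- condition_rate(design$speech_rate)
  if (any(is.na(rate))) stop("unknown speech_rate level in design")
  eta <- model$intercept + model$rate_slope * rate +
    model$channel_effect[as.character(design$spectral_content)] +
    model$repackaging_gain[as.character(design$spectral_content)] *
      as.numeric(design$silence_added) +
    subject_intercept
  unname(stats::plogis(eta))
}

#' Simulate listener keyword scores for a design
#'
#' Draws one normal intercept per subject and, per condition row, a
#' binomial count of correctly recalled keywords with the probability given
#' by the psychometric model. Keywords are independent Bernoulli trials
#' given the condition probability.
#'
#' @param model a `psychometric_model`.
#' @param design data.frame of condition rows (see
#'   [predict_psychometric()]); a `measurement` column is carried through if
#'   present, otherwise `"test"` is filled in.
#' @param n_subjects number of simulated listeners (>= 2).
#' @param keywords_per_condition keywords scored per subject and condition
#'   row (>= 1).
#' @param seed integer seed.
#' @return a long-format score table (data.frame) with columns `subject`,
#'   `speech_rate`, `spectral_content`, `silence_added`, `measurement`,
#'   `n_keywords`, `n_correct`, `percent`, `rau`.
#' @export
simulate_responses <- function(model, design, n_subjects = 14,
                               keywords_per_condition = 33, seed = 1) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  if (keywords_per_condition < 1) stop("`keywords_per_condition` must be >= 1")
  if (is.null(design$measurement)) design$measurement <- "test"
  n_cond <- nrow(design)
  with_seed(seed, {
    subj_int <- stats::rnorm(n_subjects, 0, model$subject_sd)
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      p <- predict_psychometric(model, design, subject_intercept = subj_int[s])
      n_correct <- stats::rbinom(n_cond, keywords_per_condition, p)
      rows[[s]] <- data.frame(subject = sprintf("S%02d", s),
                              speech_rate = design$speech_rate,
                              spectral_content = design$spectral_content,
                              silence_added = design$silence_added,
                              measurement = design$measurement,
                              n_keywords = keywords_per_condition,
                              n_correct = n_correct)
    }
    add_score_columns(do.call(rbind, rows))
  })
}

#' The 2 x 3 x 2 main-experiment design
#'
#' Silence (no/yes) by spectral content (8ch/16ch/original) by measurement
#' (test/retest), all at compression ratio 0.166 — the within-subject design
#' of the main analysis.
#'
#' @return a data.frame of 12 condition rows.
#' @export
main_experiment_design <- function() {
  d <- expand.grid(silence_added = c(FALSE, TRUE),
                   spectral_content = c("8ch", "16ch", "original"),
                   measurement = c("test", "retest"),
                   stringsAsFactors = FALSE)
  d$speech_rate <- "0.166"
  d[, c("speech_rate", "spectral_content", "silence_added", "measurement")]
}
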