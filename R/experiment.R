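#' The experimental condition matrix
#'
#' The eight unique conditions of the design — original speech; CR 0.4
#' control; and the six CR 0.166 cells crossing spectral content (8-channel,
#' 16-channel, original) with silence insertion (no/yes) — plus retest
#' duplicates of every time-compressed condition (the six CR 0.166 cells and
#' the CR 0.4 control), giving 15 assessments in total. Vocoding and silences combine
#' only with CR 0.166; the original-rate condition is assessed once.
#'
#' @return data.frame of 15 assessment rows with columns `speech_rate`,
#'   `spectral_content`, `silence_added`, `measurement`, and `condition_id`;
#'   the attribute `"unique_conditions"` holds the 8-row unique matrix.
#' @export
build_condition_matrix <- function() {
  base <- data.frame(
    speech_rate = c("original", "0.4", rep("0.166", 6)),
    spectral_content = c("original", "original",
                         "8ch", "16ch", "original",
                         "8ch", "16ch", "original"),
    silence_added = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  retested <- base$speech_rate != "original"   # all TC conditions get a retest
  test <- base
  test$measurement <- "test"
  retest <- base[retested, ]
  retest$measurement <- "retest"
  out <- rbind(test, retest)
  out$condition_id <- paste0("cr", gsub("^original$", "orig", out$speech_rate),
                             "_", out$spectral_content, "_",
                             ifelse(out$silence_added, "sil", "nosil"),
                             "_", out$measurement)
  rownames(out) <- NULL
  attr(out, "unique_conditions") <- base
  out
}

#' Assign corpus lists, presentation orders, and test ears to participants
#'
#' Per participant: one unique list per assessment (no list is heard twice
#' by the same listener), an independent pseudo-random presentation order
#' within the test block and within the retest block, and an ear assignment
#' balanced across the cohort (half left, half right). Deterministic for a
#' fixed seed.
#'
#' @param n_participants cohort size.
#' @param list_pool vector of available list identifiers; needs at least as
#'   many entries as there are assessments.
#' @param seed integer seed.
#' @return a list of per-participant assignments, each with `participant`,
#'   `lists` (named by `condition_id`), `order_test`, `order_retest`
#'   (condition ids in presentation order), and `ear`.
#' @export
assign_lists <- function(n_participants, list_pool, seed = 1) {
  conditions <- build_condition_matrix()
  n_assess <- nrow(conditions)
  if (length(unique(list_pool)) < n_assess)
    stop("list pool too small: need at least ", n_assess, " unique lists")
  test_ids <- conditions$condition_id[conditions$measurement == "test"]
  retest_ids <- conditions$condition_id[conditions$measurement == "retest"]
  with_seed(seed, {
    n_left <- floor(n_participants / 2)
    ears <- sample(c(rep("left", n_left),
                     rep("right", n_participants - n_left)))
    lapply(seq_len(n_participants), function(i) {
      lists <- sample(list_pool, n_assess)
      names(lists) <- conditions$condition_id
      list(participant = sprintf("P%02d", i),
           lists = lists,
           order_test = sample(test_ids),
           order_retest = sample(retest_ids),
           ear = ears[i])
    })
  })
}

# A-weighting magnitude response (IEC 61672 analog curve), normalized to
# unity gain at 1 kHz.
a_weight_gain <- function(f) {
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  ra(f) / ra(1000)
}

#' A-weighted RMS level in dB re full scale
#'
#' Computed in the frequency domain: the signal's power spectrum is weighted
#' by the squared A-weighting magnitude curve and integrated. A 1 kHz sine
#' reads the same level weighted and unweighted.
#'
#' @param signal an `audio_signal`.
#' @return A-weighted level in dB FS.
#' @export
a_weighted_level <- function(signal) {
  assert_audio(signal)
  x <- signal$samples
  n <- length(x)
  spec <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * signal$sample_rate
  freqs <- pmin(freqs, signal$sample_rate - freqs)  # two-sided -> |f|
  w <- a_weight_gain(freqs)
  w[freqs == 0] <- 0
  power <- sum((Mod(spec) * w)^2) / n^2
  db(sqrt(power))
}

#' Scale a signal to a target A-weighted presentation level
#'
#' Free-field SPL has no meaning inside a file, so presentation level is
#' mapped to a digital reference: the default of -25 dB FS A-weighted RMS
#' stands in for the 65 dB SPL used at the loudspeaker, preserving relative
#' levels across conditions.
#'
#' @param signal a non-silent `audio_signal`.
#' @param target_dbfs target A-weighted RMS in dB re full scale.
#' @return the scaled `audio_signal`, with the linear gain recorded in
#'   attribute `"gain"`. Warns if scaling pushes the peak above full scale.
#' @export
set_level <- function(signal, target_dbfs = -25) {
  assert_audio(signal)
  if (all(signal$samples == 0)) stop("cannot set the level of silence")
  current <- a_weighted_level(signal)
  gain <- 10^((target_dbfs - current) / 20)
  out <- audio_signal_unclamped(signal$samples * gain, signal$sample_rate)
  if (max(abs(out$samples)) > 1)
    warning("target level drives the peak above full scale")
  attr(out, "gain") <- gain
  out
}

# internal: like audio_signal() but tolerates peaks slightly above 1
audio_signal_unclamped <- function(samples, sample_rate) {
  s <- audio_signal(pmax(-1e6, pmin(1e6, samples)), sample_rate)
  s$samples <- samples
  s
}

#' Render all stimuli for an assigned cohort
#'
#' Composes the pipeline per participant and assessment: uniform time
#' compression (tempo), optional silence insertion using the ground-truth
#' segmentation carried through compression (repackage), optional noise
#' vocoding, and presentation-level scaling — writing one WAV per sentence
#' and a manifest CSV.
#'
#' @param corpus named list of sentence lists (as from [generate_list()]);
#'   names are the list identifiers referenced by the assignments.
#' @param assignments output of [assign_lists()] built from a pool of
#'   `names(corpus)`.
#' @param out_dir output directory (created if needed).
#' @param silence inserted silence in seconds for repackaged conditions
#'   (default 0.1).
#' @param target_dbfs presentation level in A-weighted dB FS (default -25).
#' @param carrier_seed base seed for vocoder noise carriers.
#' @return the manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`): participant, condition fields,
#'   list id, file, realized syllabic rate in sps, applied level.
#' @export
render_all <- function(corpus, assignments, out_dir, silence = 0.1,
                       target_dbfs = -25, carrier_seed = 1) {
  if (is.null(names(corpus)) || any(!nzchar(names(corpus))))
    stop("`corpus` must be a named list of sentence lists")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- build_condition_matrix()
  cr_map <- c(original = 1, `0.4` = 0.4, `0.166` = 0.166)
  rows <- list()
  for (a in assignments) {
    for (j in seq_len(nrow(conditions))) {
      cond <- conditions[j, ]
      list_id <- a$lists[[cond$condition_id]]
      sentences <- corpus[[as.character(list_id)]]
      if (is.null(sentences))
        stop("assignment references list '", list_id, "' absent from corpus")
      cr <- unname(cr_map[cond$speech_rate])
      rates <- numeric(length(sentences))
      rendered <- vector("list", length(sentences))
      for (si in seq_along(sentences)) {
        sent <- sentences[[si]]
        sig <- sent$audio
        seg <- sent$syllables
        if (cr < 1) {
          sig <- time_compress(sig, cr)
          seg <- scale_segmentation(seg, cr)
          seg <- syllable_segmentation(seg$start,
                                       pmin(seg$end, length(sig$samples)))
        }
        if (cond$silence_added) {
          # manual-style segmentation: syllables abut, nothing is dropped
          rep_out <- insert_silences(sig, tile_segmentation(seg, length(sig$samples)),
                                     silence)
          sig <- rep_out$audio
          seg <- rep_out$segmentation
        }
        if (cond$spectral_content != "original") {
          spec <- vocoder_preset(sub("ch$", "", cond$spectral_content),
                                 carrier_seed = carrier_seed + 131L * j + si)
          sig <- vocode(sig, spec)
        }
        sig <- set_level(sig, target_dbfs)
        rates[si] <- syllabic_rate(seg, duration(sig))
        rendered[[si]] <- sig
      }
      stim <- audio_signal(unlist(lapply(rendered, `[[`, "samples")),
                           rendered[[1]]$sample_rate)
      fname <- sprintf("%s_%s_list%s.wav", a$participant, cond$condition_id,
                       list_id)
      write_wav(stim, file.path(out_dir, fname), format = "float32")
      rows[[length(rows) + 1L]] <-
        data.frame(participant = a$participant,
                   condition_id = cond$condition_id,
                   speech_rate = cond$speech_rate,
                   spectral_content = cond$spectral_content,
                   silence_added = cond$silence_added,
                   measurement = cond$measurement,
                   list = as.character(list_id),
                   file = fname,
                   realized_rate_sps = mean(rates),
                   level_dbfs = target_dbfs,
                   ear = a$ear)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
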