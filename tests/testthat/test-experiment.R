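test_that("condition matrix has 8 unique conditions and 15 assessments", {
  cm <- build_condition_matrix()
  uniq <- attr(cm, "unique_conditions")
  expect_equal(nrow(uniq), 8)
  expect_equal(nrow(cm), 15)
  # exactly one original-rate, original-spectrum condition
  expect_equal(sum(uniq$speech_rate == "original" &
                     uniq$spectral_content == "original"), 1)
  # vocoding and silences only combine with CR 0.166
  expect_false(any(uniq$spectral_content != "original" &
                     uniq$speech_rate != "0.166"))
  expect_false(any(uniq$silence_added & uniq$speech_rate != "0.166"))
  # every time-compressed condition is retested, the original is not
  expect_equal(sum(cm$measurement == "retest"), 7)
  expect_false(any(cm$measurement == "retest" & cm$speech_rate == "original"))
  expect_equal(anyDuplicated(cm$condition_id), 0)
})

test_that("list assignment is injective, balanced, and seed-deterministic", {
  pool <- paste0("L", 1:15)
  asg <- assign_lists(14, pool, seed = 5)
  expect_length(asg, 14)
  for (a in asg) {
    expect_equal(anyDuplicated(a$lists), 0)       # unique list per assessment
    expect_setequal(a$order_test,
                    build_condition_matrix()$condition_id[
                      build_condition_matrix()$measurement == "test"])
  }
  ears <- vapply(asg, `[[`, character(1), "ear")
  expect_equal(sum(ears == "left"), 7)

  asg2 <- assign_lists(14, pool, seed = 5)
  expect_identical(asg, asg2)
  asg3 <- assign_lists(14, pool, seed = 6)
  expect_false(identical(asg, asg3))
  expect_error(assign_lists(4, paste0("L", 1:10)), "pool too small")
})

test_that("assignment determinism holds across many seeds", {
  pool <- paste0("L", 1:20)
  for (seed in sample.int(1e6, 25)) {
    a1 <- assign_lists(6, pool, seed = seed)
    a2 <- assign_lists(6, pool, seed = seed)
    expect_identical(a1, a2)
    for (a in a1) expect_equal(anyDuplicated(a$lists), 0)
  }
})

test_that("level scaling hits the A-weighted target and is scale-invariant", {
  x <- white_noise(dur = 1, amp = 0.05, seed = 9)
  y <- set_level(x, -25)
  expect_equal(a_weighted_level(y), -25, tolerance = 1e-6)
  expect_equal(attr(set_level(y, -25), "gain"), 1, tolerance = 1e-6)

  x2 <- audio_signal(x$samples * 2, x$sample_rate)
  y2 <- set_level(x2, -25)
  expect_equal(y2$samples, y$samples, tolerance = 1e-9)
  expect_error(set_level(audio_signal(numeric(100), FS), -25), "silence")
})

test_that("A-weighting matches the standard curve", {
  # 1 kHz sine: weighted level equals the unweighted level (0 dB weight)
  s1k <- tone(1000, dur = 1, amp = 0.2)
  expect_equal(a_weighted_level(s1k), dbfs(s1k), tolerance = 0.05)
  # 100 Hz sine: the standard curve gives about -19.1 dB
  s100 <- tone(100, dur = 2, amp = 0.2)
  expect_equal(a_weighted_level(s100) - dbfs(s100), -19.1, tolerance = 0.3)
  # white noise: oracle = direct integration of the curve over a flat spectrum
  wn <- white_noise(dur = 2, amp = 0.05, seed = 10)
  f <- seq(1, FS / 2, by = 1)
  w2 <- (12194^2 * f^4 /
           ((f^2 + 20.6^2) * sqrt((f^2 + 107.7^2) * (f^2 + 737.9^2)) *
              (f^2 + 12194^2)))^2
  w2 <- w2 / (12194^2 * 1000^4 /
                ((1000^2 + 20.6^2) * sqrt((1000^2 + 107.7^2) *
                                            (1000^2 + 737.9^2)) *
                   (1000^2 + 12194^2)))^2
  expected_offset <- 10 * log10(mean(w2))
  expect_equal(a_weighted_level(wn) - dbfs(wn), expected_offset,
               tolerance = 0.3)
})

test_that("render_all writes a consistent, reproducible manifest", {
  # desk-scale corpus: 15 one-sentence lists of 5 syllables each
  corpus <- lapply(1:15, function(i) {
    s <- generate_sentence(5, 2.5, seed = 600 + i, sample_rate = FS,
                           n_keywords = 3)
    list(s)
  })
  names(corpus) <- paste0("L", 1:15)
  asg <- assign_lists(2, names(corpus), seed = 3)
  out_dir <- withr::local_tempdir()
  man <- render_all(corpus, asg, out_dir)
  expect_equal(nrow(man), 2 * 15)
  expect_true(all(file.exists(file.path(out_dir, man$file))))

  fast <- man[man$speech_rate == "0.166" & !man$silence_added, ]
  expect_true(all(abs(fast$realized_rate_sps - 15.6) / 15.6 < 0.1))
  slow <- man[man$speech_rate == "0.166" & man$silence_added, ]
  expect_true(all(abs(slow$realized_rate_sps - 6.1) / 6.1 < 0.1))

  man2 <- render_all(corpus, asg, withr::local_tempdir())
  expect_equal(man$realized_rate_sps, man2$realized_rate_sps)

  # vocoding after repackaging keeps the inserted silences silent
  v_row <- man[man$silence_added & man$spectral_content == "8ch", ][1, ]
  sig <- read_wav(file.path(out_dir, v_row$file))
  # gap level in the rendered file: at least 40 dB below the syllable level
  env <- sqrt(stats::filter(sig$samples^2, rep(1 / 160, 160), sides = 2))
  env <- env[!is.na(env)]
  expect_lt(db(stats::quantile(env, 0.1) / max(env)), -40)
})
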