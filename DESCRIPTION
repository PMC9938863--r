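Package: tcrepack
Title: Time-Compressed Speech, Syllabic Repackaging, Noise Vocoding, and
    Intelligibility Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and analyse psychoacoustic experiments on
    time-compressed (TC) speech. Provides a synthetic sentence generator
    with known syllable boundaries, waveform-similarity overlap-add
    (WSOLA) uniform time compression, syllable segmentation and
    rhythm-restoring silence insertion ("repackaging"), multi-channel
    noise vocoding with Butterworth filter banks, a simulated-listener
    psychometric model, and the statistics used to analyse keyword
    intelligibility scores: the rationalized arcsine unit (RAU)
    transform, Welch t-tests, repeated-measures ANOVA with Mauchly
    sphericity testing, Greenhouse-Geisser correction and generalized
    eta-squared, Bonferroni-corrected pairwise post-hocs, and
    repackaging-benefit contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
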