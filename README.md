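# tcrepack

Stimulus generation and analysis for psychoacoustic experiments on
**time-compressed (TC) speech**: uniform time compression, syllabic
**repackaging** (re-inserting silences to restore speech rhythm),
multi-channel **noise vocoding** (controlled degradation of temporal fine
structure), and the **intelligibility statistics** used to analyse keyword
scores. A synthetic sentence generator with exact syllable ground truth and
a simulated listener replace the copyrighted speech corpus and the human
cohort, so the whole chain runs reproducibly at desk scale.

It is written for hearing scientists and psychoacousticians who want to
build, check, or re-analyse this family of experiments without PRAAT/MATLAB
tooling or access to the original corpus.

## What it computes

**Rates.** Speech at syllabic rate *r* (syllables per second, sps),
compressed by ratio CR, runs at *r*/CR. Appending *s* seconds of silence
per syllable gives

    rate_repackaged = 1 / (1/rate + s)

so a 15.6 sps stream repackaged with 100 ms silences runs at 6.09 ≈ 6.1 sps.

**Vocoder.** n contiguous 4th-order Butterworth band-pass channels between
printed edges (187.5–7937.5 Hz; 8 or 16 bands), envelopes by half-wave
rectification + 200 Hz low-pass, seeded noise carriers band-filtered,
modulated, re-filtered, matched per channel to the original in-band RMS,
and summed.

**Scores.** Percent keywords correct; rationalized arcsine units
RAU = (146/π)·[asin√(X/(N+1)) + asin√((X+1)/(N+1))] − 23; Welch t;
repeated-measures ANOVA with Mauchly sphericity tests, Greenhouse–Geisser
correction and generalized eta-squared; Bonferroni paired post-hocs; and
the per-subject repackaging benefit (silence − no-silence).

## Worked example

```r
library(tcrepack)

# a 9-syllable synthetic sentence at the corpus rate
s <- generate_sentence(n_syllables = 9, nominal_rate = 2.59, seed = 1,
                       sample_rate = 16000)

# compress to CR 0.166, carry the ground-truth segmentation along
fast <- time_compress(s$audio, 0.166)
seg  <- scale_segmentation(s$syllables, 0.166)
seg  <- syllable_segmentation(seg$start, pmin(seg$end, length(fast$samples)))
syllabic_rate(seg, duration(fast))            # 15.6 sps

# repackage: tile the segmentation (syllables abut), insert 100 ms silences
rep <- insert_silences(fast, tile_segmentation(seg, length(fast$samples)), 0.1)
syllabic_rate(rep$segmentation, duration(rep$audio))   # 6.1 sps

# vocode and check level conservation
voc <- vocode(rep$audio, vocoder_preset(8, carrier_seed = 2))

# simulate a 14-listener cohort on the 2x3x2 design and analyse it
tab <- simulate_responses(psychometric_model(), main_experiment_design(),
                          n_subjects = 14, keywords_per_condition = 33, seed = 1)
res <- rm_anova(tab)          # ANOVA on percent correct
ben <- repackaging_benefit(tab)
round(tapply(ben$benefit_percent, ben$spectral_content, mean), 2)
```

This prints a fast rate of `15.6` sps, a repackaged rate of `6.1` sps, and
for seed 1 the ANOVA gives (excerpt)

```
                         effect     F df_num df_den        p    ges
                  silence_added 438.5      1     13 2.13e-11 0.3373
               spectral_content 393.3      2     26 3.68e-20 0.8230
 silence_added:spectral_content  14.1      2     26 7.12e-05 0.0977
```

with mean repackaging benefits of `4.76` (8-channel), `15.15` (16-channel)
and `18.83` (original spectrum) percentage points — both main effects and
the benefit's growth with available fine structure, as in the paradigm this
models.

A command-line front end for the same pipeline ships at
`system.file("cli", "tcrepack", package = "tcrepack")` with subcommands
`synth`, `compress`, `repackage`, `vocode`, `level`, `simulate`, `analyze`.

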