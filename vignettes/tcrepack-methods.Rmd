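---
title: "Time-compressed speech, repackaging, and noise vocoding: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-compressed speech, repackaging, and noise vocoding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrepack)
```

## The problem this package models

When speech is uniformly time-compressed (TC), intelligibility collapses
once the syllabic rate passes roughly 11–16 syllables per second (sps).
Part of that collapse is rhythmic: re-inserting short silences between the
syllables of TC speech — *repackaging* — restores the original syllabic
rhythm without slowing the speech segments themselves, and recovers a
substantial share of intelligibility. How much it recovers depends on the
temporal fine structure (TFS) available to the listener, which noise
vocoding degrades in a controlled way.

`tcrepack` implements the full stimulus-generation and analysis chain of
this paradigm at desk scale: a synthetic sentence generator with exact
syllable ground truth, a WSOLA time-scale modifier, an envelope-based
syllable segmenter and silence inserter, an 8/16-channel noise vocoder,
a simulated listener, and the intelligibility statistics (RAU transform,
repeated-measures ANOVA with sphericity handling, Bonferroni post-hocs,
benefit contrasts).

## Synthetic speech instead of a copyrighted corpus

The reference corpus (35 lists of 10 Dutch sentences, 32–33 keywords per
list, mean 9 syllables per sentence, SD 2.2, range 4–15, roughly 2.5 sps)
is not redistributable, and no listener data are deposited. The generator
therefore emulates its *structure*, not its language:

* a sentence is a train of syllable units at a nominal rate (default
  2.5 sps); syllable counts are drawn from a discretized normal
  (mean 9, SD 2.2, truncated to 4–15);
* each syllable is a harmonic complex (fundamental drawn from 100–140 Hz)
  shaped by two formant-like resonances, a −6 dB/oct source tilt and an
  aspiration-like high-frequency plateau about 30 dB below the formant
  peak, with raised-cosine onset/offset ramps (25 ms). The plateau keeps
  the long-term spectrum falling gently across the vocoder span, as real
  speech does; a purely harmonic source would leave the top filter-bank
  channels ~50 dB down, where any contiguous filter bank's leakage
  dominates the level measurements;
* inter-syllable gaps sit at −60 dB relative to the syllable peak (never
  digital zero), so the automatic segmenter is exercised on non-trivial
  material while the exact boundaries are stored as ground truth;
* lists carry a keyword budget (default 32–33) partitioned randomly across
  sentences with at least one keyword each.

Everything is deterministic given a seed. What the generator does *not*
emulate: phonology, coarticulation, lexical redundancy, talker variability.
Passing tests on this material shows the *signal-processing and statistical
contracts* hold; it says nothing about intelligibility of real Dutch
sentences to real listeners.

## Time compression

The original production chain used pitch-synchronous overlap-add (PSOLA)
inside PRAAT. PSOLA's pitch marking is underdetermined from the outside, so
`time_compress()` implements a waveform-similarity overlap-add (WSOLA)
modifier instead: 25 ms Hann-windowed frames, 50% synthesis hop, and a
±10 ms search that maximizes the normalized cross-correlation between each
candidate frame and the natural continuation of the previously selected
frame. Both algorithms satisfy the contract that matters here: duration
scales by the compression ratio CR (output trimmed to exactly
`round(n × CR)` samples), the long-term magnitude spectrum is preserved
(no pitch or formant transposition; spectral centroid within ±5% on
harmonic fixtures), energy is preserved within 3 dB, and the modulation
spectrum shifts up by 1/CR. The two study settings are CR 0.4 (control,
≈6.6 sps) and CR 0.166 (fast, ≈15.6 sps).

The printed corpus rates are treated as empirical values, not arithmetic
identities: the corpus is "approximately 2.5 sps" while 15.6 sps is the
measured rate at CR 0.166 (implying ≈2.59 sps); pipeline cross-checks
therefore synthesize at 2.59 sps where the 15.6 → 6.1 sps arithmetic is
being reproduced.

## Segmentation and repackaging

`segment_syllables()` stands in for manual syllable marking: a 10 ms RMS
envelope, activity runs above 5% of the peak envelope, merging or splitting
at the shallowest/deepest valleys when the expected count is known, and
snapping every boundary to the nearest zero crossing (|amplitude| < 10⁻⁴
within ±5 ms, else the nearest sign change) so splices create no
transients. Ground-truth segmentations can always be used instead, so
repackaging never depends on the detector.

`insert_silences()` appends exactly `round(silence × fs)` zero samples per
syllable and concatenates in order; output length is exact by construction.
Material between intervals is dropped — with manual-style segmentation
there is none, and `tile_segmentation()` converts a voiced-cores-only
segmentation into that tiling form (boundaries at inter-syllable valley
midpoints). On tiled input the measured post-insertion rate equals the
closed form `1 / (1/rate + silence)`: 15.6 sps with 100 ms of silence gives
6.09 ≈ 6.1 sps.

## Noise vocoder

The analysis bank uses the printed band edges exactly (9 edges for
8 channels, 17 for 16, spanning 187.5–7937.5 Hz). Each channel is a causal
4th-order Butterworth band-pass between consecutive edges; envelopes are
half-wave rectification followed by a causal 4th-order 200 Hz Butterworth
low-pass; carriers are independent seeded white-noise streams passed
through the same band filters; each modulated channel is rescaled to the
original band's RMS and the channels are summed. Causal forward filtering
(no zero-phase double pass) mirrors real-time vocoder practice.

Two implementation choices deserve justification:

* **Band-pass rather than cascaded high-pass + low-pass.** A cascade of
  4th-order HP and LP has shallow skirts relative to the narrow 16-channel
  bands (−12 dB one bandwidth beyond the 187.5–312.5 Hz band); summing
  independent noise channels then inflates every re-analyzed band by
  ~1.5 dB. The band-pass transformation is numerically stable at 16 and
  44.1 kHz and keeps adjacent channels separated, which is what a
  contiguous "analytical filter bank" requires.
* **Re-filtering after modulation.** Envelope modulation spreads each
  channel's noise ±200 Hz beyond its band. The modulated noise is passed
  through the channel filter once more before level matching, so the RMS
  match is genuinely an in-band match. With both choices, per-band levels
  of the vocoded output match the input within 0.5 dB on speech-like
  fixtures for both presets.

The envelope cutoff stays uniformly at 200 Hz, including for 16-channel
bands narrower than 200 Hz. Normalization is per-channel only; the summed
output is peak-limited (with the factor recorded) rather than re-scaled to
the input RMS, because a global re-scale would shift every band by a common
offset whenever the input has energy outside the filter-bank span.
An overall input-RMS match is available as an option.

**Measuring envelope fidelity.** `envelope_fidelity()` correlates
re-extracted envelopes after smoothing both to the modulation band that
carries syllabic and phonemic information (default 16 Hz), allowing a small
lag for the synthesis path's extra group delay. Raw 200-Hz-wide envelopes
of a noise vocoder necessarily carry carrier-intrinsic fluctuations whose
relative size grows as bands narrow; per-channel correlations in 125-Hz
bands are bounded near 0.85 by that physics regardless of implementation
quality, so the filter-bank-level summary is the mean across channels
(≥ 0.9 for both presets on generated sentences, every channel > 0.7).
`fine_structure_correlation()` confirms TFS destruction: input and output
within-band carriers correlate near zero (|r| < 0.1).

## The experiment layer

`build_condition_matrix()` returns the eight unique conditions — original
speech, the CR 0.4 control, and the six CR 0.166 cells crossing spectral
content (8ch/16ch/original) with silence insertion — plus retest duplicates
of all seven time-compressed conditions (15 assessments; the original-rate
condition is assessed once). `assign_lists()` gives each participant one
unique list per assessment, independent pseudo-random block orders (plain
seeded permutations; the original's pseudo-randomization constraints are
unspecified), and a cohort-balanced ear assignment.

Free-field presentation level has no meaning in a file; 65 dB SPL is mapped
to a configurable digital reference, by default −25 dB FS A-weighted RMS
(`set_level()`, IEC A-weighting curve evaluated in the frequency domain).
Relative levels across conditions — all the computation needs — are
preserved. `render_all()` composes compress → repackage → vocode → level
per assessment (vocoding after silence insertion; silences are zeros either
way under a level-matched vocoder) and writes WAVs plus a manifest.

## The simulated listener

`psychometric_model()` is a logistic per-keyword recall model:

> logit p = intercept + rate_slope·rate + channel_effect[spectral] +
> repackaging_gain[spectral]·silence + subject intercept,

with keywords as independent Bernoulli trials given p (no within-sentence
correlation structure is published) and subject intercepts ~N(0, σ²).
The `rate` covariate is the articulation rate of the compressed speech
(2.5 / 6.6 / 15.6 sps for original / CR 0.4 / CR 0.166): silence insertion
restores rhythm without slowing articulation, so its effect enters only
through `repackaging_gain`. A single logit linear in the *realized* rate
cannot simultaneously produce ~100% at 6.6 sps and ~65% for repackaged
speech at 6.1 sps — the paradigm's central observation is precisely that
repackaged 6.1 sps speech is much harder than natural-rate 6.6 sps speech.

Default magnitudes (intercept 11.0, slope −0.726 logit/sps, channel
offsets 0/−0.773/−2.613, repackaging gains 0.959/0.757/0.740 for
original/16ch/8ch, subject SD 0.35) were calibrated once to the published
group means: ≈100% for both control conditions, ≈42% at 15.6 sps with
original TFS, ≈5/25/42% without and ≈10/41/65% with silences for
8ch/16ch/original, i.e. repackaging benefits of roughly 5/16/23 percentage
points growing with available TFS. Only group means are matched: no claim
is made about individual-difference structure beyond the single subject
intercept.

## Statistics

* **RAU.** `rau()` implements the rationalized arcsine transform
  θ = asin√(X/(N+1)) + asin√((X+1)/(N+1)), RAU = (146/π)θ − 23 (the
  source study cites the transform without printing the formula). It is
  defined at both endpoints (−15.0 at 0/33, 115.0 at 33/33), strictly
  increasing, and near-linear against percent between ~20% and ~80%.
* **Group comparison.** `welch_t()` is the unpaired unequal-variance t
  with Satterthwaite df — the printed df of ~28.8 exceeds n−1 = 13, which
  identifies the test as Welch on per-list observations pooled over test
  and retest. A paired alternative is available through
  `posthoc_pairwise()`.
* **rm-ANOVA.** `rm_anova()` handles complete balanced within-subject
  designs by orthonormal-contrast projection, giving per-effect F, df, p,
  Mauchly's W, Greenhouse–Geisser ε (applied to df and p when Mauchly's
  p < 0.05), and generalized eta-squared (effect SS over effect SS plus
  subject and all error SS). It is validated against `stats::aov` error
  strata, a hand-written sums-of-squares decomposition, the classic
  double-centering ε formula, and `stats::mauchly.test` — all matching to
  numerical precision. Two-level factors have ε = 1 by construction. Note
  that "corrected p ≥ uncorrected p" holds whenever F ≥ 1; for F < 1 the
  inequality can mathematically reverse, a property of the F distribution,
  irrelevant to inference. The ANOVA is run on percent correct and the
  post-hocs on RAU, as in the modeled analysis.
* **Benefit.** `repackaging_benefit()` is the silence minus no-silence
  contrast per subject and spectral content, averaged over test and retest,
  in percentage points and RAU.

## Numerical choices and degenerate inputs

* WSOLA: 25 ms frames, 50% hop, ±10 ms search; inputs shorter than two
  frames are rejected; CR outside (0, 1] is rejected (compression only).
* Segmentation: activity threshold 5% of peak envelope, runs under 15 ms
  discarded; pure silence and structureless (flat-envelope) inputs raise
  errors; segmentations are validated (sorted, disjoint, non-empty, within
  signal) at every interface.
* Vocoder: a top cutoff at or above Nyquist is rejected (sample rates must
  be ≥ 16 kHz for the printed presets); silent inputs vocode to silence.
* RAU/scores: `n_correct` outside [0, n_keywords] is rejected; Bonferroni
  p-values are capped at 1; constant input to the normality check and
  all-constant Welch groups raise errors rather than returning NaN.
* Unbalanced or incomplete ANOVA tables raise a structural error — no
  imputation.

## Problem sizes

Tests and the acceptance script run at 16 kHz (the lowest rate that keeps
the 7937.5 Hz band edge below Nyquist) with sentences of 4–9 syllables;
the Monte-Carlo studies use 500 null cohorts (type-I error) and 200
effect-pattern cohorts of 14 subjects × 12 cells × 33 keywords, sizes at
which the binomial Monte-Carlo error on a rejection rate is about ±2
percentage points. The default 44.1 kHz path is exercised once. All
randomness flows through explicit seeds; identical parameters and seed
give bit-identical output.

## Known limitations

* Synthetic sentences are not speech; intelligibility simulation is a
  calibrated logistic stand-in, not an auditory model.
* WSOLA is not PSOLA; only contract-level equivalence is claimed.
* Per-channel envelope fidelity in narrow bands is limited by noise-carrier
  statistics (see above), as it is for any noise vocoder.
* The t-test's pooling of test/retest lists is an interpretation consistent
  with the printed degrees of freedom; per-list observations are the
  default and pooling is the caller's choice.
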