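---
title: "Frequency tagging of prosodic and syntactic tracking: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency tagging of prosodic and syntactic tracking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The paradigm

Listeners hear trials of twelve four-word sentences built from 320-ms
monosyllabic words concatenated without pauses. Everything in the design
follows from the word duration: words recur at 3.125 Hz, sentences at
0.78125 Hz, and — when the four words split into two two-word phrases
("2 + 2" syntax) — phrases at the half-sentence rate of 1.5625 Hz. In a
"1 + 3" structure the phrase boundary after the first word is not
isochronous, so no acoustic or syntactic event recurs at 1.5625 Hz.
Prosody is manipulated on top of this grid: stimuli are either
prosodically neutralized (implicit prosody, `ImplP`), carry an overt
sinusoidal intensity/pitch contour at 1.5625 Hz with maxima on words 2
and 4 (`OvP`, the "W24" contour), or are acoustically neutral while the
listener imagines the W24 contour (`InstrP`).

Neural tracking of any of these levels appears as a spectral peak at the
corresponding frequency in the *evoked* EEG spectrum — the spectrum of
the across-trial average, which retains only activity phase-locked to
trial onset. The package implements this analysis end to end, and a
synthetic-data generator that produces recordings with exactly the
statistical structure the analysis assumes, so that every stage can be
verified quantitatively without access to any real recordings.

## Stimulus envelopes

`render_trial_envelope()` models each word as a unit-amplitude pulse
with raised-cosine onset/offset ramps (default 10 ms), identical for all
words. Any identical-across-words shape gives the same spectral logic:
the flat envelope is exactly periodic at the word rate, so its spectrum
lives on multiples of 3.125 Hz and vanishes at 0.78125 and 1.5625 Hz —
the acoustic signal carries no sentence or phrase cue. The W24 contour
multiplies this envelope by `1 + m cos(2*pi*1.5625*(t - 0.48))`, whose
maxima fall at the midpoints of words 2 and 4 (0.48 s and 1.12 s within
each 1.28-s sentence) — the unique phase consistent with maxima "on
words 2 and 4". The peak-to-trough depth is a free parameter (the source
experiment does not quantify it); the default is 6 dB, so
`m = (10^(6/20) - 1) / (10^(6/20) + 1) ~ 0.33`.

Two departures from an idealized pulse train are deliberate:

* **Per-word intensity jitter.** Natural spoken words differ in
  loudness. A lognormal gain per word (sd 0.05, seeded from the design)
  puts a broadband floor under the single-trial spectra; without it the
  envelope spectrum is a line spectrum and the neighbor-bin SNR of a
  deterministic signal would be 0/0. Set `word_gain_jitter_sd = 0` to
  recover the exactly periodic case (used by the purity tests).
* **Pitch as metadata.** The analysis consumes intensity envelopes only;
  the pitch excursion is recorded in the contour object but never
  rendered, matching the role of the acoustic panels in the analysis.

## The synthetic EEG model

`simulate_recording()` writes, per trial and channel,

```
x(t) = sum_c A_c * w_c(channel) * cos(2*pi*f_c*(t - t_onset)) + noise(t)
```

a sum of pure sinusoids at the tagged frequencies plus `1/f^alpha`
noise. A pure sinusoid is the simplest generator of a single-bin evoked
peak; a convolved response kernel would add harmonics the analysis does
not need. Phases are fixed relative to trial onset and identical across
trials, which is what "evoked" means operationally: components flagged
`fixed_phase = FALSE` get a fresh random phase per trial and must vanish
from the evoked spectrum as `1/n` — a property the tests verify, and the
reason the analysis uses the FFT of the ERP rather than single-trial
power.

Choices and their rationale:

* **Effect table.** Absolute amplitudes are unconstrained (the empirical
  spectra are in scaled arbitrary units); only orderings matter. The
  defaults encode the qualitative findings: prosody-syntax alignment
  boosts and misalignment suppresses the constituent-rate responses,
  instructed prosody acts like a smaller overt prosody, and the
  half-sentence response under 1 + 3 implicit prosody exceeds its 2 + 2
  counterpart despite the absence of any 1.5625-Hz stimulus cue (the
  covert-prosody effect). Topographies: sentence-rate responses are
  centro-posterior; half-sentence responses posterior for 2 + 2 but
  broad/frontal for 1 + 3.
* **Noise.** `alpha = 1`, scale 5 uV per channel. With 22 trials
  averaged, this puts the default component SNRs in the single-digit to
  low-double-digit range (roughly 2-15 at the sentence and phrase
  rates), the regime of the empirical spectra.
* **Participant variability.** Neither the source experiment nor the
  spec fixes between-subject variance, but group-level bootstrap tests
  and cross-condition correlations require it. Each participant draws
  lognormal gains (sd 0.25) per component; the half-sentence gain is
  drawn *independently* for the two syntax types, modeling the claim
  that the 2 + 2 phrase-rate response (syntactic/prosodic alignment) and
  the 1 + 3 response (covert prosody) are distinct processes — which
  makes the two half-sentence peaks uncorrelated across participants
  while the sentence peaks stay correlated.
* **Artifacts.** Square pulses of +/-500 uV for 200 ms in a random
  channel of a random fraction of trials — large enough to trip the
  +/-400 uV rule, short enough to leave the rest of the trial usable.
* **What is not modeled.** No volume conduction or forward model, no
  ocular sources (hence no ICA on synthetic data), no trial-to-trial
  amplitude drift, no channel bridging. A green end-to-end test
  therefore establishes that the *analysis* recovers what the generator
  put in — not that the generator reproduces raw human EEG.

## Preprocessing

The chain is re-reference to linked mastoids, resample 500 to 250 Hz,
then low-pass (20 Hz, order 152) and high-pass (0.2 Hz, order 2266)
windowed-sinc FIR filters with Kaiser windows (beta = 5.65326), orders
interpreted at the 250-Hz rate. Filters are applied in a single
delay-compensated pass: a symmetric (linear-phase, type I) FIR applied
once and shifted by half its order is exactly a zero-phase filter, so
the implementation multiplies the spectrum by the kernel's real
amplitude response, fused with the rate conversion in one
frequency-domain step (padded to a 5-smooth length generously beyond
the kernel span, so the convolution is linear, not circular).
Zero-phase filtering keeps evoked components phase-aligned across
trials, which the evoked-power statistic depends on.

Epochs of 14.08 s (3520 samples, eleven sentences) start 1.28 s (one
sentence) after each trial onset, skipping the trial-initial transient,
and are demeaned per channel. Two rejection rule sets:

* the three dummy-epoch amplitude rules used only to prepare ICA
  (+/-400 uV absolute; deviation from the electrode's pooled mean by
  more than 2 pooled SDs; deviation from the all-electrode pooled mean
  by more than 6 pooled SDs), read literally as per-sample tests against
  statistics pooled over the whole epoch set;
* the final spectral rule: an epoch is removed when its power at any
  channel and any 0-4 Hz bin exceeds the mean power of the *remaining*
  epochs by more than 40 dB. The reference is leave-one-out because an
  include-self mean saturates: a single dominating epoch inflates the
  mean it is compared against, capping the ratio at the epoch count, so
  the rule could never fire. The leave-one-out reading reproduces the
  intended arithmetic (a 10^5-fold outlier is 50 dB above the others and
  is removed). With very few epochs (2-3) the single-epoch reference is
  itself noisy; the pipeline uses it with >= 22 epochs.

ICA unmixing itself is delegated: the module exposes the strongly
high-pass-filtered copy (1 Hz, order 454) and the dummy-epoch rules, and
no ICA is applied to synthetic data.

## Evoked power, SNR, and the peak measure

`evoked_power()` averages epochs per channel and transforms the average
with no taper: all targets are exact multiples of the 1/14.08-Hz grid
(bins 11, 22, 44), so the rectangular window is leakage-free at the
bins of interest and tapering would only smear the single-bin peaks
into their noise neighborhoods. Power is `|X_k|^2 / N^2`; Parseval
consistency is tested to 1e-9.

`snr_normalize()` divides each bin by the mean power of its 14
neighbors (7 bins of 0.071 Hz on each side, 0.5 Hz per side), which
flattens the `1/f` floor: a noise-only bin has SNR near 1 and the
measure is invariant to overall scale. One numerical choice deviates
from a symmetric edge rule: near DC the neighborhood is completed by
*mirroring* (bin `-j` carries the same power as bin `+j` for any real
signal), because otherwise the sentence-rate target (bin 11) would have
an undefined noise estimate — its lower neighbors sit within 7 bins of
DC. Only the Nyquist edge remains undefined.

The dependent measure is the peak-minus-noise statistic
`D = SNR(target) - mean(SNR of the 14 neighbors)`, zero for a
spectrally flat input. `D` subtracts neighbor *SNR* (not raw power),
consistent with "normalized power minus the noise at the surrounding
bins". Per-participant spectra come from that participant's own trial
average; group curves average participant SNR spectra (the averaging
order is configurable in principle but participant-level SNR averaging
is the default and the tested path).

## Inference

`bca_bootstrap_test()` resamples participants — the unit that yields
"one average per participant" — with replacement, statistic = mean of
the per-participant `D`. Bias correction `z0` is the normal quantile of
the fraction of bootstrap means below the observed mean; acceleration
`a` is the jackknife skewness. The two-sided p-value inverts the CI on
a grid of levels (resolution 1e-4, implemented as a binary search over
the monotone exclusion boundary), floored at `1/n_boot`; everything is
deterministic given the seed. Degenerate input (all values equal) gets
a zero-width interval and a floor (or, at exactly zero, p = 1).
Bonferroni correction multiplies by the family size — in the pipeline,
the number of condition-by-target tests actually run. The type-I error
of the whole construction is verified by simulation (2000 null
datasets, n = 26, 2000 resamples, 5% +/- 1.5%).

`dprime()` uses the log-linear correction `(x + 0.5)/(n + 1)` on both
rates — the correction scheme is not documented in the source analysis;
log-linear was chosen because it is unconditionally defined and
symmetric. Pearson peak correlations report `r`, `r^2` and the
t-distribution p, with zero-variance input flagged rather than
propagated as numeric garbage.

## The pipeline and its acceptance experiment

`run_pipeline()` crosses 26 participants with the six condition cells,
simulates the implicit-prosody condition twice (early/late) and pools
the two runs' epochs before averaging — mirroring the averaging of the
two real runs — then produces peak tables, bootstrap tests with
Bonferroni correction, ROI means on the 3 x 3 anteriority-by-laterality
grid, cross-condition correlations, and behavioral d-prime. Seeding is
hierarchical: every design, recording, behavioral draw, and bootstrap
derives its own child seed from the master seed via a multiplicative
mixing function, so reports regenerate exactly.

Two scale decisions keep the default run inside a desk-scale budget and
are deliberate parts of the stated world rather than tunings: the EEG
stream simulates the 22 outlier-free analysis trials (trials containing
a semantic outlier never enter the spectral analysis; they exist in the
30-trial behavioral stream), and inter-trial gaps are omitted (trial
blocks are contiguous between zero-padded flanks; nothing is analyzed
between trials).

The end-to-end acceptance experiment asserts the full sign pattern on
the default cohort: all twelve cell-by-target peaks above noise and
significant after correction; half-sentence `D` for 2 + 2 ordered
overt > instructed > implicit > 0; a significant half-sentence peak for
1 + 3 implicit prosody (the covert-prosody signature) exceeding its
2 + 2 counterpart; sentence-rate suppression under misaligned overt and
instructed prosody for 1 + 3; and a more posterior half-sentence
topography for 2 + 2 than for 1 + 3.

## Known limitations

* The generator's amplitudes are stipulated, not fitted; only orderings
  and ratios are meaningful, so the package cannot (and does not try
  to) reproduce the empirical effect sizes or model betas.
* The EDF writer/reader covers plain 16-bit EDF with uniform sampling
  and a JSON sidecar for events; EDF+ annotations are out of scope.
* The dummy-epoch SD rules, read literally, reject almost everything on
  heavy-tailed data pooled over long recordings; they are faithful to
  their wording and used only for ICA preparation, not in the default
  synthetic pipeline.
* The Gamma mixed-model analysis of condition effects is intentionally
  not implemented; the pipeline exports tidy per-participant tables for
  external mixed-model tooling.
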