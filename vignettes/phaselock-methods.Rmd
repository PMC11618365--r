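---
title: "Simulating the auditory periphery with an adjustable phase-locking limit"
author: "phaselock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the auditory periphery with an adjustable phase-locking limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaselock)
```

## The scientific problem

Auditory nerve fibers fire at preferred phases of low-frequency sounds
("phase locking"), conveying temporal fine structure to the brain up to a
limit of a few kilohertz set by the low-pass character of the inner hair
cell (IHC) membrane. How much of hearing depends on this temporal code is a
long-standing question, because the phase-locking limit cannot be altered
experimentally in a living ear. In a model it can: `phaselock` implements a
simplified cochlear front-end in which the IHC low-pass cutoff is an
explicit parameter, together with the psychoacoustic stimulus manipulations
(tone vocoding, inharmonic jitter, modulated and spectrum-matched noise,
imposed interaural differences) and the analysis machinery (psychometric
fits, criterion thresholds, perceptual cue weights, human-model similarity
statistics) needed to exercise a battery of classic experiments end-to-end
at desk scale.

The intended user is a hearing researcher who wants to ask "what does this
task look like through a periphery that cannot phase lock above X Hz?"
without training large networks: the package supplies simple, fully
documented reference observers (rate-place, spike-timing, binaural
cross-correlation) in place of task-optimized networks. Their purpose is to
propagate the peripheral manipulation through to behavior-like judgments,
not to reproduce network- or human-level performance numbers.

## The periphery model

The front-end is a linear-filterbank periphery:

1. **Gammatone filterbank.** FIR approximations (impulse responses
   truncated to 50 ms) of 4th-order gammatone filters with bandwidth
   1.019 ERB(CF), one per characteristic frequency. The default CF axis
   has 50 CFs spaced uniformly on the ERB-number scale,
   `E(f) = 21.4 log10(0.00437 f + 1)`, endpoints inclusive, over
   125–8000 Hz (a 125–16000 Hz axis suits localization-style analyses).
   Channel gain at CF is normalized to 1.
2. **IHC stage (the phase-locking knob).** Each subband is half-wave
   rectified and convolved with an FIR approximation of 7 cascaded
   identical first-order low-pass sections with per-section cutoff `fc`
   (the experimental values are 3000, 1000, 320 and 50 Hz). The impulse
   response is truncated at 50 ms and Hanning-windowed (the decaying half
   of the window, so the causal onset is untouched), then normalized to DC
   gain 1. Note the composite −3 dB point lies well below `fc`: seven
   cascaded sections attenuate by about 21 dB at `fc` itself. The
   manipulation is defined by `fc`, not by the composite −3 dB point.
3. **Downsampling.** The rectified, low-passed subbands are anti-alias
   filtered (129-tap windowed-sinc low-pass at 0.45 of the output rate —
   needed because the 3000 Hz condition has non-negligible energy near the
   output Nyquist) and decimated to 10 kHz. The audio rate must be an
   integer multiple of the output rate; tiny negative filter-ringing
   excursions are clamped to zero before the sigmoids.
4. **Rate-level sigmoids.** Three pointwise sigmoids map instantaneous
   subband amplitude to firing rates of high-, medium- and
   low-spontaneous-rate fibers: rates span 0–250 spikes/s over dynamic
   ranges of 20, 40 and 80 dB with thresholds of 0, 12 and 28 dB SPL. The
   parametric form is a design choice (the published description names
   only thresholds and ranges): we use a logistic in instantaneous level,
   `L = 20 log10(max(a, 1e-9)/20e-6)` dB SPL, centered at
   threshold + range/2, with slope set so the rate spans 5%–95% of the
   maximum across `[threshold, threshold + range]`. One consequence is
   that "rate at threshold + range" is 237.5 spikes/s exactly, and input
   silence maps to a floor far below 5% of the maximum.
5. **Spike sampling.** Counts per time-frequency-fiber bin are
   Binomial(n, p) with `p = rate / 10000` and
   `n = fraction × 32000 / n_CF` (60/25/15% across the three fiber
   types, so n = 384/160/96 at 50 CFs). For speed a Gaussian
   approximation, `round(Normal(np, np(1−p)))` clipped to `[0, n]`, is
   used; an optional variant simulates individual fibers as Bernoulli
   processes with a 1 ms dead time after each spike.

### Which rates carry the phase-locking signal

At a 60 dB SPL probe level the high-spontaneous-rate sigmoid (20 dB
dynamic range) is saturated: its rate sits at the ceiling for almost the
whole stimulus cycle and the temporal modulation is flattened. The
low-spontaneous-rate fiber, with its 80 dB range, tracks the within-cycle
amplitude excursions. Vector-strength analyses in the package therefore
read the low-spontaneous-rate channel, which is also the physiologically
standard expectation (fibers with wide dynamic ranges preserve modulation
at conversational levels).

```{r rolloff}
cfg <- periphery_config(ihc_cutoff = 3000)
w <- apply_ramp(synth_tone(500, 0.15, 20000, 60), "hanning", 0.01)
r <- periphery_response(w, cfg)
ch <- which.min(abs(cfg$cf_axis - 500))
vector_strength(r$rates[ch, , 3], 500, r$fs_out)
```

### Validation logic

Two properties operationalize the claim that the cutoff degrades timing
without disturbing place information. First, the vector strength of the
on-CF rate response to a 60 dB tone falls with tone frequency above the
cutoff (exceeding 0.5 at 500 Hz under the 3000 Hz cutoff; below 0.05 at
2 kHz under the 50 Hz cutoff). The vector-strength implementation itself is
validated against analytic values: a half-wave-rectified sinusoid gives
π/4 and `1 + cos` gives 0.5. Second, time-averaged rate-vs-CF excitation
patterns for 0.5/1/2/4 kHz tones correlate above 0.95 across all four
cutoffs: "place" cues are preserved.

### The refractory comparison

Refractoriness is omitted from the default sampler on the grounds that
summation across fibers minimizes its effect. The package checks this by
comparing the across-fiber summed spike train of the default sampler
against the per-fiber dead-time sampler, binned at 2 ms. The binning
deserves a note: at the raw 0.1 ms resolution the correlation between
*any* two independently sampled spike arrays is capped near 0.9 by per-bin
binomial sampling noise (r² = var(np)/(var(np) + np(1−p)) per bin), so a
comparison at that scale measures sampling noise, not the samplers.
Two-millisecond bins sit just above the 1 ms dead time, so the statistic
measures rate fidelity at the timescale where refractoriness could act;
there the two samplers correlate above 0.99, with the dead-time variant
losing roughly 10% of spikes overall.

## Stimulus machinery

**Calibration.** Samples are sound pressure in pascal and levels are
dB SPL re 20 µPa RMS throughout; no digital full-scale convention is
needed. A tone synthesized at L dB SPL has RMS `20e-6 × 10^(L/20)` Pa
within 0.01 dB. "Cosine phase" means every component is a cosine with zero
initial phase. The noiseless condition of a signal-to-noise grid is the
sentinel `snr = Inf`, and `mix_at_snr` never touches the target samples;
mismatched lengths are a hard error unless cropping is requested
explicitly, because silent data corruption is worse than an error.

**Tone vocoding.** A 32-channel gammatone filterbank whose 33 edges are
ERB-spaced over the analysis range (100–10000 Hz by default, where the
upper edge of channel 24 lands at 4102 Hz; 80–8000 Hz suits 20 kHz audio)
decomposes the input; channels above the cutoff channel are replaced by
their Hilbert envelope imposed on a tone carrier at the channel center,
refiltered by the same channel filter, and all channels are summed. Band
filters are applied zero-phase (forward and time-reversed), a choice the
published description leaves open; it keeps the summed analysis–synthesis
chain time-aligned, so the fully intact condition (cutoff 32) reconstructs
in-band signals with correlation above 0.95, and vocoded-channel envelopes
correlate above 0.9 with the original subband envelopes. Carrier phase
starts at 0 to keep the operation deterministic.

**Inharmonic jitter.** Components above the fundamental are shifted by
fractions of F0 drawn independently and uniformly in ±0.5, with whole
patterns rejected and resampled until all adjacent spacings are at least
30 Hz. Pattern-level rejection preserves the independent-uniform law
conditional on acceptance; at F0 = 200 Hz the constraint rejects few
patterns, so accepted jitters pass a goodness-of-fit check against the
uniform law.

**Noises.** Spectrum-matched ("speech-shaped") noise randomizes the phases
of the reference's spectrum, preserving its magnitude spectrum exactly (an
FIR-filtered white-noise route, matching only in expectation, is available
behind a flag). Modulated noise multiplies by a gain that is sinusoidal
*in decibels* — 8 Hz, 30 dB peak-to-valley by default — so the max/min
gain ratio is exact.

**Binaural cues.** Positive ITD/ILD favor the right ear (the convention is
arbitrary but used consistently and tested). Whole-waveform ITDs use
band-limited (FFT phase-shift) fractional delays split ±itd/2 across ears,
since microsecond steps are sub-sample at audio rates; fine-structure ITDs
shift only the carrier phase under a shared, undelayed envelope, as the
tone-lateralization paradigm requires. ILDs are split ±ild/2 dB to
conserve the mean binaural level. `estimate_itd` inverts the imposition by
cross-correlation with parabolic peak refinement, to well within one
sample for broadband noise over ±800 µs, and flags unstable peaks
(independent noises at the ears) as unreliable.

## Psychophysics and statistics

Psychometric functions are maximum-likelihood Normal-CDF fits (probit
regression on binomial counts); thresholds at a criterion c are
`mu + sigma × qnorm(c)`, so the 50% threshold is `mu` exactly and 70.7%
is `mu + 0.545 sigma`. Data that never support the criterion — flat at
chance, or entirely 0/1 (complete separation, where the ML scale
degenerates to 0) — yield `measurable = FALSE` rather than a number,
mirroring "unmeasurably high" thresholds above a phase-locking limit.
Experiment protocols that saturate (near-perfect observers produce step
psychometrics) fall back to linear interpolation of the criterion
crossing. No lapse parameter is fitted by default. Speech reception
thresholds use a logistic sigmoid with a free asymptote fitted by least
squares (the sigmoid family is a design choice), read at half the fitted
asymptote or at a fixed proportion; benefit-from-TFS subtracts each SRT
from the fully vocoded baseline, so the baseline benefit is 0 exactly.

Perceptual cue weights express azimuth shifts in cue units through an
azimuth-to-cue lookup (rear-hemifield responses reflected across the
coronal plane first) divided by the imposed cue amount. The bundled
`spherical_head_cue_map()` (Woodworth ITD, sine-law ILD) is a synthetic
stand-in; supply measured tables for fidelity to a particular head.

Similarity statistics follow standard practice: Pearson correlation
across condition means; RMS error after min-max normalization with
human-derived scaling only (optionally shared across grouped experiments
so null-effect experiments cannot deflate the error); percentile bootstrap
CIs of the mean with two-tailed p-values from a Gaussian fitted to a
bootstrapped null; split-half reliabilities Spearman-Brown corrected
(`2r/(1+r)`) for noise-corrected explained variance; and a permutation
test for a between-by-within interaction that recomputes the interaction
F with within-unit labels permuted (sign flips of the within-unit
difference — the exchangeable operation under the null of no within-factor
effect), with +1 smoothing so finite permutations never report p = 0.

## Reference observers and desk-scale grids

The rate-place observer compares ERB-weighted centroids of time-averaged
excitation patterns — by construction blind to spike timing, so its
thresholds are unchanged across cutoffs. The timing observer estimates
each interval's dominant periodicity from the Fourier magnitude of the
summed population spike train (peak must exceed 4× the in-band median;
otherwise it falls back on the rate-place rule). The binaural observer
pools per-CF interaural cross-correlograms of summed spike trains over
±1 ms and reports the refined best lag. The package's central qualitative
property is an ordering: the timing observer's advantage over rate-place,
and the measurability of fine-structure ITD thresholds, are non-increasing
as the cutoff drops from 3000 to 50 Hz, with timing ≈ rate-place at 50 Hz.

Default protocol grids are deliberate desk-scale reductions of the full
published sweeps (which are training-scale): ITD lateralization uses five
frequencies (250–3500 Hz) and 40 µs ITD steps over ±160 µs with a few
spike-sampling repeats per stimulus, rather than 1 µs × 50 Hz grids;
frequency discrimination evaluates seven interval magnitudes over
10⁻⁴–10⁻¹ octaves with ~10 trials each, rather than 5×10⁻⁷–5×10⁻¹ with
thousands. Test and acceptance runs use 0.1–0.15 s tones. These sizes keep
every protocol in seconds-to-minutes on one CPU; finer grids sharpen the
thresholds but do not change the orderings, which is what the reference
observers are for.

## What the synthetic conditions do and do not show

All inputs are synthesized (tones, harmonic complexes, Gaussian noises);
word recognition on real speech, HRTF/BRIR spatialization and trained
networks are out of scope. Passing tests therefore demonstrate that the
peripheral manipulation, the stimulus transformations and the analysis
chain behave as specified — not that any observer reproduces human or
network performance on natural stimuli. The SRT harness, in particular, is
validated closed-loop: a synthetic accuracy generator with a built-in 5 dB
benefit must be recovered within 0.3 dB through the full
fit-and-subtract-baseline chain.

## Numerical notes and limitations

- Gammatone and IHC FIRs are truncated at 50 ms; for the 50 Hz cutoff the
  IHC impulse response still carries ~2% of its peak at the truncation
  point, which the Hanning taper absorbs.
- The Gaussian spike approximation is accurate for the default n (96–384
  per bin) but clips at 0, biasing variance slightly downward (< 1% at
  typical rates); moments match Binomial(n, p) within 2% over 10⁵ draws.
- `fit_psychometric` relies on `glm` convergence; extreme data are caught
  by the degeneracy checks rather than by inspecting warnings.
- Ties in lateralization judgments are broken at random under a recorded
  seed; identical estimates therefore produce 50% rightward in the long
  run.
- The CF axis places endpoints exactly at the stated range limits; the
  vocoder centers sit at ERB-number midpoints between edges. These two
  conventions differ (centers vs edges) and are deliberately kept
  separate.
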