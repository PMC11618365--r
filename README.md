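# phaselock

A desk-scale simulator of the auditory periphery in which the upper
frequency limit of auditory nerve **phase locking** — the inner-hair-cell
(IHC) low-pass cutoff — is an explicit, adjustable parameter, together
with the psychoacoustic stimulus manipulations and analysis statistics
needed to run a battery of classic hearing experiments end-to-end.

It is written for computational auditory neuroscientists and
psychoacousticians who want to ask: *what does a task look like through a
periphery that cannot phase lock above X Hz?* The periphery is a
simplified cochlear model — gammatone filterbank, half-wave rectification,
a 7th-order IHC low-pass at a configurable cutoff (3000 / 1000 / 320 /
50 Hz are the canonical conditions), downsampling to 10 kHz, fiber-type
rate-level sigmoids (high/medium/low spontaneous rate: 0–250 spikes/s over
20/40/80 dB dynamic ranges with 0/12/28 dB SPL thresholds) — followed by
binomial spike sampling of a 32,000-fiber population per ear,

```
count ~ Binomial(n, p),   p = rate / 10000,   n = fraction × 32000 / N_CF
```

approximated by `round(Normal(np, np(1−p)))` for speed, with an optional
per-fiber sampler with 1 ms refractoriness.

Around the periphery the package provides:

- **stimuli** — calibrated synthesis in pascal / dB SPL (tones, harmonic
  complexes, noises), ERB-number frequency utilities, ramps, SNR mixing,
  float WAV I/O with a JSON calibration sidecar;
- **binaural** — imposing and estimating interaural time and level
  differences (fine-structure ITDs under a shared envelope, sub-sample
  whole-waveform delays, symmetric ILDs);
- **manipulations** — tone vocoding with a cutoff channel on a 32-channel
  ERB-spaced filterbank, inharmonic jitter with a 30 Hz spacing
  constraint, spectrum-matched noise, sinusoidal dB-scale modulation
  (8 Hz, 30 dB);
- **psychophysics** — maximum-likelihood Normal-CDF psychometric fits,
  thresholds at 70.7 / 75 / 50% criteria (fit or interpolation),
  lateralization judgments, dimensionless ITD/ILD perceptual weights,
  speech reception thresholds and benefit-from-TFS;
- **similarity** — Pearson and min-max-normalized RMS human-model
  comparison, bootstrap CIs and Gaussian-null p-values, Spearman-Brown
  noise-corrected explained variance, a permutation test for
  between-by-within interactions;
- **protocols** — executable experiment protocols (ITD lateralization vs
  frequency, two-interval frequency discrimination, vocoding-SRT,
  localization grids) driven by simple reference observers (rate-place,
  spike-timing, binaural cross-correlation) that stand in for trained
  networks.

## Worked example

Run a 60 dB SPL, 500 Hz tone through the periphery at each phase-locking
cutoff and measure the synchronization (vector strength) of the on-CF
low-spontaneous-rate response:

```r
library(phaselock)

w <- apply_ramp(synth_tone(500, 0.15, 20000, level = 60), "hanning", 0.01)
ch <- which.min(abs(make_cf_axis() - 500))
for (cut in c(3000, 1000, 320, 50)) {
  cfg <- periphery_config(ihc_cutoff = cut)
  r <- periphery_response(w, cfg)
  cat(sprintf("cutoff %4d Hz: vector strength at 500 Hz = %.3f\n",
              cut, vector_strength(r$rates[ch, , 3], 500, r$fs_out)))
}
```

```
cutoff 3000 Hz: vector strength at 500 Hz = 0.557
cutoff 1000 Hz: vector strength at 500 Hz = 0.196
cutoff  320 Hz: vector strength at 500 Hz = 0.003
cutoff   50 Hz: vector strength at 500 Hz = 0.003
```

Phase locking to the 500 Hz fine structure is strong when the IHC cutoff
is above the tone frequency and collapses once the cutoff falls below it —
while the time-averaged excitation pattern across CFs stays essentially
unchanged (correlation > 0.95 across cutoffs), so place cues survive the
manipulation. Spike counts for the same response:

```r
cfg <- periphery_config(ihc_cutoff = 3000)
sp <- sample_spikes(periphery_response(w, cfg), cfg, seed = 1)
sp
#> spike_response: [50 CF x 1500 time x 3 fiber types] @ 10000 Hz, seed 1
```

The vocoder filterbank reproduces a well-known landmark — with 33 channel
edges ERB-spaced over 100–10000 Hz, the boundary between channels 24 and
25 falls at 4102 Hz:

```r
round(vocoder_filterbank()$edges[25])
#> [1] 4102
```

A thin command-line front-end over the same functions is installed at
`inst/cli/phaselock` (`phaselock tone|noise|vocode|jitter|modnoise|binaural|periphery|grids`).

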