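# Shared fixtures: a compact periphery configuration (fewer CFs, shorter
# stimuli) used where a test exercises pipeline behavior rather than the
# full published geometry.

FS_AUDIO <- 20000

small_cfg <- function(ihc_cutoff = 3000, n_cf = 20) {
  periphery_config(cf_axis = make_cf_axis(n_cf, 125, 8000),
                   ihc_cutoff = ihc_cutoff)
}

# a short calibrated tone with gentle ramps
fix_tone <- function(freq, dur = 0.1, level = 60, fs = FS_AUDIO) {
  apply_ramp(synth_tone(freq, dur, fs, level), "hanning", 0.005)
}

# frequency of the largest FFT magnitude peak
peak_freq <- function(x, fs, fmax = fs / 2) {
  n <- length(x)
  X <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sel <- f > 0 & f < fmax
  f[sel][which.max(X[sel])]
}
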