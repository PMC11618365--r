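# Gammatone FIR impulse response, order 4, bandwidth 1.019*ERB(cf),
# truncated to `dur` seconds, peak gain at cf normalized to 1.
gammatone_fir <- function(cf, fs, dur = 0.05, order = 4) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  b <- 1.019 * erb_bandwidth(cf)
  h <- t^(order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  # normalize magnitude response at cf to unity
  H <- sum(h * exp(-2i * pi * cf * t))
  h / Mod(H)
}

# Filter x with the gammatone at cf. zero_phase applies the filter forward
# and time-reversed (squared magnitude, zero group delay), which keeps the
# summed filterbank output time-aligned with the input.
gammatone_filter <- function(x, cf, fs, zero_phase = FALSE, dur = 0.05) {
  h <- gammatone_fir(cf, fs, dur)
  n <- length(x)
  if (!zero_phase) return(fft_conv(x, h)[seq_len(n)])
  g <- fft_conv(h, rev(h))        # zero-phase kernel, center at length(h)
  y <- fft_conv(x, g)
  y[seq.int(length(h), length.out = n)]
}

#' Vocoder filterbank specification
#'
#' A bank of `n_channels` gammatone band-pass filters whose 33 channel edges
#' are equally spaced on the ERB-number scale over `[f_lo, f_hi]` and whose
#' center frequencies sit at the ERB-number midpoints of each channel. With
#' the default 100-10000 Hz range the upper edge of channel 24 falls at
#' 4102 Hz.
#'
#' @param n_channels number of channels (default 32)
#' @param f_lo,f_hi frequency range in Hz (defaults 100 and 10000)
#' @return an object of class `vocoder_filterbank` with fields `edges`
#'   (n_channels + 1 Hz values), `centers` (n_channels Hz values),
#'   `n_channels`, `f_lo`, `f_hi`
#' @export
vocoder_filterbank <- function(n_channels = 32, f_lo = 100, f_hi = 10000) {
  edges <- erb_space(f_lo, f_hi, n_channels + 1L, mode = "edges")$values
  centers <- erb_space(f_lo, f_hi, n_channels, mode = "centers")$values
  structure(list(n_channels = n_channels, edges = edges, centers = centers,
                 f_lo = f_lo, f_hi = f_hi),
            class = "vocoder_filterbank")
}

#' @export
print.vocoder_filterbank <- function(x, ...) {
  cat(sprintf("vocoder_filterbank: %d channels, edges %g-%g Hz\n",
              x$n_channels, x$f_lo, x$f_hi))
  invisible(x)
}

#' Tone vocoding with a cutoff channel
#'
#' Decomposes the waveform into gammatone subbands. Channels up to and
#' including `cutoff_channel` are left intact. In channels above the cutoff
#' the temporal fine structure is removed: the band is replaced by a pure
#' tone carrier at the channel center frequency, amplitude-modulated by the
#' band's Hilbert envelope, then band-pass filtered with the same channel
#' filter. All subbands are summed. `cutoff_channel = 0` vocodes every
#' channel; `cutoff_channel = n_channels` reconstructs the input through the
#' analysis-synthesis chain with no channel vocoded.
#'
#' @param w a `waveform`
#' @param cutoff_channel integer in `[0, n_channels]`: highest intact channel
#' @param fb a `vocoder_filterbank` (default spans 100-10000 Hz, 32 channels)
#' @param keep_channels also return the per-channel contributions (attribute
#'   `"subbands"`, a `[n_channels x n]` matrix) for channel-level analyses
#' @return a `waveform` of the same duration
#' @export
tone_vocode <- function(w, cutoff_channel, fb = vocoder_filterbank(),
                        keep_channels = FALSE) {
  k <- cutoff_channel
  if (k < 0 || k > fb$n_channels || k != round(k))
    stop("cutoff_channel must be an integer in [0, n_channels]")
  n <- length(w$samples)
  t <- (seq_len(n) - 1L) / w$fs
  out <- numeric(n)
  chans <- if (keep_channels) matrix(0, fb$n_channels, n) else NULL
  for (ch in seq_len(fb$n_channels)) {
    cf <- fb$centers[ch]
    if (cf >= w$fs / 2) next
    band <- gammatone_filter(w$samples, cf, w$fs, zero_phase = TRUE)
    if (ch <= k) {
      contrib <- band
    } else {
      env <- hilbert_envelope(band)
      carrier <- cos(2 * pi * cf * t)
      voc <- env * carrier
      # RMS of env*cos is env_rms/sqrt(2); restore the band's power
      if (rms(voc) > 0) voc <- voc * (rms(band) / rms(voc))
      contrib <- gammatone_filter(voc, cf, w$fs, zero_phase = TRUE)
    }
    out <- out + contrib
    if (keep_channels) chans[ch, ] <- contrib
  }
  res <- waveform(out, w$fs,
                  meta = sprintf("tone-vocoded, cutoff channel %d", k))
  if (keep_channels) attr(res, "subbands") <- chans
  res
}

#' Inharmonic jitter pattern for a harmonic complex
#'
#' Component 1 stays at `f0` exactly; each harmonic above the fundamental is
#' shifted by a jitter fraction drawn independently and uniformly in
#' `[-0.5, +0.5]` of `f0`. Whole patterns are rejected and resampled until
#' every pair of adjacent components is separated by at least `min_spacing`
#' Hz, preserving the independent-uniform law conditional on acceptance.
#'
#' @param f0 fundamental frequency in Hz
#' @param n_harmonics number of components (>= 1)
#' @param seed integer seed; the pattern is deterministic given the seed
#' @param jitter_max maximal |jitter| as a fraction of f0 (default 0.5);
#'   0 gives the exact harmonic diagnostic pattern
#' @param min_spacing minimal adjacent spacing in Hz (default 30)
#' @param max_attempts rejection-sampling attempt budget
#' @return an object of class `jitter_pattern` with fields `f0`,
#'   `frequencies` (Hz), `jitter` (fractions of f0), `seed`
#' @export
jitter_harmonics <- function(f0, n_harmonics, seed, jitter_max = 0.5,
                             min_spacing = 30, max_attempts = 10000) {
  if (f0 <= 0 || n_harmonics < 1) stop("need f0 > 0 and n_harmonics >= 1")
  if (n_harmonics > 1 && f0 * (1 + 2 * jitter_max) < min_spacing)
    stop("spacing constraint unsatisfiable for this f0")
  old <- local_seed(seed); on.exit(restore_seed(old))
  base <- f0 * seq_len(n_harmonics)
  for (attempt in seq_len(max_attempts)) {
    j <- c(0, stats::runif(n_harmonics - 1L, -jitter_max, jitter_max))
    freqs <- base + j * f0
    if (n_harmonics == 1L || all(diff(freqs) >= min_spacing)) {
      return(structure(list(f0 = f0, frequencies = freqs, jitter = j,
                            seed = seed, attempts = attempt),
                       class = "jitter_pattern"))
    }
  }
  stop("rejection sampling failed within the attempt budget; ",
       "spacing constraint may be unsatisfiable")
}

#' @export
print.jitter_pattern <- function(x, ...) {
  cat(sprintf("jitter_pattern: f0 %g Hz, %d components, min spacing %.1f Hz\n",
              x$f0, length(x$frequencies), min(diff(x$frequencies))))
  invisible(x)
}

#' Noise with the power spectrum of a reference sound
#'
#' Randomizes the phases of the reference's Fourier spectrum (exactly
#' preserving its magnitude spectrum), yielding a noise with the same length,
#' power spectrum and RMS as the reference. An alternative FIR route filters
#' fresh white noise with the reference's smoothed spectrum (magnitudes then
#' match only in expectation).
#'
#' @param ref a non-silent `waveform`
#' @param seed integer seed
#' @param method "phase_randomization" (default, exact magnitude match) or
#'   "fir" (filtered white noise)
#' @return a `waveform`
#' @export
speech_shaped_noise <- function(ref, seed,
                                method = c("phase_randomization", "fir")) {
  method <- match.arg(method)
  x <- ref$samples
  if (all(x == 0)) stop("silent reference")
  n <- length(x)
  old <- local_seed(seed); on.exit(restore_seed(old))
  X <- stats::fft(x)
  if (method == "phase_randomization") {
    half <- seq(2L, ceiling((n + 1) / 2))
    phi <- stats::runif(length(half), 0, 2 * pi)
    Y <- X
    Y[half] <- Mod(X[half]) * exp(1i * phi)
    # hermitian symmetry for a real output
    if (n %% 2 == 0) {
      conj_idx <- seq(n, n / 2 + 2L)
      Y[conj_idx] <- Conj(Y[half[seq_along(conj_idx)]])
      Y[n / 2 + 1L] <- Mod(X[n / 2 + 1L])
    } else {
      conj_idx <- seq(n, (n + 3) / 2)
      Y[conj_idx] <- Conj(Y[half[seq_along(conj_idx)]])
    }
    y <- Re(stats::fft(Y, inverse = TRUE)) / n
  } else {
    wn <- stats::rnorm(n)
    y <- Re(stats::fft(stats::fft(wn) * Mod(X) / sqrt(n), inverse = TRUE)) / n
  }
  y <- y * rms(ref) / sqrt(mean(y^2))
  waveform(y, ref$fs, meta = "speech-shaped noise")
}

#' Sinusoidal amplitude modulation on a decibel scale
#'
#' Multiplies the waveform by a gain whose dB value follows
#' `(peak_to_valley/2) * sin(2*pi*rate*t + phase0)`, so the ratio of maximal
#' to minimal gain is exactly `peak_to_valley` dB. Defaults follow the
#' modulated-noise condition of speech-in-noise experiments: an 8 Hz sinusoid
#' with a 30 dB peak-to-valley ratio.
#'
#' @param w a `waveform`
#' @param rate modulation rate in Hz (default 8, must be below fs/2)
#' @param peak_to_valley peak-to-valley ratio in dB (default 30)
#' @param phase0 modulator starting phase in radians
#' @return a `waveform`
#' @export
sinusoidal_db_modulate <- function(w, rate = 8, peak_to_valley = 30,
                                   phase0 = 0) {
  if (rate <= 0) stop("modulation rate must be positive")
  if (rate >= w$fs / 2) stop("modulation rate at or above Nyquist")
  if (peak_to_valley == 0) return(w)
  n <- length(w$samples)
  t <- (seq_len(n) - 1L) / w$fs
  gain_db <- (peak_to_valley / 2) * sin(2 * pi * rate * t + phase0)
  waveform(w$samples * 10^(gain_db / 20), w$fs,
           meta = sprintf("dB-modulated %g Hz, %g dB", rate, peak_to_valley))
}
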