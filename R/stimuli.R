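# Reference sound pressure for dB SPL (pascal RMS)
P_REF <- 20e-6

#' Calibrated waveform container
#'
#' A `waveform` holds sound pressure samples in pascal together with the
#' sampling rate. All synthesis functions in the package calibrate levels in
#' dB SPL re 20 uPa RMS, so a tone synthesized at level L has RMS
#' 20e-6 * 10^(L/20) Pa.
#'
#' @param samples numeric vector of sound pressure values (pascal)
#' @param fs sampling rate in Hz (> 0)
#' @param meta optional free-text provenance string
#' @return an object of class `waveform`
#' @export
waveform <- function(samples, fs, meta = "") {
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("waveform samples must be finite numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 meta = as.character(meta)[1L]),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f ms), RMS %.3g Pa (%.1f dB SPL)\n",
              length(x$samples), x$fs, 1000 * length(x$samples) / x$fs,
              rms(x), db_spl(x)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Waveform RMS and sound level
#'
#' `rms()` returns the root-mean-square pressure in pascal; `db_spl()` the
#' corresponding sound pressure level in dB re 20 uPa.
#'
#' @param w a `waveform`
#' @return a single number
#' @export
rms <- function(w) {
  x <- if (inherits(w, "waveform")) w$samples else w
  sqrt(mean(x^2))
}

#' @rdname rms
#' @export
db_spl <- function(w) 20 * log10(rms(w) / P_REF)

#' ERB-number scale conversions
#'
#' Maps frequency in Hz to ERB-number (the number of equivalent rectangular
#' bandwidths below that frequency, Glasberg & Moore constants) and back:
#' E(f) = 21.4 log10(0.00437 f + 1). Equal steps on this scale approximate
#' equal distances along the cochlea.
#'
#' @param f frequency in Hz, >= 0 (vectorized)
#' @param E ERB-number (vectorized)
#' @return `erb_number` returns ERB-numbers; `erb_to_hz` frequencies in Hz.
#' @export
erb_number <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  21.4 * log10(0.00437 * f + 1)
}

#' @rdname erb_number
#' @export
erb_to_hz <- function(E) (10^(E / 21.4) - 1) / 0.00437

#' Equivalent rectangular bandwidth at a frequency
#' @param f frequency in Hz
#' @return bandwidth in Hz
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' Frequencies equally spaced on the ERB-number scale
#'
#' With `mode = "edges"` returns `n` points whose first and last values are
#' exactly `f_lo` and `f_hi`; with `mode = "centers"` returns the `n`
#' ERB-number midpoints of the `n + 1`-edge partition of `[E(f_lo), E(f_hi)]`.
#'
#' @param f_lo,f_hi frequency range in Hz, 0 < f_lo < f_hi
#' @param n number of points (>= 2)
#' @param mode "edges" or "centers"
#' @return an object of class `erb_axis` with fields `values` (Hz),
#'   `n_points`, `f_lo`, `f_hi`, `mode`
#' @export
erb_space <- function(f_lo, f_hi, n, mode = c("edges", "centers")) {
  mode <- match.arg(mode)
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  if (n < 2) stop("n must be >= 2")
  E_lo <- erb_number(f_lo); E_hi <- erb_number(f_hi)
  if (mode == "edges") {
    E <- seq(E_lo, E_hi, length.out = n)
    v <- erb_to_hz(E)
    v[1L] <- f_lo; v[n] <- f_hi  # pin endpoints exactly
  } else {
    edges <- seq(E_lo, E_hi, length.out = n + 1L)
    v <- erb_to_hz((edges[-1L] + edges[-(n + 1L)]) / 2)
  }
  structure(list(values = v, n_points = n, f_lo = f_lo, f_hi = f_hi,
                 mode = mode),
            class = "erb_axis")
}

#' @export
print.erb_axis <- function(x, ...) {
  cat(sprintf("erb_axis: %d %s over [%g, %g] Hz\n",
              x$n_points, x$mode, x$f_lo, x$f_hi))
  invisible(x)
}

# amplitude scale for a target dB SPL level given current RMS
level_gain <- function(current_rms, level) {
  if (current_rms <= 0) stop("cannot calibrate a silent signal")
  (P_REF * 10^(level / 20)) / current_rms
}

#' Synthesize a calibrated pure tone
#'
#' The tone is a cosine: `phase = 0` gives cosine (peak) starting phase,
#' matching the "cosine phase" convention of tone-discrimination stimuli.
#'
#' @param freq tone frequency in Hz, 0 < freq < fs/2
#' @param dur duration in seconds
#' @param fs sampling rate in Hz
#' @param level level in dB SPL re 20 uPa RMS
#' @param phase starting phase in radians (0 = cosine phase)
#' @return a `waveform`
#' @export
synth_tone <- function(freq, dur, fs, level = 60, phase = 0) {
  if (freq <= 0 || dur <= 0) stop("freq and dur must be positive")
  if (freq >= fs / 2) stop("tone frequency at or above Nyquist (aliasing)")
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- cos(2 * pi * freq * t + phase)
  amp <- P_REF * 10^(level / 20) * sqrt(2)  # peak for the requested RMS
  waveform(amp * x, fs, meta = sprintf("tone %g Hz, %g dB SPL", freq, level))
}

#' Synthesize a calibrated multi-component complex
#'
#' Components are cosines at exactly the requested frequencies with relative
#' linear amplitudes `amps`; the total waveform is rescaled so its overall
#' RMS matches `level` dB SPL.
#'
#' @param freqs component frequencies in Hz (all < fs/2)
#' @param amps per-component linear weights (recycled to length of freqs)
#' @param dur duration in seconds
#' @param fs sampling rate in Hz
#' @param level total level in dB SPL
#' @param phase starting phase in radians applied to every component
#' @return a `waveform`
#' @export
synth_complex <- function(freqs, amps = 1, dur, fs, level = 60, phase = 0) {
  if (length(freqs) < 1L) stop("at least one component required")
  if (any(freqs >= fs / 2)) stop("component frequency at or above Nyquist")
  amps <- rep_len(amps, length(freqs))
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (i in seq_along(freqs))
    x <- x + amps[i] * cos(2 * pi * freqs[i] * t + phase)
  x <- x * level_gain(sqrt(mean(x^2)), level)
  waveform(x, fs, meta = sprintf("complex, %d components", length(freqs)))
}

#' Synthesize calibrated Gaussian noise
#'
#' White Gaussian noise, optionally band-pass restricted in the frequency
#' domain, calibrated to `level` dB SPL.
#'
#' @param dur duration in seconds
#' @param fs sampling rate in Hz
#' @param level level in dB SPL
#' @param seed integer seed for reproducibility (NULL = current RNG state)
#' @param band optional c(f_lo, f_hi) Hz pass band
#' @return a `waveform`
#' @export
synth_noise <- function(dur, fs, level = 60, seed = NULL, band = NULL) {
  n <- round(dur * fs)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  x <- stats::rnorm(n)
  if (!is.null(band)) {
    X <- stats::fft(x)
    f <- fft_freqs(n, fs)
    X[abs(f) < band[1] | abs(f) > band[2]] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  x <- x * level_gain(sqrt(mean(x^2)), level)
  waveform(x, fs, meta = "gaussian noise")
}

#' Apply an onset/offset amplitude ramp
#'
#' Gain rises from 0 over the first `ramp_dur` seconds and falls back to 0
#' over the last `ramp_dur`; interior samples are untouched.
#'
#' @param w a `waveform`
#' @param shape one of "hanning", "half_hanning", "linear", "squared_cosine"
#' @param ramp_dur ramp duration in seconds; `2 * ramp_dur` must not exceed
#'   the waveform duration
#' @return a `waveform`
#' @export
apply_ramp <- function(w, shape = c("hanning", "half_hanning", "linear",
                                    "squared_cosine"),
                       ramp_dur) {
  shape <- match.arg(shape)
  if (ramp_dur < 0) stop("ramp_dur must be non-negative")
  if (ramp_dur == 0) return(w)
  n <- length(w$samples)
  nr <- round(ramp_dur * w$fs)
  if (2L * nr > n) stop("ramps longer than half the waveform")
  if (nr == 0L) return(w)
  u <- seq(0, 1, length.out = nr)  # 0 at edge, 1 at interior end
  g <- switch(shape,
    # rising half of a Hann window (Hanning and half-Hanning ramps coincide
    # on the ramp segment; both names are accepted for the quoted protocols)
    hanning        = 0.5 * (1 - cos(pi * u)),
    half_hanning   = 0.5 * (1 - cos(pi * u)),
    linear         = u,
    squared_cosine = cos(pi * (1 - u) / 2)^2)
  x <- w$samples
  x[seq_len(nr)] <- x[seq_len(nr)] * g
  x[seq.int(n - nr + 1L, n)] <- x[seq.int(n - nr + 1L, n)] * rev(g)
  waveform(x, w$fs, meta = w$meta)
}

#' Mix a target and a noise at a given signal-to-noise ratio
#'
#' The target is returned bit-exactly; the noise is rescaled so that
#' `RMS(target) / RMS(noise) = 10^(snr/20)`. `snr = Inf` encodes the
#' noiseless condition and returns the target unchanged.
#'
#' @param target,noise `waveform`s with equal sampling rate
#' @param snr signal-to-noise ratio in dB (target level re noise level);
#'   `Inf` for noiseless
#' @param length_policy "error" (default) requires equal lengths;
#'   "crop" crops both to the shorter
#' @return a `waveform` (target plus scaled noise)
#' @export
mix_at_snr <- function(target, noise, snr,
                       length_policy = c("error", "crop")) {
  length_policy <- match.arg(length_policy)
  if (is.infinite(snr) && snr > 0) return(target)
  if (target$fs != noise$fs) stop("sampling rates differ")
  nt <- length(target$samples); nn <- length(noise$samples)
  if (nt != nn) {
    if (length_policy == "error")
      stop("target and noise lengths differ (use length_policy = 'crop')")
    n <- min(nt, nn)
    target <- waveform(target$samples[seq_len(n)], target$fs, target$meta)
    noise <- waveform(noise$samples[seq_len(n)], noise$fs, noise$meta)
  }
  rn <- rms(noise)
  if (rn == 0) stop("noise is silent; cannot set a finite SNR")
  g <- rms(target) / rn / 10^(snr / 20)
  waveform(target$samples + g * noise$samples, target$fs,
           meta = sprintf("mix @ %g dB SNR", snr))
}

# ---- internal helpers --------------------------------------------------

# two-sided FFT bin frequencies
fft_freqs <- function(n, fs) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k * fs / n
}

# Set the RNG seed, returning the previous .Random.seed (or NULL)
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# analytic signal via FFT (Hilbert transform helper)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hilbert_envelope <- function(x) Mod(analytic_signal(x))

# linear convolution via FFT; returns the full length(x)+length(h)-1 result
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                     stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}
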