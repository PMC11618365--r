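#' Auditory nerve fiber type parameters
#'
#' The three canonical spontaneous-rate classes. Rates range from 0 to
#' `max_rate` spikes/s over a dynamic range of 20, 40 or 80 dB for high-,
#' medium- and low-spontaneous-rate fibers, with respective thresholds of
#' 0, 12 and 28 dB SPL; the population is 60% high-, 25% medium- and 15%
#' low-spontaneous-rate.
#'
#' @return a data.frame with columns `name`, `threshold` (dB SPL),
#'   `dynamic_range` (dB), `max_rate` (spikes/s), `spont_fraction`
#' @export
fiber_types <- function() {
  data.frame(
    name = c("high", "medium", "low"),
    threshold = c(0, 12, 28),
    dynamic_range = c(20, 40, 80),
    max_rate = c(250, 250, 250),
    spont_fraction = c(0.60, 0.25, 0.15),
    stringsAsFactors = FALSE)
}

#' Characteristic-frequency axis
#'
#' `n` characteristic frequencies spaced uniformly on the ERB-number scale,
#' endpoints inclusive (first CF = `f_lo`, last = `f_hi`).
#'
#' @param n number of CFs (default 50)
#' @param f_lo,f_hi frequency range in Hz (defaults 125 and 8000; use
#'   16000 for the wider localization-style range)
#' @return numeric vector of CFs in Hz, strictly increasing
#' @export
make_cf_axis <- function(n = 50, f_lo = 125, f_hi = 8000) {
  erb_space(f_lo, f_hi, n, mode = "edges")$values
}

#' Periphery model configuration
#'
#' Collects the parameters of the simplified cochlear model: the CF axis,
#' the inner-hair-cell low-pass cutoff (the phase-locking limit; the
#' experimental values are 3000, 1000, 320 and 50 Hz, but any positive
#' cutoff is allowed), the filter order, the output sampling rate, the
#' fiber-type table, and the total nerve fiber count per ear used to set
#' the binomial n per time-frequency-fiber bin:
#' `n = spont_fraction * total_fibers / n_CF`, rounded.
#'
#' @param cf_axis numeric vector of CFs (default `make_cf_axis()`)
#' @param ihc_cutoff IHC low-pass cutoff in Hz (default 3000)
#' @param ihc_order number of cascaded first-order sections (default 7)
#' @param fs_out output sampling rate in Hz (default 10000)
#' @param total_fibers total nerve fibers per ear (default 32000)
#' @param fibers fiber-type table as from [fiber_types()]
#' @return an object of class `periphery_config`
#' @export
periphery_config <- function(cf_axis = make_cf_axis(),
                             ihc_cutoff = 3000,
                             ihc_order = 7,
                             fs_out = 10000,
                             total_fibers = 32000,
                             fibers = fiber_types()) {
  if (ihc_cutoff <= 0) stop("ihc_cutoff must be positive")
  if (any(diff(cf_axis) <= 0)) stop("cf_axis must be strictly increasing")
  stopifnot(abs(sum(fibers$spont_fraction) - 1) < 1e-9)
  n_per_bin <- round(fibers$spont_fraction * total_fibers / length(cf_axis))
  if (any(n_per_bin < 1)) stop("fewer than one fiber per bin; increase total_fibers")
  names(n_per_bin) <- fibers$name
  structure(list(cf_axis = cf_axis, ihc_cutoff = ihc_cutoff,
                 ihc_order = ihc_order, fs_out = fs_out,
                 total_fibers = total_fibers, fibers = fibers,
                 n_per_bin = n_per_bin),
            class = "periphery_config")
}

#' @export
print.periphery_config <- function(x, ...) {
  cat(sprintf(paste0("periphery_config: %d CFs [%g, %g] Hz, IHC cutoff %g Hz",
                     " (order %d), fs_out %g Hz, %d fibers/ear\n"),
              length(x$cf_axis), min(x$cf_axis), max(x$cf_axis),
              x$ihc_cutoff, x$ihc_order, x$fs_out, x$total_fibers))
  invisible(x)
}

#' Gammatone filterbank subband decomposition
#'
#' Filters the waveform with a bank of FIR gammatone filters (impulse
#' responses truncated to 50 ms), one per characteristic frequency. The
#' filters are linear and time-invariant; each channel's gain at its CF is
#' normalized to unity.
#'
#' @param w a `waveform`
#' @param cfs characteristic frequencies in Hz (all below fs/2)
#' @param fir_dur FIR truncation length in seconds (default 0.05)
#' @return a `[n_CF x n_time]` matrix of subband signals (pascal)
#' @export
gammatone_subbands <- function(w, cfs, fir_dur = 0.05) {
  if (any(cfs >= w$fs / 2)) stop("CF at or above Nyquist")
  n <- length(w$samples)
  out <- matrix(0, nrow = length(cfs), ncol = n)
  for (i in seq_along(cfs))
    out[i, ] <- gammatone_filter(w$samples, cfs[i], w$fs, dur = fir_dur)
  out
}

# FIR impulse response of `order` cascaded identical one-pole low-pass
# sections with per-section cutoff `cutoff`: h(t) = a^k t^(k-1) e^(-a t) /
# (k-1)!, truncated to `dur`, Hanning-windowed, normalized to DC gain 1.
ihc_fir <- function(cutoff, fs, order = 7, dur = 0.05) {
  a <- 2 * pi * cutoff
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  h <- t^(order - 1) * exp(-a * t)
  win <- 0.5 * (1 + cos(pi * (seq_len(n) - 1L) / n))  # decaying Hann half
  h <- h * win
  h / sum(h)
}

#' Inner-hair-cell stage: half-wave rectification and low-pass filtering
#'
#' The stage that imposes the upper limit on phase locking. Each subband is
#' half-wave rectified and convolved with an FIR approximation of `order`
#' cascaded identical first-order low-pass sections with per-section cutoff
#' `cutoff` (impulse response truncated at 50 ms and Hanning windowed; DC
#' gain 1). The composite -3 dB point lies below `cutoff`; the cascade
#' magnitude at `cutoff` itself is about -21.1 dB for order 7.
#'
#' @param subbands `[n_CF x n_time]` matrix (or a vector for one channel)
#' @param cutoff per-section low-pass cutoff in Hz
#' @param fs sampling rate of the subbands in Hz
#' @param order cascade order (default 7)
#' @return matrix (or vector) of rectified, low-passed subbands
#' @export
ihc_lowpass <- function(subbands, cutoff, fs, order = 7) {
  if (cutoff >= fs / 2) stop("cutoff at or above Nyquist")
  vec <- is.null(dim(subbands))
  if (vec) subbands <- matrix(subbands, nrow = 1L)
  h <- ihc_fir(cutoff, fs, order)
  n <- ncol(subbands)
  out <- subbands
  for (i in seq_len(nrow(subbands)))
    out[i, ] <- fft_conv(pmax(subbands[i, ], 0), h)[seq_len(n)]
  if (vec) out[1L, ] else out
}

# Linear-phase windowed-sinc low-pass used for anti-aliasing before
# decimation; delay-compensated (centered) so timing is preserved.
antialias_lowpass <- function(x, fs, cutoff, taps = 129L) {
  m <- (taps - 1L) / 2L
  k <- seq(-m, m)
  h <- 2 * cutoff / fs * sinc_fn(2 * cutoff / fs * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / m))  # Hamming
  h <- h / sum(h)
  n <- length(x)
  y <- fft_conv(c(x, numeric(m)), h)
  y[seq.int(m + 1L, length.out = n)]
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Fiber rate-level function
#'
#' Pointwise (memoryless) sigmoid mapping instantaneous subband amplitude to
#' instantaneous firing rate. Amplitude `a` (pascal, non-negative) is mapped
#' to an instantaneous level `L = 20 log10(max(a, 1e-9) / 20e-6)` dB SPL; the
#' rate is logistic in L, centered at `threshold + dynamic_range/2`, with
#' slope set so the rate spans 5% to 95% of `max_rate` across
#' `[threshold, threshold + dynamic_range]`.
#'
#' @param subbands_pa non-negative amplitudes (any shape; pascal)
#' @param fiber one row of [fiber_types()] (a list or 1-row data.frame with
#'   `threshold`, `dynamic_range`, `max_rate`)
#' @return instantaneous firing rates in spikes/s, same shape as input
#' @export
rate_level <- function(subbands_pa, fiber) {
  if (any(subbands_pa < 0)) stop("rate_level requires non-negative input")
  L <- 20 * log10(pmax(subbands_pa, 1e-9) / P_REF)
  L_mid <- fiber$threshold + fiber$dynamic_range / 2
  k <- 2 * log(19) / fiber$dynamic_range  # 5% at threshold, 95% at thr+DR
  fiber$max_rate / (1 + exp(-k * (L - L_mid)))
}

#' Simplified cochlear model: waveform to instantaneous firing rates
#'
#' The full front-end pipeline: gammatone filterbank, half-wave
#' rectification, IHC low-pass filtering at the configured phase-locking
#' cutoff, anti-aliased downsampling to `fs_out`, then the per-fiber-type
#' rate-level sigmoids. For a `binaural_waveform` the pipeline is applied
#' to each ear with identical parameters.
#'
#' @param w a `waveform` or `binaural_waveform`
#' @param cfg a `periphery_config`
#' @return an object of class `nerve_response` with fields `rates`
#'   (`[n_CF x n_time x 3]` array, spikes/s), `cf_axis`, `fs_out`, `cfg`;
#'   for binaural input a list with classes `binaural_nerve_response` and
#'   elements `left`, `right`
#' @export
periphery_response <- function(w, cfg = periphery_config()) {
  if (inherits(w, "binaural_waveform")) {
    out <- list(left = periphery_response(w$left, cfg),
                right = periphery_response(w$right, cfg))
    class(out) <- "binaural_nerve_response"
    return(out)
  }
  stopifnot(inherits(w, "waveform"))
  fs_in <- w$fs
  dec <- fs_in / cfg$fs_out
  if (abs(dec - round(dec)) > 1e-9)
    stop("audio fs must be an integer multiple of fs_out")
  dec <- as.integer(round(dec))
  sb <- gammatone_subbands(w, cfg$cf_axis)
  sb <- ihc_lowpass(sb, cfg$ihc_cutoff, fs_in, cfg$ihc_order)
  if (dec > 1L) {
    keep <- seq(1L, ncol(sb), by = dec)
    out <- matrix(0, nrow = nrow(sb), ncol = length(keep))
    for (i in seq_len(nrow(sb)))
      out[i, ] <- antialias_lowpass(sb[i, ], fs_in, 0.45 * cfg$fs_out)[keep]
    sb <- out
  }
  sb[sb < 0] <- 0  # clamp filter ringing below zero before the sigmoids
  n_t <- ncol(sb)
  rates <- array(0, dim = c(length(cfg$cf_axis), n_t, nrow(cfg$fibers)))
  for (s in seq_len(nrow(cfg$fibers)))
    rates[, , s] <- rate_level(sb, cfg$fibers[s, ])
  structure(list(rates = rates, cf_axis = cfg$cf_axis, fs_out = cfg$fs_out,
                 cfg = cfg),
            class = "nerve_response")
}

#' @export
print.nerve_response <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("nerve_response: [%d CF x %d time x %d fiber types] @ %g Hz\n",
              d[1], d[2], d[3], x$fs_out))
  invisible(x)
}

#' Sample spike counts from instantaneous firing rates
#'
#' Converts a `nerve_response` into integer spike counts representing the
#' population response of `total_fibers` nerve fibers per ear. Each
#' time-frequency-fiber bin is Binomial(n, p) with `p = rate / fs_out` and
#' `n = spont_fraction * total_fibers / n_CF` (rounded). By default a
#' Gaussian approximation is used: samples are drawn from
#' Normal(np, np(1-p)), rounded to the nearest integer and clipped to
#' `[0, n]`. With `refractory = TRUE`, individual fibers are simulated as
#' Bernoulli processes whose rate is set to zero for 1 ms after each spike
#' (intended for small n; use `n_override` to scale the population down).
#'
#' @param r a `nerve_response`
#' @param cfg a `periphery_config` (defaults to the one stored in `r`)
#' @param seed integer seed; identical seeds give bit-identical counts
#' @param refractory logical; per-fiber sampling with 1 ms dead time
#' @param n_override optional named vector overriding `n` per fiber type
#' @return an object of class `spike_response` with fields `counts`
#'   (`[n_CF x n_time x 3]` integer array), `n_per_bin`, `fs_out`, `seed`
#' @export
sample_spikes <- function(r, cfg = r$cfg, seed, refractory = FALSE,
                          n_override = NULL) {
  p <- r$rates / r$fs_out
  if (any(p > 1)) stop("rate exceeds sampling rate: p > 1")
  n_per_bin <- if (is.null(n_override)) cfg$n_per_bin else n_override
  old <- local_seed(seed); on.exit(restore_seed(old))
  d <- dim(r$rates)
  counts <- array(0L, dim = d)
  if (!refractory) {
    for (s in seq_len(d[3])) {
      np <- n_per_bin[s] * p[, , s]
      v <- np * (1 - p[, , s])
      x <- round(stats::rnorm(length(np), mean = np, sd = sqrt(v)))
      counts[, , s] <- array(pmin(pmax(x, 0), n_per_bin[s]), dim = d[1:2])
    }
  } else {
    dead <- round(0.001 * r$fs_out)  # 1 ms refractory period in bins
    for (s in seq_len(d[3])) {
      nf <- n_per_bin[s]
      # fiber state: number of bins each fiber must still stay silent
      refr <- matrix(0L, nrow = d[1], ncol = nf)
      ps <- p[, , s]
      for (t in seq_len(d[2])) {
        pt <- matrix(ps[, t], nrow = d[1], ncol = nf)
        pt[refr > 0L] <- 0
        spikes <- matrix(stats::runif(d[1] * nf) < pt, nrow = d[1])
        counts[, t, s] <- as.integer(rowSums(spikes))
        refr <- pmax(refr - 1L, 0L)
        refr[spikes] <- dead
      }
    }
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, n_per_bin = n_per_bin, fs_out = r$fs_out,
                 cf_axis = r$cf_axis, seed = seed, refractory = refractory),
            class = "spike_response")
}

#' @export
print.spike_response <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "spike_response: [%d CF x %d time x %d fiber types] @ %g Hz, seed %s\n",
    d[1], d[2], d[3], x$fs_out, format(x$seed)))
  invisible(x)
}

#' Vector strength (synchronization index)
#'
#' The magnitude of the period-locked mean phasor of a weighted time series:
#' `|sum(w * exp(-2i pi f t))| / sum(w)` with bin weights `w` given by rates
#' or spike counts. 0 means no phase locking to `f`, 1 perfect locking.
#' A constant series gives 0; a half-wave-rectified sinusoid at `f` gives
#' pi/4; `1 + cos(2 pi f t)` gives 0.5.
#'
#' @param x non-negative rate or count series at one CF
#' @param f analysis frequency in Hz
#' @param fs sampling rate of `x` in Hz
#' @return a number in `[0, 1]`
#' @export
vector_strength <- function(x, f, fs) {
  if (any(x < 0)) stop("weights must be non-negative")
  s <- sum(x)
  if (s == 0) stop("all-zero input: vector strength undefined")
  t <- (seq_along(x) - 1L) / fs
  Mod(sum(x * exp(-2i * pi * f * t))) / s
}

#' Time-averaged excitation pattern
#'
#' Mean firing rate per CF, averaged over time and (by default) summed over
#' fiber types weighted by their population fractions.
#'
#' @param r a `nerve_response` or `spike_response`
#' @param weights per-fiber-type weights (default the spont fractions)
#' @return numeric vector over CFs
#' @export
excitation_pattern <- function(r, weights = fiber_types()$spont_fraction) {
  a <- if (inherits(r, "nerve_response")) r$rates else r$counts
  d <- dim(a)
  out <- numeric(d[1])
  for (s in seq_len(d[3]))
    out <- out + weights[s] * rowMeans(a[, , s, drop = FALSE][, , 1])
  out
}
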