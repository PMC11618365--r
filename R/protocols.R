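# Reference observers: simple, fully documented decision rules that stand
# in for task-optimized networks so the experiment protocols can run
# end-to-end at desk scale. Their outputs support property-based checks
# (orderings, measurability), not reproduction of network-level numbers.

#' Two-interval frequency-discrimination trial set
#'
#' Samples trials for a 2AFC frequency-discrimination task: the first
#' tone's frequency f1 log-uniform within a band around `band_center`, the
#' interval magnitude I log-uniform between `i_lo` and `i_hi` octaves, the
#' direction +/- with equal probability (`f2 = f1 * 2^(+/-I)`), and the two
#' tone levels roved independently and uniformly between 37 and 43 dB SPL.
#'
#' @param band_center band center frequency in Hz
#' @param band_width band width in octaves (default 0.25)
#' @param n_trials number of trials
#' @param seed integer seed; the trial set is reproducible bit-exactly
#' @param i_lo,i_hi interval magnitude range in octaves (defaults 1e-6 and
#'   1e-1)
#' @return data.frame of class `trial_set` with columns `f1`, `f2`,
#'   `level1`, `level2`, `interval`, `label` (TRUE when f2 > f1)
#' @export
freq_discrimination_dataset <- function(band_center, band_width = 0.25,
                                        n_trials, seed,
                                        i_lo = 1e-6, i_hi = 1e-1) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  half <- band_width / 2
  f1 <- band_center * 2^stats::runif(n_trials, -half, half)
  I <- exp(stats::runif(n_trials, log(i_lo), log(i_hi)))
  up <- stats::runif(n_trials) < 0.5
  f2 <- f1 * 2^(ifelse(up, I, -I))
  out <- data.frame(f1 = f1, f2 = f2,
                    level1 = stats::runif(n_trials, 37, 43),
                    level2 = stats::runif(n_trials, 37, 43),
                    interval = I, label = up)
  class(out) <- c("trial_set", "data.frame")
  attr(out, "band_center") <- band_center
  attr(out, "seed") <- seed
  out
}

# ERB-weighted centroid of the time-averaged excitation pattern
erb_centroid <- function(sp) {
  ex <- excitation_pattern(sp)
  if (sum(ex) == 0) stop("silent interval: no excitation")
  E <- erb_number(sp$cf_axis)
  sum(E * ex) / sum(ex)
}

#' Rate-place reference observer
#'
#' Judges which of two intervals has the higher frequency using only
#' time-averaged ("rate-place") information: the ERB-weighted centroid of
#' each interval's time-averaged excitation pattern. Insensitive to spike
#' timing by construction, so its performance is unchanged across IHC
#' cutoffs.
#'
#' @param cfg a `periphery_config`
#' @return an object of class `observer` with elements `id`, `cfg` and
#'   `judge(sp1, sp2, seed)` returning TRUE when interval 2 is judged higher
#' @export
rate_place_observer <- function(cfg = periphery_config()) {
  judge <- function(sp1, sp2, seed = 1) {
    c1 <- erb_centroid(sp1); c2 <- erb_centroid(sp2)
    if (c1 == c2) {
      old <- local_seed(seed); on.exit(restore_seed(old))
      return(stats::runif(1) < 0.5)
    }
    c2 > c1
  }
  structure(list(id = "rate_place", cfg = cfg, judge = judge),
            class = "observer")
}

# dominant periodicity of the summed spike train, restricted to
# [f_lo, f_hi]; NA when no significant spectral peak stands out
dominant_periodicity <- function(sp, f_lo, f_hi) {
  x <- apply(sp$counts, 2, sum)  # population spike train
  x <- x - mean(x)
  n <- length(x)
  X <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  f <- (seq_len(floor(n / 2)) - 1L) * sp$fs_out / n
  sel <- f >= f_lo & f <= f_hi
  if (!any(sel)) return(NA_real_)
  Xs <- X[sel]; fsel <- f[sel]
  i <- which.max(Xs)
  # significance: peak must exceed 4x the median in-band magnitude
  if (Xs[i] < 4 * stats::median(Xs)) return(NA_real_)
  # parabolic refinement on the magnitude spectrum
  fi <- fsel[i]
  if (i > 1L && i < length(Xs)) {
    y1 <- Xs[i - 1]; y2 <- Xs[i]; y3 <- Xs[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) fi <- fi + 0.5 * (y1 - y3) / den * (fsel[2] - fsel[1])
  }
  fi
}

#' Spike-timing reference observer
#'
#' Estimates each interval's dominant periodicity from the discrete Fourier
#' magnitude of the summed population spike train (restricted to a band
#' around the interval frequencies) and judges the trial by comparing the
#' two estimates. When either interval lacks a significant spectral peak -
#' as happens above the phase-locking limit - the observer falls back on the
#' rate-place judgment, so its advantage over [rate_place_observer()]
#' shrinks to zero as the IHC cutoff is lowered.
#'
#' @param cfg a `periphery_config`
#' @param band c(f_lo, f_hi) Hz periodicity search band
#' @return an `observer` with `judge(sp1, sp2, seed)`
#' @export
timing_observer <- function(cfg = periphery_config(), band = c(50, 4500)) {
  rp <- rate_place_observer(cfg)
  judge <- function(sp1, sp2, seed = 1) {
    p1 <- dominant_periodicity(sp1, band[1], band[2])
    p2 <- dominant_periodicity(sp2, band[1], band[2])
    if (is.na(p1) || is.na(p2)) return(rp$judge(sp1, sp2, seed))
    if (p1 == p2) return(rp$judge(sp1, sp2, seed))
    p2 > p1
  }
  structure(list(id = "timing", cfg = cfg, judge = judge, band = band),
            class = "observer")
}

#' Cross-correlation binaural reference observer
#'
#' Estimates the interaural time difference from a binaural spike response:
#' per characteristic frequency, the summed left and right spike trains are
#' cross-correlated over lags up to +/-1 ms; cross-correlograms are pooled
#' across CFs and the best lag, refined by parabolic interpolation, is the
#' lateral estimate (in seconds; positive = right leads, i.e. perceived to
#' the right).
#'
#' @param cfg a `periphery_config`
#' @param max_lag maximum |lag| in seconds (default 1e-3)
#' @return an `observer` with `estimate(sp_left, sp_right)` returning the
#'   ITD estimate in seconds
#' @export
crosscorr_observer <- function(cfg = periphery_config(), max_lag = 1e-3) {
  estimate <- function(sp_left, sp_right) {
    if (is.null(sp_left$counts) || is.null(sp_right$counts))
      stop("binaural spike input required")
    fs <- sp_left$fs_out
    ml <- max(1L, floor(max_lag * fs))
    n_cf <- dim(sp_left$counts)[1]
    pooled <- numeric(2L * ml + 1L)
    for (i in seq_len(n_cf)) {
      xl <- rowSums(sp_left$counts[i, , , drop = FALSE][1, , ])
      xr <- rowSums(sp_right$counts[i, , , drop = FALSE][1, , ])
      xl <- xl - mean(xl); xr <- xr - mean(xr)
      if (all(xl == 0) || all(xr == 0)) next
      cc <- stats::ccf(xr, xl, lag.max = ml, plot = FALSE, demean = FALSE)
      pooled <- pooled + as.numeric(cc$acf)
    }
    lags <- seq(-ml, ml)
    i <- which.max(pooled)
    lag <- lags[i]
    if (i > 1L && i < length(pooled)) {
      y1 <- pooled[i - 1]; y2 <- pooled[i]; y3 <- pooled[i + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
    }
    -lag / fs  # ccf(xr, xl) peaks at -d when the right ear leads by d
  }
  structure(list(id = "crosscorr", cfg = cfg, estimate = estimate),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("observer: %s (IHC cutoff %g Hz)\n", x$id, x$cfg$ihc_cutoff))
  invisible(x)
}

#' ITD lateralization experiment: thresholds vs frequency
#'
#' For each tone frequency, pure tones carrying fine-structure ITDs from a
#' grid are run through the binaural periphery, spike responses are sampled
#' (`n_repeats` seeds per stimulus), and the observer produces a lateral
#' estimate per trial. All ordered pairs of trials form lateralization
#' judgments; the proportion of rightward judgments vs the ITD difference
#' is fit with a Normal CDF and the 70.7% threshold extracted. Frequencies
#' whose psychometric never supports the criterion within the grid are
#' flagged unmeasurable - the behavior expected above the phase-locking
#' limit. Default grids are desk-scale reductions of the full printed
#' 1 us x 50 Hz sweep.
#'
#' @param obs a binaural `observer` (see [crosscorr_observer()])
#' @param freqs tone frequencies in Hz (default c(250, 500, 1000, 2000,
#'   3500))
#' @param itds_us ITD grid in microseconds (default seq(-160, 160, by = 40))
#' @param cfg the `periphery_config` (defaults to the observer's)
#' @param dur tone duration in seconds (default 0.15)
#' @param ramp_dur linear ramp duration in seconds (default 0.02)
#' @param fs audio sampling rate (default 20000)
#' @param level tone level in dB SPL (default 60)
#' @param n_repeats spike-sampling repeats per stimulus (default 4)
#' @param seed integer protocol seed
#' @return data.frame with one row per frequency: `freq`, `threshold_us`,
#'   `measurable`
#' @export
run_itd_lateralization <- function(obs,
                                   freqs = c(250, 500, 1000, 2000, 3500),
                                   itds_us = seq(-160, 160, by = 40),
                                   cfg = obs$cfg, dur = 0.15,
                                   ramp_dur = 0.02, fs = 20000,
                                   level = 60, n_repeats = 4, seed = 1) {
  stopifnot(length(freqs) > 0, length(itds_us) > 1)
  res <- data.frame(freq = freqs, threshold_us = NA_real_,
                    measurable = FALSE)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    ests <- matrix(NA_real_, nrow = length(itds_us), ncol = n_repeats)
    tone <- apply_ramp(synth_tone(f, dur, fs, level), "linear", ramp_dur)
    for (ii in seq_along(itds_us)) {
      b <- impose_itd(tone, itds_us[ii] * 1e-6, mode = "fine_structure",
                      carrier_freq = f)
      nr <- periphery_response(b, cfg)
      for (rep in seq_len(n_repeats)) {
        s <- seed + 7919L * fi + 104729L * ii + rep
        spl <- sample_spikes(nr$left, cfg, seed = s)
        spr <- sample_spikes(nr$right, cfg, seed = s + 499979L)
        ests[ii, rep] <- obs$estimate(spl, spr)
      }
    }
    # all ordered pairs of trials -> rightward proportion vs delta ITD
    trials <- expand.grid(i = seq_along(itds_us), j = seq_along(itds_us),
                          r1 = seq_len(n_repeats), r2 = seq_len(n_repeats))
    trials <- trials[trials$i != trials$j, ]
    d_itd <- itds_us[trials$j] - itds_us[trials$i]
    right <- ests[cbind(trials$j, trials$r2)] >
      ests[cbind(trials$i, trials$r1)]
    agg <- stats::aggregate(right, list(d = d_itd), mean)
    nper <- stats::aggregate(right, list(d = d_itd), length)
    fit <- tryCatch(
      fit_psychometric(agg$d, round(agg$x * nper$x), nper$x),
      error = function(e) NULL)
    th <- if (!is.null(fit) && isTRUE(fit$measurable)) {
      threshold(fit, 0.707, method = "fit")
    } else {
      # near-perfect observers yield step psychometrics the ML fit cannot
      # identify; the threshold is then read off by linear interpolation,
      # bounded below by the grid resolution
      threshold(data.frame(x = agg$d, p = agg$x), 0.707,
                method = "interpolation")
    }
    # a threshold beyond the grid is not supported by the data
    if (isTRUE(th$measurable) && th$threshold > 0 &&
        th$threshold <= max(abs(itds_us))) {
      res$threshold_us[fi] <- th$threshold
      res$measurable[fi] <- TRUE
    }
  }
  res
}

#' Two-interval frequency discrimination: threshold at 75% correct
#'
#' Evaluates an observer on a grid of interval magnitudes around a band
#' center: for each magnitude, `n_eval` trials (random direction, levels
#' roved 37-43 dB SPL) are judged from sampled spike responses; accuracy vs
#' log interval magnitude is fit with a Normal CDF and the 75%-correct
#' threshold (a Weber fraction in octaves) returned.
#'
#' @param obs an `observer` with a `judge` element
#' @param band_center tone frequency at the band center, Hz
#' @param n_eval trials per interval magnitude (default 12)
#' @param intervals interval magnitudes in octaves (default a log grid
#'   5e-4..1e-1; the full printed evaluation range reaches 5e-7)
#' @param cfg the `periphery_config` (defaults to the observer's)
#' @param dur tone duration in seconds (default 0.1)
#' @param fs audio sampling rate (default 20000)
#' @param seed integer seed
#' @return a list with `threshold` (`threshold_result`, octaves),
#'   `accuracy` (data.frame interval x proportion correct)
#' @export
run_frequency_discrimination <- function(obs, band_center, n_eval = 12,
                                         intervals =
                                           10^seq(-4, -1, length.out = 7),
                                         cfg = obs$cfg, dur = 0.1,
                                         fs = 20000, seed = 1) {
  acc <- numeric(length(intervals))
  old <- local_seed(seed); on.exit(restore_seed(old))
  for (ii in seq_along(intervals)) {
    I <- intervals[ii]
    correct <- logical(n_eval)
    for (tr in seq_len(n_eval)) {
      up <- stats::runif(1) < 0.5
      f1 <- band_center
      f2 <- f1 * 2^(if (up) I else -I)
      l1 <- stats::runif(1, 37, 43); l2 <- stats::runif(1, 37, 43)
      s <- sample.int(.Machine$integer.max %/% 2L, 2L)
      sp1 <- sample_spikes(periphery_response(
        synth_tone(f1, dur, fs, l1), cfg), cfg, seed = s[1])
      sp2 <- sample_spikes(periphery_response(
        synth_tone(f2, dur, fs, l2), cfg), cfg, seed = s[2])
      judged_up <- obs$judge(sp1, sp2, seed = s[1] + 1L)
      correct[tr] <- judged_up == up
    }
    acc[ii] <- mean(correct)
  }
  fit <- tryCatch(
    fit_psychometric(log10(intervals), round(acc * n_eval),
                     rep(n_eval, length(intervals))),
    error = function(e) NULL)
  th <- if (!is.null(fit) && isTRUE(fit$measurable)) {
    t75 <- threshold(fit, 0.75, method = "fit")
    if (isTRUE(t75$measurable))
      threshold_result(10^t75$threshold, 0.75, "fit", TRUE)
    else t75
  } else threshold_result(NA_real_, 0.75, "fit", FALSE)
  list(threshold = th,
       accuracy = data.frame(interval = intervals, p_correct = acc))
}

#' Sound-localization grids
#'
#' Returns the evaluation loudspeaker array - a 19-by-5 grid spanning 180
#' degrees of frontal azimuth and 0-40 degrees of elevation in 10-degree
#' steps (95 positions) - and the source-location label space spanning 360
#' degrees of azimuth in 5-degree bins and 0-60 degrees of elevation in
#' 10-degree bins (72 x 7 = 504 classes).
#'
#' @return list with `speakers` (data.frame `azimuth`, `elevation`; 95
#'   rows) and `classes` (data.frame `azimuth_center`, `elevation_center`;
#'   504 rows) plus bin-edge attributes
#' @export
localization_grids <- function() {
  speakers <- expand.grid(azimuth = seq(-90, 90, by = 10),
                          elevation = seq(0, 40, by = 10))
  az_edges <- seq(-180, 180, by = 5)
  el_edges <- seq(-5, 65, by = 10)
  classes <- expand.grid(
    azimuth_center = az_edges[-length(az_edges)] + 2.5,
    elevation_center = seq(0, 60, by = 10))
  out <- list(speakers = speakers, classes = classes)
  attr(out, "azimuth_edges") <- az_edges
  attr(out, "elevation_edges") <- el_edges
  out
}

#' Synthetic word-recognition accuracy generator
#'
#' A closed-loop test harness for the vocoding-SRT protocol: generates
#' accuracy-vs-SNR tables from a logistic psychometric whose midpoint
#' improves (moves left) with the cutoff channel by a known built-in
#' benefit, optionally with binomial trial noise. Purely synthetic - it
#' stands in for word-recognition scores that would require speech corpora.
#'
#' @param benefit_at_32 built-in SRT benefit (dB) at cutoff 32 re cutoff 0
#' @param srt0 baseline midpoint SNR in dB at cutoff 0 (default -2)
#' @param asymptote upper accuracy asymptote (default 0.95)
#' @param slope logistic slope in dB (default 2)
#' @param n_trials binomial trials per point (Inf = noiseless)
#' @param seed integer seed
#' @return function(cutoff_channel, snrs, noise) -> accuracy vector
#' @export
synthetic_accuracy_generator <- function(benefit_at_32, srt0 = -2,
                                         asymptote = 0.95, slope = 2,
                                         n_trials = Inf, seed = 1) {
  force(benefit_at_32); force(srt0); force(asymptote); force(slope)
  counter <- 0L
  function(cutoff_channel, snrs, noise = "stationary") {
    mid <- srt0 - benefit_at_32 * cutoff_channel / 32
    p <- asymptote / (1 + exp(-(snrs - mid) / slope))
    if (is.finite(n_trials)) {
      counter <<- counter + 1L
      old <- local_seed(seed + counter); on.exit(restore_seed(old))
      p <- stats::rbinom(length(p), n_trials, p) / n_trials
    }
    p
  }
}

#' Tone-vocoding speech-reception-threshold protocol
#'
#' Runs the benefit-from-TFS analysis chain over a grid of vocoder cutoff
#' channels and noise types: an accuracy source (a function
#' `f(cutoff, snrs, noise)` such as [synthetic_accuracy_generator()], or a
#' precomputed table) provides word-accuracy-vs-SNR psychometrics, SRTs are
#' extracted at half-maximal performance via [srt()], and thresholds are
#' expressed relative to the fully vocoded baseline via [tfs_benefit()].
#'
#' @param accuracy_source function(cutoff, snrs, noise) -> accuracies, or a
#'   data.frame with columns `cutoff_channel`, `noise`, `snr`, `accuracy`
#' @param cutoffs cutoff channels (default seq(0, 32, by = 4))
#' @param snrs SNR grid in dB (default seq(-15, 15, by = 3))
#' @param noises noise-type labels (default c("stationary", "modulated"))
#' @return the benefit table from [tfs_benefit()] (columns
#'   `cutoff_channel`, `noise`, `srt`, `benefit`)
#' @export
run_vocoding_srt <- function(accuracy_source,
                             cutoffs = seq(0, 32, by = 4),
                             snrs = seq(-15, 15, by = 3),
                             noises = c("stationary", "modulated")) {
  grid <- expand.grid(cutoff_channel = cutoffs, noise = noises,
                      stringsAsFactors = FALSE)
  grid$srt <- NA_real_
  for (i in seq_len(nrow(grid))) {
    acc <- if (is.function(accuracy_source)) {
      accuracy_source(grid$cutoff_channel[i], snrs, grid$noise[i])
    } else {
      tab <- accuracy_source
      sel <- tab$cutoff_channel == grid$cutoff_channel[i] &
        tab$noise == grid$noise[i]
      tab$accuracy[sel][match(snrs, tab$snr[sel])]
    }
    res <- srt(acc, snrs, criterion = "half_max")
    grid$srt[i] <- if (isTRUE(res$measurable)) res$threshold else NA_real_
  }
  if (any(is.na(grid$srt)))
    stop("unmeasurable SRT in the grid; cannot form the benefit table")
  tfs_benefit(grid)
}
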