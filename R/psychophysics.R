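#' Maximum-likelihood Normal-CDF psychometric fit
#'
#' Fits `P(response | x) = Phi((x - mu) / sigma)` to binomial data by
#' maximum likelihood (a probit regression). `mu` is the stimulus value at
#' 50% and `sigma` the spread; thresholds at other criteria follow from the
#' inverse Normal CDF via [threshold()].
#'
#' @param x stimulus values (>= 3 distinct)
#' @param k number of "success" responses at each x
#' @param n number of trials at each x (>= 1)
#' @return an object of class `psychometric_fit` with fields `mu`, `sigma`,
#'   `loglik`, `measurable` (FALSE for degenerate/non-identifiable data),
#'   and `data`
#' @export
fit_psychometric <- function(x, k, n) {
  stopifnot(length(x) == length(k), length(x) == length(n))
  if (length(unique(x)) < 3) stop("need >= 3 distinct stimulus values")
  if (any(n < 1)) stop("each level needs >= 1 trial")
  if (any(k < 0 | k > n)) stop("successes must lie in [0, n]")
  dat <- data.frame(x = x, k = k, n = n)
  # flat data, and perfect step data (complete separation: the ML sigma
  # does not exist, it degenerates to 0), are non-identifiable
  degenerate <- all(k == 0) || all(k == n) || all(k == 0 | k == n)
  fit <- NULL
  if (!degenerate) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(cbind(k, n - k) ~ x, family =
                                    stats::binomial(link = "probit"),
                                  data = dat)),
      error = function(e) NULL)
  }
  if (is.null(fit) || !is.finite(stats::coef(fit)[2]) ||
      stats::coef(fit)[2] == 0) {
    return(structure(list(mu = NA_real_, sigma = NA_real_,
                          loglik = NA_real_, measurable = FALSE, data = dat),
                     class = "psychometric_fit"))
  }
  b <- stats::coef(fit)
  sigma <- 1 / b[2]
  mu <- -b[1] / b[2]
  # perfect-separation / step data drive sigma toward 0: flag it
  measurable <- is.finite(sigma) && sigma > 0 &&
    abs(sigma) > 1e-6 * diff(range(x))
  structure(list(mu = unname(mu), sigma = unname(sigma),
                 loglik = as.numeric(stats::logLik(fit)),
                 vcov = stats::vcov(fit), coef = b,
                 measurable = measurable, data = dat),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (isTRUE(x$measurable))
    cat(sprintf("psychometric_fit: mu = %.4g, sigma = %.4g\n", x$mu, x$sigma))
  else cat("psychometric_fit: non-identifiable (measurable = FALSE)\n")
  invisible(x)
}

#' Threshold at a criterion level
#'
#' For `method = "fit"` the input is a `psychometric_fit` and the threshold
#' is `mu + sigma * qnorm(criterion)` (so criterion 0.5 returns `mu`
#' exactly). For `method = "interpolation"` the input is a data.frame with
#' columns `x` and `p` and the threshold is the linearly interpolated
#' abscissa of the first crossing. A psychometric that never reaches the
#' criterion yields `measurable = FALSE` (an "unmeasurably high" threshold).
#'
#' @param fit_or_data a `psychometric_fit`, or a data.frame `x`, `p`
#' @param criterion criterion proportion (e.g. 0.707, 0.75, 0.5)
#' @param method "fit" or "interpolation"
#' @return an object of class `threshold_result` with fields `threshold`,
#'   `criterion`, `method`, `measurable`
#' @export
threshold <- function(fit_or_data, criterion = 0.707,
                      method = c("fit", "interpolation")) {
  method <- match.arg(method)
  if (method == "fit") {
    fit <- fit_or_data
    stopifnot(inherits(fit, "psychometric_fit"))
    if (!isTRUE(fit$measurable)) {
      return(threshold_result(NA_real_, criterion, method, FALSE))
    }
    thr <- fit$mu + fit$sigma * stats::qnorm(criterion)
    return(threshold_result(thr, criterion, method, TRUE))
  }
  dat <- fit_or_data
  stopifnot(is.data.frame(dat), all(c("x", "p") %in% names(dat)))
  dat <- dat[order(dat$x), ]
  above <- dat$p >= criterion
  if (!any(above))
    return(threshold_result(NA_real_, criterion, method, FALSE))
  i <- which(above)[1]
  if (i == 1L) return(threshold_result(dat$x[1], criterion, method, TRUE))
  x0 <- dat$x[i - 1L]; x1 <- dat$x[i]
  p0 <- dat$p[i - 1L]; p1 <- dat$p[i]
  thr <- x0 + (criterion - p0) / (p1 - p0) * (x1 - x0)
  threshold_result(thr, criterion, method, TRUE)
}

threshold_result <- function(threshold, criterion, method, measurable) {
  structure(list(threshold = threshold, criterion = criterion,
                 method = method, measurable = measurable),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (isTRUE(x$measurable))
    cat(sprintf("threshold_result: %.4g at %.1f%% (%s)\n",
                x$threshold, 100 * x$criterion, x$method))
  else cat(sprintf("threshold_result: unmeasurable at %.1f%%\n",
                   100 * x$criterion))
  invisible(x)
}

#' Proportion of rightward judgments from paired location estimates
#'
#' Trials in which the signed estimate for the second stimulus exceeds that
#' for the first count as rightward judgments. Exact ties are broken at
#' random (each direction with probability 1/2) under the given seed; the
#' number of ties is recorded in the result's attributes.
#'
#' @param est1,est2 paired signed location estimates (azimuth or lateral
#'   position), equal length
#' @param seed integer seed for tie breaking
#' @return proportion of rightward judgments, with attribute `n_ties`
#' @export
lateralization_judgments <- function(est1, est2, seed = 1) {
  if (length(est1) == 0L) stop("empty input")
  stopifnot(length(est1) == length(est2))
  right <- est2 > est1
  ties <- est2 == est1
  if (any(ties)) {
    old <- local_seed(seed); on.exit(restore_seed(old))
    right[ties] <- stats::runif(sum(ties)) < 0.5
  }
  structure(mean(right), n_ties = sum(ties))
}

#' Dimensionless perceptual cue weight
#'
#' Quantifies how strongly an imposed interaural cue (ITD or ILD) shifts
#' the perceived azimuth. Responses are mapped to cue units through
#' `cue_map` (rear-hemifield azimuths are first reflected across the
#' coronal plane), the shift in cue units is divided by the imposed cue
#' amount, and the ratio is averaged over conditions. A weight of 1 means
#' an imposed cue of tau shifts the percept by an azimuth corresponding to
#' a cue change of tau between real sources; 0 means no effect.
#'
#' @param unbiased_resp azimuth responses (degrees) to unbiased stimuli
#' @param biased_resp azimuth responses (degrees) to cue-biased stimuli
#' @param imposed_bias imposed cue amounts (cue units, recycled)
#' @param cue_map data.frame with columns `azimuth` (degrees) and `cue`
#'   mapping frontal azimuths to cue values; must be monotone in the range
#'   used. See [spherical_head_cue_map()] for a synthetic default.
#' @return mean dimensionless weight, with attribute `per_trial`
#' @export
perceptual_weight <- function(unbiased_resp, biased_resp, imposed_bias,
                              cue_map) {
  stopifnot(length(unbiased_resp) == length(biased_resp))
  imposed_bias <- rep_len(imposed_bias, length(unbiased_resp))
  if (any(imposed_bias == 0)) stop("imposed bias must be nonzero")
  lookup <- function(az) {
    az <- reflect_to_front(az)
    if (any(az < min(cue_map$azimuth) - 1e-9) ||
        any(az > max(cue_map$azimuth) + 1e-9))
      stop("azimuth outside cue_map domain")
    stats::approx(cue_map$azimuth, cue_map$cue, xout = az, rule = 2)$y
  }
  w <- (lookup(biased_resp) - lookup(unbiased_resp)) / imposed_bias
  structure(mean(w), per_trial = w)
}

#' Reflect azimuths in the rear hemifield across the coronal plane
#'
#' Azimuths are in degrees with 0 straight ahead, positive to the right.
#' Angles beyond +/-90 degrees (rear hemifield) map to their front-hemifield
#' mirror: 120 -> 60, -150 -> -30.
#'
#' @param az azimuth(s) in degrees, any real value
#' @return azimuth(s) in `[-90, 90]`
#' @export
reflect_to_front <- function(az) {
  az <- ((az + 180) %% 360) - 180  # wrap to (-180, 180]
  ifelse(az > 90, 180 - az, ifelse(az < -90, -180 - az, az))
}

#' Synthetic spherical-head azimuth-to-cue map
#'
#' A stand-in for HRTF-derived azimuth-to-cue mappings: ITDs follow the
#' Woodworth spherical-head formula `tau = (r/c) (theta + sin theta)` with
#' head radius `r` and speed of sound `c`; ILDs follow a sine law peaking
#' at `ild_max` at +/-90 degrees. This map is synthetic - supply measured
#' tables for fidelity to any particular head.
#'
#' @param cue "itd" (microseconds) or "ild" (dB)
#' @param azimuths grid of frontal azimuths in degrees
#' @param head_radius head radius in meters (default 0.0875)
#' @param c_sound speed of sound in m/s (default 343)
#' @param ild_max maximal ILD in dB at 90 degrees (default 10)
#' @return data.frame with columns `azimuth`, `cue`
#' @export
spherical_head_cue_map <- function(cue = c("itd", "ild"),
                                   azimuths = seq(-90, 90, by = 5),
                                   head_radius = 0.0875, c_sound = 343,
                                   ild_max = 10) {
  cue <- match.arg(cue)
  th <- azimuths * pi / 180
  v <- if (cue == "itd") 1e6 * head_radius / c_sound * (th + sin(th))
       else ild_max * sin(th)
  data.frame(azimuth = azimuths, cue = v)
}

#' Speech reception threshold from an accuracy-vs-SNR psychometric
#'
#' Fits a monotone logistic sigmoid with a free upper asymptote,
#' `acc(snr) = A / (1 + exp(-(snr - m) / s))`, by least squares, and
#' returns the SNR at the criterion: with `criterion = "half_max"` the SNR
#' yielding half the fitted asymptote (which is `m` itself); with a numeric
#' criterion `p`, the SNR where the fitted curve reaches `p` (unmeasurable
#' if `p >= A`).
#'
#' @param accuracy proportion correct at each SNR
#' @param snrs SNR values in dB (>= 4 points)
#' @param criterion "half_max" or a numeric proportion
#' @return a `threshold_result` (threshold in dB SNR); attribute `fit`
#'   holds `A`, `m`, `s`
#' @export
srt <- function(accuracy, snrs, criterion = "half_max") {
  stopifnot(length(accuracy) == length(snrs))
  if (length(snrs) < 4) stop("need >= 4 SNR points")
  if (max(accuracy) - min(accuracy) < 1e-3) {
    crit <- if (identical(criterion, "half_max")) NA_real_
            else as.numeric(criterion)
    return(threshold_result(NA_real_, crit, "fit", FALSE))
  }
  obj <- function(par) {
    A <- par[1]; m <- par[2]; s <- exp(par[3])
    sum((accuracy - A / (1 + exp(-(snrs - m) / s)))^2)
  }
  init <- c(max(accuracy), stats::median(snrs), log(diff(range(snrs)) / 6))
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  A <- opt$par[1]; m <- opt$par[2]; s <- exp(opt$par[3])
  if (identical(criterion, "half_max")) {
    res <- threshold_result(m, 0.5, "fit", TRUE)
  } else {
    p <- as.numeric(criterion)
    if (p >= A) res <- threshold_result(NA_real_, p, "fit", FALSE)
    else res <- threshold_result(m - s * log(A / p - 1), p, "fit", TRUE)
  }
  attr(res, "fit") <- c(A = A, m = m, s = s)
  res
}

#' Benefit from temporal fine structure
#'
#' Expresses speech reception thresholds relative to the fully vocoded
#' baseline: `benefit(k) = SRT(cutoff = 0) - SRT(cutoff = k)` per noise
#' type, so `benefit(0) = 0` exactly and positive benefits are leftward
#' psychometric shifts (better thresholds) as more low-frequency channels
#' keep intact fine structure.
#'
#' @param srt_table data.frame with columns `cutoff_channel`, `noise`
#'   (character), `srt` (dB); must contain `cutoff_channel == 0` for every
#'   noise type
#' @return the table with an added `benefit` column (dB)
#' @export
tfs_benefit <- function(srt_table) {
  stopifnot(all(c("cutoff_channel", "noise", "srt") %in% names(srt_table)))
  out <- srt_table
  out$benefit <- NA_real_
  for (nz in unique(out$noise)) {
    sel <- out$noise == nz
    base <- out$srt[sel & out$cutoff_channel == 0]
    if (length(base) != 1L)
      stop("missing (or duplicated) cutoff 0 baseline for noise type ", nz)
    out$benefit[sel] <- base - out$srt[sel]
  }
  out
}
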