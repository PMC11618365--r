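test_that("Normal-CDF fit recovers generating parameters", {
  set.seed(101)
  x <- seq(0, 4, length.out = 9)
  k <- stats::rbinom(9, 200, stats::pnorm((x - 2) / 0.5))
  fit <- fit_psychometric(x, k, rep(200, 9))
  expect_true(fit$measurable)
  expect_lt(abs(fit$mu - 2), 0.1)
  expect_lt(abs(fit$sigma - 0.5), 0.1)
  # the probit fit is the ML Normal-CDF fit: check against a direct
  # likelihood maximization (independent route)
  nll <- function(par) {
    p <- stats::pnorm((x - par[1]) / exp(par[2]))
    -sum(stats::dbinom(k, 200, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
  }
  opt <- stats::optim(c(1.5, log(0.4)), nll)
  expect_equal(fit$mu, opt$par[1], tolerance = 1e-3)
  expect_equal(fit$sigma, exp(opt$par[2]), tolerance = 1e-3)
})

test_that("symmetric data give mu at the symmetry point", {
  x <- c(-2, -1, 0, 1, 2) + 7
  k <- c(2, 30, 50, 70, 98)
  fit <- fit_psychometric(x, k, rep(100, 5))
  expect_equal(fit$mu, 7, tolerance = 1e-6)
})

test_that("degenerate psychometric data are flagged, not fit", {
  x <- 1:5
  expect_false(fit_psychometric(x, rep(0, 5), rep(10, 5))$measurable)
  expect_false(fit_psychometric(x, rep(10, 5), rep(10, 5))$measurable)
  # perfect step data: sigma -> 0, flagged
  step <- fit_psychometric(x, c(0, 0, 0, 10, 10), rep(10, 5))
  expect_false(isTRUE(step$measurable) && step$sigma > 1e-3)
  expect_error(fit_psychometric(c(1, 1, 1), c(1, 2, 3), rep(5, 3)),
               "distinct")
})

test_that("threshold criteria map through the inverse Normal CDF", {
  fit <- structure(list(mu = 2, sigma = 0.5, measurable = TRUE),
                   class = "psychometric_fit")
  expect_equal(threshold(fit, 0.707)$threshold,
               2 + 0.5 * stats::qnorm(0.707))
  expect_equal(threshold(fit, 0.5)$threshold, 2)
  expect_equal(threshold(fit, 0.75)$threshold, 2 + 0.5 * stats::qnorm(0.75))
  # interpolation route
  d <- data.frame(x = c(0, 1, 2, 3), p = c(0.4, 0.6, 0.8, 1.0))
  expect_equal(threshold(d, 0.707, "interpolation")$threshold,
               1 + (0.707 - 0.6) / 0.2)
  # flat-at-chance data: unmeasurable
  flat <- data.frame(x = 0:4, p = rep(0.5, 5))
  expect_false(threshold(flat, 0.707, "interpolation")$measurable)
  unfit <- structure(list(mu = NA, sigma = NA, measurable = FALSE),
                     class = "psychometric_fit")
  expect_false(threshold(unfit, 0.707)$measurable)
})

test_that("lateralization judgments count est2 > est1, ties at random", {
  expect_equal(as.numeric(lateralization_judgments(1:10, 1:10 + 0.5)), 1)
  expect_equal(as.numeric(lateralization_judgments(1:10 + 0.5, 1:10)), 0)
  mixed <- lateralization_judgments(c(0, 0, 0, 0), c(1, -1, 2, -3))
  expect_equal(as.numeric(mixed), 0.5)
  # tie policy: long-run rate 0.5
  p_tie <- mean(vapply(1:200, function(s)
    as.numeric(lateralization_judgments(rep(1, 10), rep(1, 10), seed = s)),
    numeric(1)))
  expect_equal(p_tie, 0.5, tolerance = 0.1)
  expect_error(lateralization_judgments(numeric(0), numeric(0)), "empty")
})

test_that("perceptual weights scale shifts by the imposed cue", {
  # linear cue map cue = c * az: weight = c * shift / bias
  cm <- data.frame(azimuth = seq(-90, 90, 5), cue = 3 * seq(-90, 90, 5))
  w <- perceptual_weight(c(0, 10), c(5, 15), 30, cm)
  expect_equal(as.numeric(w), 3 * 5 / 30)
  # no shift -> weight 0
  expect_equal(as.numeric(perceptual_weight(c(0, 10), c(0, 10), 30, cm)), 0)
  # response shift whose mapped cue change equals the bias -> weight 1
  expect_equal(as.numeric(perceptual_weight(0, 10, 30, cm)), 1)
  # rear-hemifield reflection before lookup
  expect_equal(as.numeric(perceptual_weight(0, 170, 30, cm)),
               3 * 10 / 30)
  # invariance under consistent affine reparameterization of azimuth
  cm2 <- data.frame(azimuth = (cm$azimuth - 0) / 2, cue = cm$cue)
  w2 <- perceptual_weight(c(0, 10) / 2, c(5, 15) / 2, 30, cm2)
  expect_equal(as.numeric(w2), as.numeric(w))
  expect_error(perceptual_weight(0, 10, 0, cm), "nonzero")
})

test_that("reflect_to_front folds the rear hemifield", {
  expect_equal(reflect_to_front(c(120, -150, 45, 0, 90, -90)),
               c(60, -30, 45, 0, 90, -90))
})

test_that("SRT fitting finds the half-maximal SNR", {
  snrs <- seq(-15, 15, by = 3)
  acc <- 0.9 / (1 + exp(-(snrs + 3) / 2))
  res <- srt(acc, snrs)
  expect_true(res$measurable)
  expect_equal(res$threshold, -3, tolerance = 0.05)
  # translation equivariance
  res2 <- srt(0.9 / (1 + exp(-(snrs + 1) / 2)), snrs)
  expect_equal(res2$threshold - res$threshold, 2, tolerance = 0.1)
  # flat data: unmeasurable
  expect_false(srt(rep(0.9, 11), snrs)$measurable)
  # fixed criterion above the asymptote: unmeasurable
  expect_false(srt(acc, snrs, criterion = 0.95)$measurable)
  expect_error(srt(c(0.2, 0.8), c(-3, 0)), "4 SNR")
})

test_that("TFS benefit is relative to the fully vocoded baseline", {
  tab <- expand.grid(cutoff_channel = c(0, 8, 16, 24, 32),
                     noise = c("stationary", "modulated"),
                     stringsAsFactors = FALSE)
  tab$srt <- c(-2, -3, -4, -6, -7, -1, -3, -5, -8, -8.5)
  out <- tfs_benefit(tab)
  expect_equal(out$benefit[out$cutoff_channel == 0], c(0, 0))
  expect_equal(out$benefit[out$cutoff_channel == 24 &
                             out$noise == "stationary"], 4)
  # monotone SRTs give monotone benefits
  for (nz in unique(out$noise)) {
    b <- out$benefit[out$noise == nz][order(out$cutoff_channel[out$noise == nz])]
    expect_true(all(diff(b) >= 0))
  }
  expect_error(tfs_benefit(tab[tab$cutoff_channel != 0, ]), "baseline")
})
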