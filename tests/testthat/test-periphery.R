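test_that("CF axis spans the stated range with constant ERB step", {
  cfs <- make_cf_axis(50, 125, 8000)
  expect_length(cfs, 50)
  expect_identical(cfs[1], 125)
  expect_identical(cfs[50], 8000)
  expect_lt(max(abs(diff(diff(erb_number(cfs))))), 1e-9)
  expect_equal(make_cf_axis(2, 125, 16000), c(125, 16000))
})

test_that("fiber table and binomial n follow the published parameters", {
  ft <- fiber_types()
  expect_equal(ft$threshold, c(0, 12, 28))
  expect_equal(ft$dynamic_range, c(20, 40, 80))
  expect_equal(sum(ft$spont_fraction), 1)
  cfg <- periphery_config()
  # n = fraction * 32000 / 50 channels
  expect_equal(unname(cfg$n_per_bin), c(384, 160, 96))
  expect_error(periphery_config(ihc_cutoff = -5), "positive")
})

test_that("gammatone filterbank is linear and band-centered", {
  cfs <- c(500, 1000, 2000, 4000)
  a <- fix_tone(1000, dur = 0.08)
  b <- fix_tone(2000, dur = 0.08)
  sa <- gammatone_subbands(a, cfs)
  sb <- gammatone_subbands(b, cfs)
  ab <- gammatone_subbands(waveform(a$samples + b$samples, a$fs), cfs)
  expect_equal(ab, sa + sb, tolerance = 1e-12)
  # on-CF channel has maximal RMS
  expect_equal(which.max(apply(sa, 1, function(x) sqrt(mean(x^2)))), 2L)
  expect_equal(which.max(apply(sb, 1, function(x) sqrt(mean(x^2)))), 3L)
  expect_error(gammatone_subbands(a, c(500, 11000)), "Nyquist")
})

test_that("impulse response of each channel is the truncated gammatone", {
  fs <- FS_AUDIO
  imp <- waveform(c(1, numeric(round(0.08 * fs) - 1)), fs)
  cf <- 1000
  got <- gammatone_subbands(imp, cf)[1, ]
  t <- (seq_len(round(0.05 * fs)) - 1) / fs
  b <- 1.019 * erb_bandwidth(cf)
  h <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  h <- h / Mod(sum(h * exp(-2i * pi * cf * t)))
  expect_equal(got[seq_along(h)], h, tolerance = 1e-9)
  expect_equal(got[-seq_along(h)], rep(0, length(got) - length(h)),
               tolerance = 1e-12)
})

test_that("IHC stage has unit DC gain and the 7-section rolloff", {
  fs <- FS_AUDIO
  # constant (already non-negative) input is unchanged after settling
  x <- rep(0.01, 4000)
  y <- ihc_lowpass(x, 3000, fs)
  expect_equal(y[2000:4000], rep(0.01, 2001), tolerance = 1e-6)
  # magnitude at the per-section cutoff: 7 sections at -3.01 dB each
  h <- phaselock:::ihc_fir(3000, fs)
  t <- (seq_along(h) - 1) / fs
  mag_fc <- 20 * log10(Mod(sum(h * exp(-2i * pi * 3000 * t))))
  expect_equal(mag_fc, -21.07, tolerance = 0.1)
  # monotone non-increasing magnitude response
  f_grid <- seq(0, 8000, by = 250)
  mags <- vapply(f_grid, function(f)
    Mod(sum(h * exp(-2i * pi * f * t))), numeric(1))
  expect_true(all(diff(mags) < 1e-6))
  # 50 Hz cutoff crushes a 2 kHz carrier to (near) its envelope
  h50 <- phaselock:::ihc_fir(50, fs)
  mag2k <- 20 * log10(Mod(sum(h50 * exp(-2i * pi * 2000 * t))))
  expect_lt(mag2k, -60)
  expect_error(ihc_lowpass(x, 11000, fs), "Nyquist")
})

test_that("rate-level sigmoids span 5-95% over the dynamic range", {
  ft <- fiber_types()
  for (s in 1:3) {
    fb <- ft[s, ]
    amp_at <- function(db) 20e-6 * 10^(db / 20)
    expect_equal(rate_level(amp_at(fb$threshold), fb), 0.05 * 250,
                 tolerance = 1e-6)
    expect_equal(rate_level(amp_at(fb$threshold + fb$dynamic_range), fb),
                 237.5, tolerance = 1e-6)
    # silence floor: below 5% of max
    expect_lt(rate_level(0, fb), 0.05 * 250)
    # monotone in amplitude
    r <- rate_level(seq(0, 0.1, length.out = 50), fb)
    expect_true(all(diff(r) >= 0))
  }
  # high-SR saturates before low-SR at a 30 dB SPL drive
  a30 <- 20e-6 * 10^(30 / 20)
  expect_gt(rate_level(a30, ft[1, ]) / 250, rate_level(a30, ft[3, ]) / 250)
  expect_error(rate_level(-0.1, ft[1, ]), "non-negative")
})

test_that("silence produces near-zero rates through the full pipeline", {
  cfg <- small_cfg()
  r <- periphery_response(waveform(numeric(2000), FS_AUDIO), cfg)
  expect_lt(max(r$rates), 0.05 * 250)
  expect_equal(dim(r$rates), c(20, 1000, 3))
})

test_that("phase locking appears below the cutoff and dies above it", {
  cfg3000 <- small_cfg(3000)
  cfg50 <- small_cfg(50)
  w <- fix_tone(500, dur = 0.1)
  ch <- which.min(abs(cfg3000$cf_axis - 500))
  r_hi <- periphery_response(w, cfg3000)
  r_lo <- periphery_response(w, cfg50)
  # low-spont fibers keep the widest unsaturated range at 60 dB SPL
  vs_hi <- vector_strength(r_hi$rates[ch, , 3], 500, r_hi$fs_out)
  vs_lo <- vector_strength(r_lo$rates[ch, , 3], 500, r_lo$fs_out)
  expect_gt(vs_hi, 0.5)
  expect_lt(vs_lo, 0.05)
  # place profile is preserved despite the cutoff change
  expect_gt(stats::cor(excitation_pattern(r_hi), excitation_pattern(r_lo)),
            0.95)
})

test_that("binaural input yields a response per ear", {
  cfg <- small_cfg()
  b <- impose_itd(fix_tone(500, dur = 0.05), 300e-6, "whole_waveform")
  r <- periphery_response(b, cfg)
  expect_s3_class(r, "binaural_nerve_response")
  expect_s3_class(r$left, "nerve_response")
  expect_equal(dim(r$left$rates), dim(r$right$rates))
})

test_that("spike sampling matches binomial moments and is deterministic", {
  cfg <- periphery_config()
  rate <- 100
  fake <- structure(list(rates = array(rate, dim = c(2, 50000, 3)),
                         cf_axis = cfg$cf_axis[1:2], fs_out = cfg$fs_out,
                         cfg = cfg), class = "nerve_response")
  sp <- sample_spikes(fake, cfg, seed = 5)
  x <- as.vector(sp$counts[, , 1])
  n <- 384; p <- rate / cfg$fs_out
  expect_equal(mean(x), n * p, tolerance = 0.02 * n * p)
  expect_equal(stats::var(x), n * p * (1 - p),
               tolerance = 0.02 * n * p * (1 - p))
  expect_true(all(sp$counts >= 0 & sp$counts <= 384))
  expect_true(is.integer(sp$counts))
  # zero rate -> zero counts, always
  fake0 <- fake; fake0$rates[] <- 0
  expect_true(all(sample_spikes(fake0, cfg, seed = 1)$counts == 0))
  # determinism
  r <- periphery_response(fix_tone(1000, dur = 0.05), small_cfg())
  s1 <- sample_spikes(r, r$cfg, seed = 42)
  s2 <- sample_spikes(r, r$cfg, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts,
                         sample_spikes(r, r$cfg, seed = 43)$counts))
})

test_that("refractory sampling reduces spikes but keeps the response", {
  cfg <- small_cfg()
  r <- periphery_response(fix_tone(500, dur = 0.06), cfg)
  sp_d <- sample_spikes(r, cfg, seed = 1)
  sp_r <- sample_spikes(r, cfg, seed = 2, refractory = TRUE)
  expect_true(all(sp_r$counts >= 0))
  expect_lt(sum(sp_r$counts), sum(sp_d$counts))
  # small n override keeps counts within the overridden bound
  sp_s <- sample_spikes(r, cfg, seed = 3, refractory = TRUE,
                        n_override = c(high = 10, medium = 5, low = 3))
  expect_true(all(sp_s$counts[, , 1] <= 10))
  expect_true(all(sp_s$counts[, , 3] <= 3))
})

test_that("vector strength reproduces the analytic reference values", {
  fs <- 100000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  f <- 100
  expect_lt(vector_strength(rep(5, length(t)), f, fs), 1e-9)
  expect_equal(vector_strength(pmax(sin(2 * pi * f * t), 0), f, fs),
               pi / 4, tolerance = 1e-3)
  expect_equal(vector_strength(1 + cos(2 * pi * f * t), f, fs), 0.5,
               tolerance = 1e-3)
  expect_error(vector_strength(numeric(100), 100, fs), "zero")
  expect_error(vector_strength(c(-1, 1), 100, fs), "non-negative")
})
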