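test_that("frequency-discrimination trial sets obey the sampling law", {
  ts <- freq_discrimination_dataset(500, 0.25, 400, seed = 1)
  expect_true(all(ts$level1 >= 37 & ts$level1 <= 43))
  expect_true(all(ts$level2 >= 37 & ts$level2 <= 43))
  expect_true(all(ts$interval >= 1e-6 & ts$interval <= 1e-1))
  expect_true(all(abs(log2(ts$f2 / ts$f1)) >= 1e-6 - 1e-12))
  expect_true(all(ts$f1 >= 500 * 2^-0.125 & ts$f1 <= 500 * 2^0.125))
  expect_equal(ts$f2, ts$f1 * 2^(ifelse(ts$label, 1, -1) * ts$interval))
  expect_equal(mean(ts$label), 0.5, tolerance = 0.1)
  expect_identical(ts, freq_discrimination_dataset(500, 0.25, 400, seed = 1))
})

test_that("localization grids enumerate speakers and classes", {
  g <- localization_grids()
  expect_equal(nrow(g$speakers), 95)
  expect_equal(nrow(g$classes), 504)
  expect_equal(length(unique(g$classes$azimuth_center)), 72)
  expect_equal(length(unique(g$classes$elevation_center)), 7)
  # azimuth bins partition 360 degrees exactly
  edges <- attr(g, "azimuth_edges")
  expect_equal(diff(range(edges)), 360)
  expect_equal(unique(diff(edges)), 5)
  expect_true(all(g$speakers$azimuth >= -90 & g$speakers$azimuth <= 90))
  expect_true(all(g$speakers$elevation >= 0 & g$speakers$elevation <= 40))
})

test_that("rate-place observer reads the excitation centroid", {
  cfg <- small_cfg()
  obs <- rate_place_observer(cfg)
  sp_lo <- sample_spikes(periphery_response(fix_tone(500, 0.05, 40), cfg),
                         cfg, seed = 1)
  sp_hi <- sample_spikes(periphery_response(fix_tone(1000, 0.05, 40), cfg),
                         cfg, seed = 2)
  expect_true(obs$judge(sp_lo, sp_hi))
  expect_false(obs$judge(sp_hi, sp_lo))
  # identical intervals: judged up about half the time under the tie seed
  p_up <- mean(vapply(1:50, function(s) obs$judge(sp_lo, sp_lo, seed = s),
                      logical(1)))
  expect_gt(p_up, 0.25); expect_lt(p_up, 0.75)
})

test_that("timing observer reads periodicity and falls back gracefully", {
  cfg <- small_cfg(3000)
  sp <- sample_spikes(periphery_response(fix_tone(500, 0.1, 40), cfg),
                      cfg, seed = 3)
  est <- phaselock:::dominant_periodicity(sp, 300, 900)
  expect_equal(est, 500, tolerance = 1 / 0.1)  # within one DFT bin
  # above the phase-locking limit no peak survives -> NA triggers fallback
  cfg50 <- small_cfg(50)
  sp50 <- sample_spikes(periphery_response(fix_tone(500, 0.1, 40), cfg50),
                        cfg50, seed = 3)
  expect_true(is.na(phaselock:::dominant_periodicity(sp50, 300, 900)))
})

test_that("large intervals are judged correctly by both observers", {
  cfg <- small_cfg(3000)
  rp <- rate_place_observer(cfg)
  tm <- timing_observer(cfg, band = c(300, 900))
  correct_rp <- 0; correct_tm <- 0
  n <- 10
  set.seed(9)
  for (i in seq_len(n)) {
    up <- i %% 2 == 0
    f1 <- 500; f2 <- f1 * 2^(if (up) 0.1 else -0.1)
    sp1 <- sample_spikes(periphery_response(
      fix_tone(f1, 0.05, runif(1, 37, 43)), cfg), cfg, seed = i)
    sp2 <- sample_spikes(periphery_response(
      fix_tone(f2, 0.05, runif(1, 37, 43)), cfg), cfg, seed = 100 + i)
    correct_rp <- correct_rp + (rp$judge(sp1, sp2, seed = i) == up)
    correct_tm <- correct_tm + (tm$judge(sp1, sp2, seed = i) == up)
  }
  expect_gte(correct_rp / n, 0.9)
  expect_gte(correct_tm / n, 0.9)
})

test_that("crosscorr observer recovers an imposed whole-waveform ITD", {
  cfg <- small_cfg(3000)
  obs <- crosscorr_observer(cfg)
  nz <- synth_noise(0.12, FS_AUDIO, 60, seed = 6, band = c(200, 1200))
  b <- impose_itd(nz, 300e-6, "whole_waveform")
  nr <- periphery_response(b, cfg)
  ests <- vapply(1:3, function(k) {
    spl <- sample_spikes(nr$left, cfg, seed = k)
    spr <- sample_spikes(nr$right, cfg, seed = 50 + k)
    obs$estimate(spl, spr) * 1e6
  }, numeric(1))
  expect_equal(mean(ests), 300, tolerance = 100)
  # zero ITD: near-zero estimate
  b0 <- impose_itd(nz, 0, "whole_waveform")
  nr0 <- periphery_response(b0, cfg)
  e0 <- obs$estimate(sample_spikes(nr0$left, cfg, seed = 1),
                     sample_spikes(nr0$right, cfg, seed = 2)) * 1e6
  expect_lt(abs(e0), 100)
})

test_that("synthetic accuracy generator drives the SRT harness", {
  gen <- synthetic_accuracy_generator(benefit_at_32 = 5)
  out <- run_vocoding_srt(gen, cutoffs = c(0, 16, 32))
  expect_equal(out$benefit[out$cutoff_channel == 0],
               rep(0, sum(out$cutoff_channel == 0)))
  got32 <- out$benefit[out$cutoff_channel == 32]
  expect_equal(got32, rep(5, 2), tolerance = 0.3)
  got16 <- out$benefit[out$cutoff_channel == 16]
  expect_equal(got16, rep(2.5, 2), tolerance = 0.3)
  # precomputed-table route agrees with the function route
  snrs <- seq(-15, 15, by = 3)
  tab <- expand.grid(cutoff_channel = c(0, 16, 32),
                     noise = c("stationary", "modulated"),
                     snr = snrs, stringsAsFactors = FALSE)
  tab$accuracy <- mapply(function(k, s) gen(k, s), tab$cutoff_channel,
                         tab$snr)
  out2 <- run_vocoding_srt(tab, cutoffs = c(0, 16, 32))
  expect_equal(out2$srt, out$srt, tolerance = 1e-6)
})

test_that("SRT grid respects the printed SNR range and steps", {
  gen <- synthetic_accuracy_generator(benefit_at_32 = 3)
  # default grid: -15..+15 dB in 3 dB steps, cutoffs 0..32 step 4
  out <- run_vocoding_srt(gen)
  expect_setequal(unique(out$cutoff_channel), seq(0, 32, by = 4))
  expect_setequal(unique(out$noise), c("stationary", "modulated"))
  expect_true(all(out$srt >= -15 & out$srt <= 15))
})
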