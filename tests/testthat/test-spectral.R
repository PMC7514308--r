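test_that("calibrated tone PSD recovers the tone's mean-square pressure", {
  # 125 Hz sits exactly on a bin center for nfft 1024 at 8 kHz
  a <- tone_audio(freq = 125, spl_db = 120, seconds = 8)
  spec <- welch_spectrogram(a, nfft = 1024, seg_seconds = 1, avg_seconds = 8)
  expect_equal(ncol(spec$power), 1L)
  # band-integrate across the leakage width of the peak
  spl <- band_spl(spec, c(100, 150))
  expect_equal(as.numeric(spl), 120, tolerance = 0.1)
})

test_that("white-noise PSD satisfies the Parseval/variance identity", {
  a <- noise_audio(spl_db = 110, seconds = 80, seed = 2)
  spec <- welch_spectrogram(a, nfft = 1024, seg_seconds = 1, avg_seconds = 80)
  p <- pressure <- a$samples * 10^(-a$sensitivity_db / 20)
  total <- sum(spec$power[, 1]) * spec$df
  expect_equal(total, mean(p^2), tolerance = 0.05)
  # flat spectrum: central bins near the theoretical density
  dens <- mean(p^2) / (a$rate / 2)
  mid <- spec$power[spec$freqs > 500 & spec$freqs < 3500, 1]
  expect_equal(mean(mid), dens, tolerance = 0.05)
})

test_that("band SPL of an in-band tone matches the analytic level", {
  a <- tone_audio(freq = 1000, spl_db = 113, seconds = 6)
  spec <- welch_spectrogram(a, nfft = 1024, seg_seconds = 1, avg_seconds = 6)
  expect_equal(as.numeric(band_spl(spec, c(500, 2500))), 113, tolerance = 0.2)
  # out-of-band tone: the chorus band only sees the (near-zero) floor
  expect_lt(as.numeric(band_spl(spec, c(3000, 3900))), 60)
  expect_error(band_spl(spec, c(2500, 500)), "f_lo < f_hi")
  expect_error(band_spl(spec, c(4100, 4200)), "no frequency bin")
})

test_that("doubling pressure raises every SPL by 6.02 dB exactly", {
  a <- noise_audio(spl_db = 105, seconds = 10, seed = 9)
  b <- calibrated_audio(a$samples * 2, a$rate, a$sensitivity_db)
  sa <- band_spl(welch_spectrogram(a, avg_seconds = 10), c(500, 2500))
  sb <- band_spl(welch_spectrogram(b, avg_seconds = 10), c(500, 2500))
  expect_equal(as.numeric(sb - sa), rep(20 * log10(2), length(sa)),
               tolerance = 1e-9)
})

test_that("digital silence is floored and flagged, not -Inf", {
  a <- calibrated_audio(rep(0, 8000), 8000)
  spec <- welch_spectrogram(a, avg_seconds = 1)
  expect_true(all(attr(spec_db(spec), "silent")))
  s <- band_spl(spec, c(500, 2500))
  expect_true(all(is.finite(s)))
  expect_true(all(attr(s, "silent")))
})

test_that("SPL statistics use linear-mean RMS and dB order statistics", {
  st <- spl_statistics(c(100, 120))
  expect_equal(st$mean_rms, 10 * log10((1e10 + 1e12) / 2), tolerance = 1e-9)
  expect_equal(st$median, 110)
  cst <- spl_statistics(rep(93.5, 10))
  expect_equal(cst$mean_rms, 93.5, tolerance = 1e-9)
  expect_equal(cst$median, 93.5)
  expect_equal(cst$p95, 93.5)
  set.seed(2); x <- rnorm(500, 110, 5)
  st2 <- spl_statistics(x)
  expect_gte(st2$p95, st2$median)
  expect_gte(st2$median, min(x))
  expect_error(spl_statistics(numeric(0)), "empty")
})

test_that("hourly aggregation averages power, not decibels, by default", {
  spl <- c(100, 120, 90, 90)
  clock <- c(3, 3, 12, 12)
  h <- hourly_mean_spl(spl, clock)
  expect_equal(h$mean_spl[h$hour == 3], 10 * log10((1e10 + 1e12) / 2))
  expect_equal(h$mean_spl[h$hour == 12], 90)
  hdb <- hourly_mean_spl(spl, clock, stat = "db")
  expect_equal(hdb$mean_spl[hdb$hour == 3], 110)
  expect_error(hourly_mean_spl(spl, 1:3), "lengths differ")
})

test_that("hourly SPL of a diel scene peaks in the programmed chorus hours", {
  sc <- cached_scene("preset_a_like",
                     scene_config(seed = 55, sediment = list(rate_per_hour = 2)))
  spec <- welch_spectrogram(sc$audio, nfft = 1024, seg_seconds = 1,
                            avg_seconds = sc$config$seconds_per_hour)
  spl <- band_spl(spec, c(500, 2500))
  clock <- floor(spec$times / sc$config$seconds_per_hour)
  h <- hourly_mean_spl(spl, clock)
  chorus_hours <- which(sc$truth$chorus == 1) - 1
  top <- h$hour[order(h$mean_spl, decreasing = TRUE)][seq_along(chorus_hours)]
  expect_setequal(top, chorus_hours)
})
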