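test_that("ACI of a constant tone is zero; intermittent sound raises it", {
  tone <- tone_audio(1000, 110, seconds = 12)
  v <- aci(tone, cluster_s = 12)
  expect_lt(v$value, 1e-6)
  # amplitude-modulated pulse train vs steady tone of equal power
  rate <- 8000; t <- (0:(12 * rate - 1)) / rate
  gate <- as.numeric((t %% 0.5) < 0.1)
  pulses <- sin(2 * pi * 1000 * t) * gate
  pulses <- pulses / sqrt(mean(pulses^2))
  steady <- sin(2 * pi * 1000 * t); steady <- steady / sqrt(mean(steady^2))
  a1 <- aci(calibrated_audio(pulses * 1e-3, rate), cluster_s = 12)
  a2 <- aci(calibrated_audio(steady * 1e-3, rate), cluster_s = 12)
  expect_gt(a1$value, a2$value)
})

test_that("ACI alternating-amplitude closed form: aci_j -> 2 - 2/K", {
  # construct a spectrogram-level check through a gated bin: frames of
  # amplitude a, 0, a, 0 ... in one bin give sum|diff|/sum = 2 - 2/K
  # for K frames starting and ending on 'a'.  Use frame-synchronous
  # gating: nfft 2048 at 8 kHz -> 0.256 s frames.
  rate <- 8000; nfft <- 2048
  K <- 40                           # even: a,0,...,a,0
  n <- K * nfft
  frame_id <- rep(seq_len(K) - 1, each = nfft)
  x <- sin(2 * pi * 1000 * (0:(n - 1)) / rate) * (frame_id %% 2 == 0)
  # restrict to the tone's own bin (1000 Hz is a bin center)
  v <- aci(calibrated_audio(x * 1e-3, rate), f_lo = 999, f_hi = 1001,
           nfft = nfft, cluster_s = n / rate)
  expect_equal(v$meta$bins, 1L)
  expect_equal(v$value, 2 - 2 / K, tolerance = 1e-6)
})

test_that("ACI is invariant to global amplitude scaling", {
  sc <- quiet_scene()
  a <- calibrated_audio(sc$audio$samples[1:80000], 8000)
  b <- calibrated_audio(a$samples * 7.3, 8000)
  expect_equal(aci(a, cluster_s = 10)$value, aci(b, cluster_s = 10)$value,
               tolerance = 1e-9)
})

test_that("ADI hits its extremes: single band 0, uniform occupancy ln 17", {
  # energy confined to one 200-Hz band
  one <- tone_audio(300, 115, seconds = 6)
  expect_equal(adi(one)$value, 0, tolerance = 1e-9)
  # white noise fills every band above the -50 dB threshold equally
  v <- adi(noise_audio(110, seconds = 20, seed = 5))
  expect_equal(v$value, log(17), tolerance = 1e-3)
  expect_lte(v$value, log(17) + 1e-12)
})

test_that("ADI of silence is zero and flagged", {
  v <- adi(calibrated_audio(rep(0, 16000), 8000))
  expect_equal(v$value, 0)
  expect_true(attr(v, "silent"))
})

test_that("ADI is invariant to global scaling (threshold is relative)", {
  sc <- quiet_scene()
  a <- calibrated_audio(sc$audio$samples[1:80000], 8000)
  b <- calibrated_audio(a$samples * 0.05, 8000)
  expect_equal(adi(a)$value, adi(b)$value, tolerance = 1e-9)
})

test_that("BI: flat in-band spectrum scores 0; a tone adds ~height x width", {
  # an exactly flat spectrum: one impulse per FFT frame, |FFT| constant
  rate <- 8000
  imp <- rep(c(1, rep(0, 2047)), 40)
  v0 <- bi(calibrated_audio(imp, rate))
  expect_lt(v0$value, 1e-6)
  # finite white noise is only statistically flat: ~2 dB/bin of sampling
  # wobble between the mean spectrum and its minimum
  n <- noise_audio(110, seconds = 20, seed = 7)
  vn <- bi(n)
  expect_lt(vn$value / vn$meta$bins, 3.5)
  # add a strong tone 20 dB above the floor: BI grows by about 20 x width
  t <- (0:(20 * rate - 1)) / rate
  p <- n$samples + sin(2 * pi * 1000 * t) * sd(n$samples) * 12
  v1 <- bi(calibrated_audio(p, rate))
  expect_gt(v1$value, vn$value + 40)
  expect_error(bi(n, f_lo = 4100, f_hi = 4200), "empty")
})

test_that("chorus energizing the band raises BI and ADI over a quiet scene", {
  quiet <- quiet_scene()
  loud <- cached_scene("chorus_hour",
                       scene_config(hours = 2, seed = 404,
                                    chorus = list(intensity = 1,
                                                  dawn_hours = 0:1)))
  qa <- calibrated_audio(quiet$audio$samples[1:80000], 8000)
  la <- calibrated_audio(loud$audio$samples[1:80000], 8000)
  expect_gt(bi(la)$value, bi(qa)$value)
  expect_gte(adi(la)$value, adi(qa)$value)
})

test_that("indices are deterministic and non-negative", {
  sc <- quiet_scene()
  a <- calibrated_audio(sc$audio$samples[1:40000], 8000)
  for (f in list(function() aci(a, cluster_s = 5), function() adi(a),
                 function() bi(a))) {
    v1 <- f()$value; v2 <- f()$value
    expect_identical(v1, v2)
    expect_gte(v1, 0)
  }
})
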