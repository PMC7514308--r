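# Shared fixtures built in code.  Scenes are rendered lazily and cached
# for the session so several test files can reuse them.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, cfg) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- render_scene(cfg)
  .scene_cache[[key]]
}

# a short quiet scene: background only
quiet_scene <- function(hours = 2, seed = 404) {
  cached_scene(sprintf("quiet_%d_%d", hours, seed),
               scene_config(hours = hours, seed = seed,
                            chorus = list(intensity = 0)))
}

# tone audio helper: calibrated sinusoid at given SPL (dB re 1 uPa)
tone_audio <- function(freq, spl_db, rate = 8000, seconds = 4,
                       sensitivity_db = -164.5) {
  amp_upa <- 10^(spl_db / 20) * sqrt(2)   # peak from rms
  t <- (0:(round(rate * seconds) - 1)) / rate
  p <- amp_upa * sin(2 * pi * freq * t)
  calibrated_audio(p * 10^(sensitivity_db / 20), rate, sensitivity_db)
}

# white-noise audio at a given full-band SPL
noise_audio <- function(spl_db, rate = 8000, seconds = 4, seed = 1,
                        sensitivity_db = -164.5) {
  set.seed(seed)
  p <- stats::rnorm(round(rate * seconds))
  p <- p / sqrt(mean(p^2)) * 10^(spl_db / 20)
  calibrated_audio(p * 10^(sensitivity_db / 20), rate, sensitivity_db)
}
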