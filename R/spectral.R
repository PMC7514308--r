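#' Calibrated hydrophone audio
#'
#' Couples full-scale PCM samples with the sample rate and the
#' end-to-end system sensitivity, the single number (dB re 1 uPa) that
#' maps digital full scale to absolute sound pressure.  A recorder whose
#' sensitivity is -164.5 dB re 1 uPa clips at 164.5 dB re 1 uPa, so
#' pressure in uPa is `samples * 10^(-sensitivity/20)`.
#'
#' @param samples numeric vector, full-scale `[-1, 1]`.
#' @param rate sample rate, Hz.
#' @param sensitivity_db end-to-end sensitivity, dB re 1 uPa (negative).
#' @return Object of class `"calibrated_audio"`.
#' @export
calibrated_audio <- function(samples, rate, sensitivity_db = -164.5) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive number", call. = FALSE)
  if (!is.finite(sensitivity_db))
    stop("`sensitivity_db` must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate,
                 sensitivity_db = sensitivity_db),
            class = "calibrated_audio")
}

#' @export
print.calibrated_audio <- function(x, ...) {
  cat(sprintf("calibrated_audio: %d samples @ %g Hz (%.2f s), sensitivity %.1f dB re 1 uPa\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              x$sensitivity_db))
  invisible(x)
}

# absolute pressure series in uPa
pressure <- function(audio) {
  audio$samples * 10^(-audio$sensitivity_db / 20)
}

.window_fn <- function(name, n) {
  k <- seq_len(n) - 1
  switch(name,
         hann    = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         rect    = rep(1, n),
         stop("unknown window: ", name, call. = FALSE))
}

# one-sided Welch PSD of a numeric block: units x^2/Hz
.welch_psd <- function(x, rate, nfft, window = "hann", overlap = 0.5) {
  w <- .window_fn(window, nfft)
  hop <- max(1L, floor(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  nb <- nfft %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    X <- stats::fft(x[s:(s + nfft - 1L)] * w)[seq_len(nb)]
    acc <- acc + Re(X * Conj(X))
  }
  psd <- acc / length(starts) / (rate * sum(w^2))
  psd[2:(nb - 1L)] <- 2 * psd[2:(nb - 1L)]  # one-sided, keep DC and Nyquist
  psd
}

#' Calibrated Welch spectrogram
#'
#' Computes a power spectral density per `seg_seconds` segment (Welch
#' average of `nfft`-point Hann-windowed frames with 50% overlap inside
#' the segment) and then averages the linear PSD arithmetically over
#' `avg_seconds` blocks.  The defaults (nfft = 1024, 1-s segments
#' averaged to 60-s resolution) match long-term soundscape practice.
#' Calibration is applied through the audio's end-to-end sensitivity so
#' power is in uPa^2/Hz.
#'
#' @param audio a [calibrated_audio()].
#' @param nfft FFT length (must fit inside one segment).
#' @param seg_seconds Welch segment length, s.
#' @param avg_seconds output time resolution, s (trailing partial block
#'   is kept if it holds at least one segment).
#' @param window `"hann"` (default), `"hamming"` or `"rect"`.
#' @param overlap frame overlap fraction inside a segment (default 0.5).
#' @return Object of class `"spectrogram_matrix"`: `times` (block
#'   centers, s), `freqs` (bin centers, Hz), `power` (matrix
#'   freq x time, uPa^2/Hz), `df`, `rate`, `nfft`.
#' @export
welch_spectrogram <- function(audio, nfft = 1024L, seg_seconds = 1,
                              avg_seconds = 60, window = "hann",
                              overlap = 0.5) {
  stopifnot(inherits(audio, "calibrated_audio"))
  rate <- audio$rate
  seg_len <- round(seg_seconds * rate)
  if (nfft > seg_len)
    stop("`nfft` must not exceed the segment length in samples", call. = FALSE)
  p <- pressure(audio)
  if (length(p) < seg_len)
    stop("audio shorter than one segment", call. = FALSE)
  n_seg <- length(p) %/% seg_len
  nb <- nfft %/% 2L + 1L
  seg_psd <- matrix(0, nb, n_seg)
  for (i in seq_len(n_seg)) {
    blk <- p[((i - 1L) * seg_len + 1L):(i * seg_len)]
    seg_psd[, i] <- .welch_psd(blk, rate, nfft, window, overlap)
  }
  per_blk <- max(1L, round(avg_seconds / seg_seconds))
  blk_id <- (seq_len(n_seg) - 1L) %/% per_blk
  ids <- unique(blk_id)
  power <- vapply(ids, function(b)
    rowMeans(seg_psd[, blk_id == b, drop = FALSE]), numeric(nb))
  power <- matrix(power, nrow = nb)
  times <- vapply(ids, function(b) {
    segs <- which(blk_id == b)
    mean((segs - 0.5) * seg_seconds)
  }, numeric(1))
  structure(list(times = times,
                 freqs = (seq_len(nb) - 1L) * rate / nfft,
                 power = power,
                 df = rate / nfft, rate = rate, nfft = as.integer(nfft)),
            class = "spectrogram_matrix")
}

#' @export
print.spectrogram_matrix <- function(x, ...) {
  cat(sprintf("spectrogram_matrix: %d freq bins (df = %.2f Hz) x %d windows, %g Hz\n",
              length(x$freqs), x$df, length(x$times), x$rate))
  invisible(x)
}

#' dB view of a spectrogram
#'
#' `10 log10(power)` in dB re 1 uPa^2/Hz.  Zero-power cells (digital
#' silence) are floored at `floor_db` and flagged via the `"silent"`
#' attribute.
#'
#' @param spec a [welch_spectrogram()] result.
#' @param floor_db floor for zero power (default -300).
#' @return Matrix of dB values with attribute `silent`.
#' @export
spec_db <- function(spec, floor_db = -300) {
  silent <- spec$power <= 0
  out <- matrix(floor_db, nrow(spec$power), ncol(spec$power))
  out[!silent] <- 10 * log10(spec$power[!silent])
  out[out < floor_db] <- floor_db
  attr(out, "silent") <- silent
  out
}

#' Band sound pressure level series
#'
#' Integrates the calibrated PSD over the bins whose center frequencies
#' fall inside `band` (inclusive on both edges) and converts to dB:
#' `SPL = 10 log10(sum(PSD) * df)`, dB re 1 uPa, one value per
#' spectrogram time window.
#'
#' @param spec a [welch_spectrogram()] result.
#' @param band numeric length-2, `c(f_lo, f_hi)` Hz.
#' @param floor_db value reported for silent windows (default -300),
#'   flagged via the `"silent"` attribute.
#' @return Numeric SPL series (dB re 1 uPa) with attribute `silent`.
#' @export
band_spl <- function(spec, band, floor_db = -300) {
  stopifnot(inherits(spec, "spectrogram_matrix"))
  if (length(band) != 2L || band[1] >= band[2])
    stop("`band` must be c(f_lo, f_hi) with f_lo < f_hi", call. = FALSE)
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(sel))
    stop(sprintf("no frequency bin inside band %g-%g Hz", band[1], band[2]),
         call. = FALSE)
  bp <- colSums(spec$power[sel, , drop = FALSE]) * spec$df
  silent <- bp <= 0
  out <- ifelse(silent, floor_db, 10 * log10(pmax(bp, 1e-300)))
  attr(out, "silent") <- silent
  out
}

#' Summary statistics of an SPL series
#'
#' The mean is computed in the RMS sense - average of linear power,
#' converted back to dB - while the median and the 95th percentile are
#' order statistics of the dB values themselves.
#'
#' @param series numeric SPL values, dB.
#' @param band optional band label, `c(f_lo, f_hi)`.
#' @return Object of class `"band_spl_stats"`: `mean_rms`, `median`,
#'   `p95` (dB) plus the input series.
#' @export
spl_statistics <- function(series, band = NULL) {
  x <- as.numeric(series)
  if (!length(x)) stop("empty SPL series", call. = FALSE)
  structure(list(band = band,
                 mean_rms = 10 * log10(mean(10^(x / 10))),
                 median = stats::median(x),
                 p95 = as.numeric(stats::quantile(x, 0.95)),
                 hourly_series = x),
            class = "band_spl_stats")
}

#' @export
print.band_spl_stats <- function(x, ...) {
  lab <- if (is.null(x$band)) "" else sprintf(" [%g-%g Hz]", x$band[1], x$band[2])
  cat(sprintf("band SPL%s: mean (RMS) %.2f dB, median %.2f dB, 95th pct %.2f dB (n = %d)\n",
              lab, x$mean_rms, x$median, x$p95, length(x$hourly_series)))
  invisible(x)
}

#' Hourly mean sound pressure level
#'
#' Aggregates an SPL series by clock hour.  By default the mean within
#' an hour is taken on linear power and converted back to dB (RMS
#' sense); `stat = "db"` averages the dB values directly.  The standard
#' deviation is always that of the dB values.
#'
#' @param series numeric SPL values, dB.
#' @param clock integer clock hour (0-23) per value.
#' @param stat `"rms"` (default) or `"db"`.
#' @return Data frame: `hour`, `mean_spl`, `sd_spl`, `n`.
#' @export
hourly_mean_spl <- function(series, clock, stat = c("rms", "db")) {
  stat <- match.arg(stat)
  if (length(series) != length(clock))
    stop("`series` and `clock` lengths differ", call. = FALSE)
  hours <- sort(unique(as.integer(clock)))
  out <- lapply(hours, function(h) {
    v <- series[clock == h]
    m <- if (stat == "rms") 10 * log10(mean(10^(v / 10))) else mean(v)
    data.frame(hour = h, mean_spl = m,
               sd_spl = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, out)
}
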