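# Short-time amplitude spectrogram used by the ecoacoustic indices:
# Hamming window, no overlap by default (the convention of the classic
# index implementations), linear magnitude, uncalibrated (all three
# indices are scale-free).
.amp_spectrogram <- function(audio, nfft = 2048L, window = "hamming",
                             overlap = 0) {
  x <- if (inherits(audio, "calibrated_audio")) audio$samples else as.numeric(audio)
  rate <- if (inherits(audio, "calibrated_audio")) audio$rate else
    stop("supply a calibrated_audio (rate needed)", call. = FALSE)
  w <- .window_fn(window, nfft)
  hop <- max(1L, floor(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  if (!length(starts)) stop("audio shorter than one FFT frame", call. = FALSE)
  nb <- nfft %/% 2L + 1L
  amp <- vapply(starts, function(s)
    Mod(stats::fft(x[s:(s + nfft - 1L)] * w)[seq_len(nb)]), numeric(nb))
  amp <- matrix(amp, nrow = nb)
  list(amp = amp, freqs = (seq_len(nb) - 1L) * rate / nfft,
       frame_s = hop / rate, rate = rate)
}

#' Acoustic complexity index (ACI)
#'
#' Measures intensity variability between successive spectrogram frames:
#' within each frequency bin of the analysis band and each temporal
#' cluster, the sum of absolute intensity differences between adjacent
#' frames divided by the total intensity, summed over bins and clusters.
#' Quasi-steady sounds (vessel tonals, flat noise) contribute little;
#' intermittent biological sound raises the index.  The ratio form makes
#' ACI invariant to global amplitude scaling.
#'
#' @param audio a [calibrated_audio()].
#' @param f_lo,f_hi analysis band, Hz (defaults 10-3500).
#' @param nfft FFT size (default 2048), no overlap, Hamming window.
#' @param cluster_s cluster length in seconds (default 60); the index is
#'   summed over complete clusters.  For compressed synthetic scenes use
#'   the scene's hour length to treat each hour as one cluster.
#' @return Object of class `"index_value"` (name `"ACI"`).
#' @export
aci <- function(audio, f_lo = 10, f_hi = 3500, nfft = 2048L,
                cluster_s = 60) {
  sg <- .amp_spectrogram(audio, nfft)
  sel <- sg$freqs >= f_lo & sg$freqs <= f_hi
  if (!any(sel)) stop("empty analysis band", call. = FALSE)
  A <- sg$amp[sel, , drop = FALSE]
  # intensities more than 120 dB below the spectrogram peak are beyond
  # any PCM dynamic range: treat as silence so float roundoff in the
  # leakage floor of a perfectly steady tone does not register as
  # intensity variation
  A[A < max(A) * 1e-6] <- 0
  frames_per_cluster <- max(2L, floor(cluster_s / sg$frame_s))
  n_cl <- ncol(A) %/% frames_per_cluster
  if (n_cl < 1L)
    stop("audio shorter than one ACI cluster", call. = FALSE)
  total <- 0
  for (k in seq_len(n_cl)) {
    cols <- ((k - 1L) * frames_per_cluster + 1L):(k * frames_per_cluster)
    I <- A[, cols, drop = FALSE]
    num <- rowSums(abs(I[, -1, drop = FALSE] - I[, -ncol(I), drop = FALSE]))
    den <- rowSums(I)
    r <- ifelse(den > 0, num / den, 0)  # silent bins contribute 0
    total <- total + sum(r)
  }
  .index_value("ACI", total, clusters = n_cl, bins = sum(sel))
}

#' Acoustic diversity index (ADI)
#'
#' Shannon diversity of spectral occupancy: the dB spectrogram is
#' referenced to its own maximum, the band below `max_freq` is split
#' into `band_width`-Hz bands (any remainder above the last full band is
#' discarded - 17 bands of 200 Hz below 3500 Hz), the fraction of cells
#' at or above `threshold_db` is taken per band, and the Shannon index
#' is computed over the normalized fractions.  Ranges from 0 (all
#' occupancy in one band) to `ln(n_bands)` (all bands equally occupied).
#'
#' @param audio a [calibrated_audio()].
#' @param max_freq top of the analysis range, Hz (default 3500).
#' @param band_width band width, Hz (default 200).
#' @param threshold_db occupancy threshold relative to the spectrogram
#'   maximum, dB (default -50).
#' @param nfft FFT size (default 2048).
#' @return Object of class `"index_value"` (name `"ADI"`); attribute
#'   `silent` is `TRUE` when no cell reaches the threshold.
#' @export
adi <- function(audio, max_freq = 3500, band_width = 200,
                threshold_db = -50, nfft = 2048L) {
  if (threshold_db >= 0) stop("`threshold_db` must be negative", call. = FALSE)
  sg <- .amp_spectrogram(audio, nfft)
  if (max_freq > sg$rate / 2)
    stop("`max_freq` exceeds the Nyquist frequency", call. = FALSE)
  n_bands <- floor(max_freq / band_width)
  if (n_bands < 1L) stop("no full band below `max_freq`", call. = FALSE)
  amp <- sg$amp
  ref <- max(amp)
  if (ref <= 0) {
    out <- .index_value("ADI", 0, bands = n_bands)
    attr(out, "silent") <- TRUE
    return(out)
  }
  lev <- 20 * log10(pmax(amp / ref, 1e-300))
  p <- vapply(seq_len(n_bands), function(b) {
    sel <- sg$freqs >= (b - 1) * band_width & sg$freqs < b * band_width
    mean(lev[sel, , drop = FALSE] >= threshold_db)
  }, numeric(1))
  tot <- sum(p)
  if (tot <= 0) {
    out <- .index_value("ADI", 0, bands = n_bands)
    attr(out, "silent") <- TRUE
    return(out)
  }
  q <- p / tot
  q <- q[q > 0]
  .index_value("ADI", -sum(q * log(q)), bands = n_bands)
}

#' Bioacoustic index (BI)
#'
#' Area under the mean dB spectrum inside the biophony band, measured
#' above the band's own minimum: the frame-averaged dB spectrum is
#' restricted to `[f_lo, f_hi]`, offset by its minimum, and summed in
#' single-bin units.  A spectrally flat band scores 0; in-band energy
#' concentrations raise the index.
#'
#' @param audio a [calibrated_audio()].
#' @param f_lo,f_hi analysis band, Hz (defaults 10-3500).
#' @param nfft FFT size (default 2048).
#' @return Object of class `"index_value"` (name `"BI"`).
#' @export
bi <- function(audio, f_lo = 10, f_hi = 3500, nfft = 2048L) {
  sg <- .amp_spectrogram(audio, nfft)
  sel <- sg$freqs >= f_lo & sg$freqs <= f_hi
  if (!any(sel)) stop("empty analysis band", call. = FALSE)
  spec_db <- rowMeans(20 * log10(pmax(sg$amp[sel, , drop = FALSE], 1e-300)))
  .index_value("BI", sum(spec_db - min(spec_db)), bins = sum(sel))
}

.index_value <- function(name, value, ...) {
  structure(list(name = name, value = value, meta = list(...)),
            class = "index_value")
}

#' @export
print.index_value <- function(x, ...) {
  cat(sprintf("%s = %.4f\n", x$name, x$value))
  invisible(x)
}

#' @export
as.numeric.index_value <- function(x, ...) x$value
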