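#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the formats passive-acoustic recorders
#' produce: integer PCM at 16 or 24 bit (format tag 1) and IEEE float 32
#' bit (format tag 3), any sample rate, any channel count.  Samples are
#' returned normalized to `[-1, 1)` full scale.
#'
#' @param path file path.
#' @param channel which channel to return, or `"all"` for a matrix with
#'   one column per channel.  Default 1.
#' @return List with `samples` (numeric vector, or matrix for
#'   `channel = "all"`), `rate` (Hz), `bits`, `channels`.
#' @export
read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        tag      = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))  # skip, chunks are padded
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt or data chunk in ", path, call. = FALSE)
  bytes <- fmt$bits / 8
  n <- floor(length(data_raw) / bytes)
  x <- if (fmt$tag == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n, size = 4, endian = "little")
  } else if (fmt$tag == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$tag == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    (v - ifelse(v >= 8388608, 16777216, 0)) / 8388608
  } else {
    stop(sprintf("unsupported WAV format: tag %d, %d bit", fmt$tag, fmt$bits),
         call. = FALSE)
  }
  nch <- fmt$channels
  if (nch > 1L) {
    x <- matrix(x, nrow = nch)  # interleaved
    x <- if (identical(channel, "all")) t(x) else x[channel, ]
  }
  list(samples = x, rate = fmt$rate, bits = fmt$bits, channels = nch)
}

#' Write a PCM WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, full-scale `[-1, 1)`; values outside are clipped.
#' @param rate sample rate, Hz.
#' @param path output file.
#' @param bits 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16L) {
  if (!bits %in% c(16L, 24L)) stop("`bits` must be 16 or 24", call. = FALSE)
  x <- if (is.matrix(samples)) as.numeric(t(samples)) else as.numeric(samples)
  nch <- if (is.matrix(samples)) ncol(samples) else 1L
  full <- 2^(bits - 1)
  x <- pmin(pmax(round(x * full), -full), full - 1)
  bytes <- bits / 8
  data_sz <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, nch)), con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * nch * bytes), con, 4, endian = "little")
  writeBin(as.integer(c(nch * bytes, bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(x), con, size = 2, endian = "little")
  } else {
    v <- as.integer(x %% 16777216)
    raw3 <- as.raw(rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L))
    writeBin(raw3, con)
  }
  invisible(path)
}
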