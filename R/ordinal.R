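#' Ordinal analysis configuration
#'
#' Bundles the two Bandt-Pompe parameters: the embedding dimension `d`
#' (number of samples per ordinal vector, hence `d!` accessible patterns)
#' and the embedding delay `tau` (spacing, in samples, between the values
#' of a vector).  Bandt and Pompe recommend `d` between 3 and 7 with
#' `tau = 1`; the package default is `d = 6`, `tau = 1`, the configuration
#' used throughout the chorus-detection pipeline.
#'
#' @param d integer embedding dimension, `d >= 2`.
#' @param tau integer embedding delay in samples, `tau >= 1`.
#' @return An object of class `"ordinal_config"`: a list with elements
#'   `d` and `tau`.
#' @examples
#' ordinal_config()        # d = 6, tau = 1
#' ordinal_config(4, 1)
#' @export
ordinal_config <- function(d = 6L, tau = 1L) {
  d <- as.integer(d); tau <- as.integer(tau)
  if (length(d) != 1L || is.na(d) || d < 2L)
    stop("`d` must be a single integer >= 2", call. = FALSE)
  if (length(tau) != 1L || is.na(tau) || tau < 1L)
    stop("`tau` must be a single integer >= 1", call. = FALSE)
  if (d > 10L)
    stop("`d` > 10 implies more than 3.6 million patterns; use d <= 10 ",
         "(3..7 recommended)", call. = FALSE)
  structure(list(d = d, tau = tau), class = "ordinal_config")
}

#' @export
print.ordinal_config <- function(x, ...) {
  cat(sprintf("ordinal_config: d = %d (%d patterns), tau = %d\n",
              x$d, factorial(x$d), x$tau))
  invisible(x)
}

.as_ordinal_config <- function(config, d, tau) {
  if (!missing(config) && !is.null(config)) {
    if (!inherits(config, "ordinal_config"))
      config <- do.call(ordinal_config, as.list(config))
    return(config)
  }
  ordinal_config(d, tau)
}

#' Symbolize one embedding vector into its ordinal pattern
#'
#' Maps a `d`-dimensional vector (already extracted from the series at
#' spacing `tau`, oldest value first) to the permutation
#' `(r0, ..., r_{d-1})` of time offsets such that
#' `x[s - r0*tau] >= x[s - r1*tau] >= ... >= x[s - r_{d-1}*tau]`,
#' where offset 0 is the most recent sample.  Ties are resolved by the
#' `>=` ordering: among equal values the sample earlier in time (larger
#' offset) is placed first, so a constant vector maps to
#' `(d-1, d-2, ..., 0)`.
#'
#' @param window numeric vector of exactly `d` finite values, in
#'   chronological order (oldest first).
#' @param config optional [ordinal_config()]; `d` defaults to
#'   `length(window)`.
#' @return An object of class `"ordinal_pattern"`: integer vector of the
#'   `d` offsets, with attribute `index`, its lexicographic rank in
#'   `0 .. d!-1`.
#' @examples
#' symbolize_window(c(7, 3, 4, 5))   # (3, 0, 1, 2)
#' symbolize_window(c(3, 4, 5, 2))   # (1, 2, 3, 0)
#' @export
symbolize_window <- function(window, config = NULL) {
  d <- if (is.null(config)) length(window) else config$d
  if (length(window) != d)
    stop(sprintf("`window` must have exactly d = %d values, got %d",
                 d, length(window)), call. = FALSE)
  if (d < 2L) stop("embedding dimension must be >= 2", call. = FALSE)
  if (any(!is.finite(window)))
    stop("non-finite value in window: cannot symbolize", call. = FALSE)
  # descending stable sort; position p (1-based, chronological) has offset d-p
  ord <- order(-window, seq_along(window))
  ranks <- as.integer(d - ord)
  structure(ranks, class = "ordinal_pattern", index = pattern_index(ranks))
}

#' @export
print.ordinal_pattern <- function(x, ...) {
  cat(sprintf("ordinal pattern (%s), lexicographic index %d\n",
              paste(unclass(x), collapse = ", "), attr(x, "index")))
  invisible(x)
}

#' Lexicographic rank of an ordinal pattern
#'
#' Bijective encoding between a permutation of `{0, ..., d-1}` and an
#' integer in `0 .. d!-1` (Lehmer code).  `(0,1,...,d-1)` maps to 0 and
#' `(d-1,...,1,0)` to `d!-1`.
#'
#' @param pattern integer vector: a permutation of `0:(d-1)`.
#' @return Integer rank in `0 .. d!-1`.
#' @seealso [index_to_pattern()]
#' @export
pattern_index <- function(pattern) {
  p <- as.integer(pattern)
  d <- length(p)
  if (d < 1L || !setequal(p, 0:(d - 1L)))
    stop("`pattern` must be a permutation of 0:(d-1)", call. = FALSE)
  f <- rev(cumprod(c(1, seq_len(max(d - 1L, 0L)))))  # (d-1)!, ..., 1!, 0!
  idx <- 0
  for (i in seq_len(d - 1L))
    idx <- idx + sum(p[(i + 1L):d] < p[i]) * f[i]
  as.integer(idx)
}

#' Decode a lexicographic rank back into an ordinal pattern
#'
#' @param i integer in `0 .. d!-1`.
#' @param d embedding dimension.
#' @return Integer vector: the permutation of `0:(d-1)` with rank `i`.
#' @seealso [pattern_index()]
#' @export
index_to_pattern <- function(i, d) {
  d <- as.integer(d)
  i <- as.numeric(i)
  if (length(i) != 1L || is.na(i) || i < 0 || i >= factorial(d))
    stop("`i` must lie in 0 .. d!-1", call. = FALSE)
  pool <- 0:(d - 1L)
  out <- integer(d)
  for (k in seq_len(d)) {
    f <- factorial(d - k)
    j <- floor(i / f)
    out[k] <- pool[j + 1L]
    pool <- pool[-(j + 1L)]
    i <- i - j * f
  }
  out
}

# Vectorized pattern indices for all sliding windows of `x`.
# Returns integer vector of length N-(d-1)*tau with the lexicographic index
# per window, NA where the window contains a non-finite value.
.window_pattern_indices <- function(x, d, tau) {
  nv <- length(x) - (d - 1L) * tau
  if (nv < 1L) return(integer(0))
  # W[, p]: value at chronological position p of each window (oldest first)
  W <- matrix(0, nv, d)
  for (p in seq_len(d)) W[, p] <- x[(p - 1L) * tau + seq_len(nv)]
  bad <- rowSums(!is.finite(W)) > 0L
  if (any(bad)) W[bad, ] <- 0  # placeholder rows, masked below
  # rank (0-based) of position p in the stable descending order
  rk <- matrix(0L, nv, d)
  for (p in seq_len(d)) {
    for (q in seq_len(d)) {
      if (q == p) next
      rk[, p] <- rk[, p] +
        if (q < p) (W[, q] >= W[, p]) else (W[, q] > W[, p])
    }
  }
  # pattern: pi[rank(p)] = offset(p) = d - p  (1-based p)
  pi_m <- matrix(0L, nv, d)
  for (p in seq_len(d)) pi_m[cbind(seq_len(nv), rk[, p] + 1L)] <- d - p
  # Lehmer code -> lexicographic rank
  f <- rev(cumprod(c(1, seq_len(d - 1L))))
  idx <- numeric(nv)
  for (i in seq_len(d - 1L)) {
    ci <- integer(nv)
    for (j in (i + 1L):d) ci <- ci + (pi_m[, j] < pi_m[, i])
    idx <- idx + ci * f[i]
  }
  idx <- as.integer(idx)
  idx[bad] <- NA_integer_
  idx
}

#' Bandt-Pompe ordinal pattern distribution of a time series
#'
#' Slides a `d`-sample window (delay `tau`) along the series, symbolizes
#' every window with [symbolize_window()]'s ordering rule, and tabulates
#' the relative frequency of each of the `d!` patterns.  Windows that
#' contain non-finite values are skipped and counted separately, so the
#' probabilities always normalize over valid windows only.  Long series
#' are processed in bounded-memory chunks with `(d-1)*tau` overlap.
#'
#' A warning is emitted when the series is too short for reliable
#' statistics (fewer than `100 * d!` samples): the pattern-frequency
#' estimate requires the series length to greatly exceed the number of
#' accessible states `d!`.
#'
#' @param x numeric time series.
#' @param config optional [ordinal_config()].
#' @param d,tau embedding dimension and delay, used when `config` is not
#'   supplied.  Defaults `d = 6`, `tau = 1`.
#' @param chunk_size samples per processing chunk (default `2^20`).
#' @return An object of class `"ordinal_distribution"`: a list with
#'   `d`, `tau`, `counts` (integer, length `d!`), `probs` (sums to 1),
#'   `n_vectors` (valid windows) and `n_dropped` (windows skipped for
#'   non-finite values).
#' @examples
#' od <- ordinal_distribution(c(7, 3, 4, 5, 2, 9), d = 4)
#' od$probs[od$probs > 0]    # three patterns, each 1/3
#' @export
ordinal_distribution <- function(x, config = NULL, d = 6L, tau = 1L,
                                 chunk_size = 2^20) {
  cfg <- .as_ordinal_config(config, d, tau)
  d <- cfg$d; tau <- cfg$tau
  x <- as.numeric(x)
  N <- length(x)
  span <- (d - 1L) * tau
  if (N < span + 1L)
    stop(sprintf("series of length %d is shorter than one embedding vector (%d samples)",
                 N, span + 1L), call. = FALSE)
  if (all(!is.finite(x)))
    stop("series contains no finite values", call. = FALSE)
  M <- factorial(d)
  if (N < 100 * M)
    warning(sprintf(
      "series length N = %d may be too short for d = %d: reliable pattern statistics require N >> d! = %d",
      N, d, M), call. = FALSE)
  counts <- numeric(M)
  n_dropped <- 0L
  start <- 1L
  while (start + span <= N) {
    end <- min(N, start + chunk_size - 1L)
    idx <- .window_pattern_indices(x[start:end], d, tau)
    n_dropped <- n_dropped + sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    if (length(idx)) counts <- counts + tabulate(idx + 1L, nbins = M)
    if (end == N) break
    start <- end - span + 1L  # overlap so no window is missed or doubled
  }
  n_vectors <- sum(counts)
  if (n_vectors == 0)
    stop("no valid embedding vector: every window contains non-finite values",
         call. = FALSE)
  structure(list(d = d, tau = tau,
                 counts = as.integer(counts),
                 probs = counts / n_vectors,
                 n_vectors = as.integer(n_vectors),
                 n_dropped = as.integer(n_dropped)),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf(
    "ordinal_distribution: d = %d, tau = %d | %d patterns, %d vectors (%d dropped), %d occupied\n",
    x$d, x$tau, length(x$probs), x$n_vectors, x$n_dropped,
    sum(x$counts > 0)))
  invisible(x)
}
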