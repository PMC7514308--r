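#' Shannon entropy of a probability vector (nats)
#'
#' `S[P] = -sum_i p_i ln p_i`, with `0 ln 0 = 0`.  Natural logarithms
#' are used throughout the package, so entropies are in nats and the
#' maximum over `M` states is `ln M`.
#'
#' @param p non-negative numeric vector summing to 1 (tolerance 1e-9).
#' @return Entropy in nats, in `[0, ln(length(p))]`.
#' @export
shannon_entropy <- function(p) {
  p <- .check_prob(p)
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

.check_prob <- function(p, tol = 1e-9) {
  if (inherits(p, "ordinal_distribution")) p <- p$probs
  p <- as.numeric(p)
  if (length(p) < 1L || any(!is.finite(p)))
    stop("probability vector must be finite and non-empty", call. = FALSE)
  if (any(p < 0))
    stop("probability vector has a negative entry", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probabilities sum to %.12f, not 1", sum(p)), call. = FALSE)
  p
}

#' Normalized permutation entropy H
#'
#' `H[P] = S[P] / ln M` with `M` the number of states (for an ordinal
#' distribution, `M = d!`), so `0 <= H <= 1`: 0 for a deterministic
#' (single-pattern) signal, 1 for equiprobable patterns.
#'
#' @param p probability vector or an [ordinal_distribution()].
#' @return H in `[0, 1]`.
#' @export
normalized_entropy <- function(p) {
  p <- .check_prob(p)
  M <- length(p)
  if (M < 2L) stop("need at least 2 states to normalize entropy", call. = FALSE)
  shannon_entropy(p) / log(M)
}

#' Jensen-Shannon divergence between two distributions (nats)
#'
#' `J[P,Q] = S[(P+Q)/2] - S[P]/2 - S[Q]/2`.  Symmetric, non-negative,
#' and zero iff `P = Q`.
#'
#' @param p,q probability vectors of equal length.
#' @return Divergence in nats.
#' @export
jensen_shannon_divergence <- function(p, q) {
  p <- .check_prob(p); q <- .check_prob(q)
  if (length(p) != length(q))
    stop("`p` and `q` must have the same length", call. = FALSE)
  shannon_entropy((p + q) / 2) - shannon_entropy(p) / 2 - shannon_entropy(q) / 2
}

# Maximum of J[P, uniform(M)], attained when P is a point mass.
# Closed form from substituting the delta distribution into J.
.max_jsd <- function(M) {
  -0.5 * (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
}

#' Normalized Jensen-Shannon disequilibrium Q_J
#'
#' `Q_J[P] = Q0 * J[P, P_e]` where `P_e` is the uniform distribution over
#' the `M` states and `Q0` is the inverse of the maximum possible
#' divergence, attained when `P` is a point mass.  `Q0` is computed from
#' the closed form of `J` at the delta distribution, so `Q_J` is exactly
#' 1 there and 0 at the uniform distribution.
#'
#' @param p probability vector or [ordinal_distribution()].
#' @return Q_J in `[0, 1]`.
#' @export
disequilibrium <- function(p) {
  p <- .check_prob(p)
  M <- length(p)
  if (M < 2L) stop("need at least 2 states", call. = FALSE)
  pe <- rep(1 / M, M)
  jensen_shannon_divergence(p, pe) / .max_jsd(M)
}

#' Statistical complexity C
#'
#' `C[P] = Q_J[P] * H[P]`: the product of the normalized Jensen-Shannon
#' disequilibrium from the uniform distribution and the normalized
#' entropy.  C vanishes at both extremes (a deterministic signal, where
#' `H = 0`, and fully random fluctuations, where `Q_J = 0`) and is
#' positive in between, quantifying correlation structure.
#'
#' @param p probability vector or [ordinal_distribution()].
#' @return C, non-negative.
#' @export
statistical_complexity <- function(p) {
  p <- .check_prob(p)
  disequilibrium(p) * normalized_entropy(p)
}

#' Permutation entropy and statistical complexity of a time series
#'
#' Builds the Bandt-Pompe ordinal distribution of the series and returns
#' its position on the complexity-entropy (C-H) plane.  Chorusing raises
#' the correlation structure of the waveform, moving hours to the left
#' of the plane (lower H, higher C); noise-dominated hours sit on the
#' right (H near 1, small C).
#'
#' @inheritParams ordinal_distribution
#' @return An object of class `"ch_point"`: list with `H`, `C`, `d`,
#'   `tau` and `n_vectors`.
#' @examples
#' set.seed(1)
#' global_complexity(rnorm(5000), d = 4)
#' @export
global_complexity <- function(x, config = NULL, d = 6L, tau = 1L,
                              chunk_size = 2^20) {
  od <- ordinal_distribution(x, config = config, d = d, tau = tau,
                             chunk_size = chunk_size)
  ch_point(normalized_entropy(od), statistical_complexity(od),
           d = od$d, tau = od$tau, n_vectors = od$n_vectors)
}

#' Construct a C-H plane point
#'
#' @param H normalized permutation entropy in `[0, 1]`.
#' @param C statistical complexity, `>= 0`.
#' @param d,tau embedding parameters the point was computed with.
#' @param n_vectors number of ordinal vectors supporting the estimate.
#' @return Object of class `"ch_point"`.
#' @export
ch_point <- function(H, C, d = NA_integer_, tau = NA_integer_,
                     n_vectors = NA_integer_) {
  if (!is.finite(H) || H < -1e-12 || H > 1 + 1e-12)
    stop("H must lie in [0, 1]", call. = FALSE)
  if (!is.finite(C) || C < -1e-12)
    stop("C must be non-negative", call. = FALSE)
  structure(list(H = min(max(H, 0), 1), C = max(C, 0),
                 d = d, tau = tau, n_vectors = n_vectors),
            class = "ch_point")
}

#' @export
print.ch_point <- function(x, ...) {
  cat(sprintf("C-H point: H = %.4f, C = %.4f (d = %s, tau = %s, n = %s)\n",
              x$H, x$C, x$d, x$tau, x$n_vectors))
  invisible(x)
}

# (H, C) of one distribution without revalidation; internal fast path
.hc_of <- function(p) {
  M <- length(p)
  pos <- p > 0
  S <- -sum(p[pos] * log(p[pos]))
  H <- S / log(M)
  pe <- rep(1 / M, M)
  m <- (p + pe) / 2
  J <- -sum(m * log(m)) - S / 2 - log(M) / 2
  c(H, J / .max_jsd(M) * H)
}

#' Minimum and maximum complexity curves of the C-H plane
#'
#' For every entropy value H there is a band of attainable complexities
#' `C_min(H) <= C <= C_max(H)`.  The lower bound is traced by the
#' one-parameter family with one component `p` and the remaining
#' `M - 1` components equal, `p` in `[1/M, 1]`.  The upper bound is the
#' upper envelope over the families having `n = 0, ..., M-2` components
#' exactly zero and the remaining mass split as one free component plus
#' equal shares.  Both curves are sampled in the family parameter and
#' re-gridded in H by linear interpolation.
#'
#' @param d embedding dimension (`M = d!` states).
#' @param n_grid sample points per family (default 2000, minimum 100).
#' @return Object of class `"plane_reference"`: list with `d`, `M`,
#'   `S_max = ln M`, `Q0`, and data frames `min_curve`, `max_curve`
#'   with columns `H`, `C` sorted by H.
#' @examples
#' pr <- limit_curves(4, n_grid = 500)
#' range(pr$max_curve$C)
#' @export
limit_curves <- function(d, n_grid = 2000L) {
  d <- as.integer(d)
  if (d < 2L) stop("`d` must be >= 2", call. = FALSE)
  if (n_grid < 100L) stop("`n_grid` must be >= 100", call. = FALSE)
  M <- factorial(d)
  if (M > 5000L)
    stop(sprintf("d = %d gives %d states; the envelope over M-1 families is impractical. Use d <= 7.",
                 d, M), call. = FALSE)
  # lower bound: p in [1/M, 1], rest equal
  pg <- seq(1 / M, 1, length.out = n_grid)
  minc <- t(vapply(pg, function(p)
    .hc_of(c(p, rep((1 - p) / (M - 1), M - 1L))), numeric(2)))
  minc <- minc[order(minc[, 1]), , drop = FALSE]
  # upper bound: envelope over n = 0..M-2 zero components
  Hg <- seq(0, 1, length.out = n_grid)
  env <- rep(0, n_grid)
  per_fam <- max(64L, ceiling(n_grid / (M - 1L)))
  for (n in 0:(M - 2L)) {
    m <- M - n
    qg <- seq(0, 1 / m, length.out = per_fam)
    pts <- t(vapply(qg, function(p)
      .hc_of(c(p, rep((1 - p) / (m - 1L), m - 1L), rep(0, n))), numeric(2)))
    pts <- pts[order(pts[, 1]), , drop = FALSE]
    f <- stats::approx(pts[, 1], pts[, 2], xout = Hg, rule = 1)$y
    env <- pmax(env, f, na.rm = TRUE)
  }
  env[!is.finite(env)] <- 0
  env[c(1, n_grid)] <- 0  # both bounds vanish at H = 0 and H = 1
  structure(list(
    d = d, M = M, S_max = log(M), Q0 = 1 / .max_jsd(M),
    min_curve = data.frame(H = minc[, 1], C = pmax(minc[, 2], 0)),
    max_curve = data.frame(H = Hg, C = env)),
    class = "plane_reference")
}

#' @export
print.plane_reference <- function(x, ...) {
  cat(sprintf(
    "C-H plane reference: d = %d (M = %d), S_max = %.4f nats, Q0 = %.4f\n  C_max peak = %.4f at H = %.3f\n",
    x$d, x$M, x$S_max, x$Q0,
    max(x$max_curve$C), x$max_curve$H[which.max(x$max_curve$C)]))
  invisible(x)
}

#' Evaluate the boundary curves at given entropies
#'
#' Linear interpolation of `C_min` / `C_max` at arbitrary H.
#'
#' @param plane a [limit_curves()] object.
#' @param H numeric vector of entropies in `[0, 1]`.
#' @param which `"min"` or `"max"`.
#' @return Numeric vector of boundary complexities.
#' @export
boundary_complexity <- function(plane, H, which = c("min", "max")) {
  which <- match.arg(which)
  crv <- if (which == "min") plane$min_curve else plane$max_curve
  stats::approx(crv$H, crv$C, xout = H, rule = 2)$y
}

#' Export C-H points or limit curves to CSV
#'
#' @param x a data frame of points (e.g. `window_id`, `H`, `C`) or a
#'   `"plane_reference"` from [limit_curves()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ch_csv <- function(x, path) {
  if (inherits(x, "plane_reference")) {
    x <- rbind(cbind(curve = "min", x$min_curve),
               cbind(curve = "max", x$max_curve))
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
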