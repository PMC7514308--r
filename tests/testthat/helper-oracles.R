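# Independent brute-force oracles, kept deliberately naive.

# all permutations of 0:(d-1), one per row
all_permutations <- function(d) {
  if (d == 1L) return(matrix(0L, 1, 1))
  sub <- all_permutations(d - 1L)
  out <- NULL
  for (k in 0:(d - 1L)) {
    rest <- sub + (sub >= k)
    out <- rbind(out, cbind(rep(k, nrow(sub)), rest))
  }
  out
}

# Does the descending chain x[s - r0*tau] >= x[s - r1*tau] >= ... hold?
# `window` is chronological (oldest first), so offset j is window[d - j].
chain_holds <- function(window, perm) {
  d <- length(window)
  vals <- window[d - perm]
  all(diff(vals) <= 0)
}

# every permutation satisfying the ordering chain for this window
brute_force_patterns <- function(window) {
  d <- length(window)
  perms <- all_permutations(d)
  keep <- apply(perms, 1, function(p) chain_holds(window, p))
  perms[keep, , drop = FALSE]
}

# tie-break oracle: among chain-satisfying permutations, the one that
# lists equal values earliest-in-time first (largest offset first)
brute_force_pattern_tiebreak <- function(window) {
  cand <- brute_force_patterns(window)
  if (nrow(cand) == 1L) return(cand[1, ])
  # lexicographically largest offset sequence among candidates
  key <- apply(cand, 1, paste, collapse = ",")
  ord <- do.call(order, c(as.data.frame(-cand), list()))
  cand[ord[1], ]
}

# naive ordinal counting: symbolize every window one at a time
brute_force_distribution <- function(x, d, tau = 1) {
  nv <- length(x) - (d - 1) * tau
  counts <- numeric(factorial(d))
  for (s in seq_len(nv)) {
    w <- x[s + (0:(d - 1)) * tau]
    if (any(!is.finite(w))) next
    p <- brute_force_pattern_tiebreak(w)
    counts[pattern_index(p) + 1] <- counts[pattern_index(p) + 1] + 1
  }
  counts
}

# direct Shannon entropy, no library shortcuts
naive_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

# random probability vector (Dirichlet(1,...,1))
random_prob <- function(M) {
  g <- stats::rgamma(M, 1)
  g / sum(g)
}
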