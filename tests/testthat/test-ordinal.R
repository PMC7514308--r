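test_that("worked symbolization example reproduces both printed patterns", {
  expect_equal(unclass(symbolize_window(c(7, 3, 4, 5)))[1:4], c(3L, 0L, 1L, 2L))
  expect_equal(unclass(symbolize_window(c(3, 4, 5, 2)))[1:4], c(1L, 2L, 3L, 0L))
  od <- suppressWarnings(ordinal_distribution(c(7, 3, 4, 5, 2, 9), d = 4))
  expect_equal(od$n_vectors, 3L)
  expect_equal(length(od$probs), 24L)   # 4! accessible symbols
  occupied <- which(od$probs > 0) - 1L
  expect_setequal(occupied,
                  c(pattern_index(c(3, 0, 1, 2)), pattern_index(c(1, 2, 3, 0)),
                    pattern_index(unclass(symbolize_window(c(4, 5, 2, 9)))[1:4])))
  expect_true(all(od$probs[od$probs > 0] == 1 / 3))
})

test_that("monotone and tied windows follow the >= ordering rule", {
  # strictly increasing: most recent sample is largest, offsets ascend
  expect_equal(unclass(symbolize_window(c(1, 2, 3, 4)))[1:4], 0:3)
  # constant window: ties broken towards the earlier sample (larger offset)
  expect_equal(unclass(symbolize_window(c(5, 5, 5, 5)))[1:4], c(3L, 2L, 1L, 0L))
  # tie-broken output always satisfies the descending chain
  set.seed(31)
  for (rep in 1:50) {
    w <- sample(1:3, 5, replace = TRUE)   # heavy ties
    p <- unclass(symbolize_window(w))[1:5]
    expect_true(chain_holds(w, p))
    expect_equal(p, brute_force_pattern_tiebreak(w))
  }
})

test_that("symbolization rejects bad windows", {
  expect_error(symbolize_window(c(1, NA, 3)), "non-finite")
  expect_error(symbolize_window(c(1, Inf, 3)), "non-finite")
  expect_error(symbolize_window(1:3, ordinal_config(4)), "exactly")
})

test_that("pattern index is a lexicographic bijection", {
  expect_equal(pattern_index(0:3), 0L)
  expect_equal(pattern_index(c(3, 2, 1, 0)), 23L)
  for (d in c(3, 4, 6)) {
    for (i in seq_len(factorial(d)) - 1L)
      expect_equal(pattern_index(index_to_pattern(i, d)), i)
  }
  expect_error(pattern_index(c(0, 0, 1)), "permutation")
  expect_error(index_to_pattern(24, 4), "0 .. d!-1")
})

test_that("vectorized counting matches the brute-force chain oracle", {
  set.seed(77)
  for (d in c(3, 4, 5)) {
    x <- rnorm(300)
    od <- ordinal_distribution(x, d = d, tau = 1) |> suppressWarnings()
    expect_equal(as.numeric(od$counts), brute_force_distribution(x, d))
  }
  # with a delay > 1
  x <- rnorm(200)
  od <- suppressWarnings(ordinal_distribution(x, d = 3, tau = 3))
  expect_equal(as.numeric(od$counts), brute_force_distribution(x, 3, tau = 3))
})

test_that("distribution normalizes, warns on short series, errors on empty", {
  set.seed(5)
  od <- suppressWarnings(ordinal_distribution(rnorm(500), d = 4))
  expect_equal(sum(od$probs), 1, tolerance = 1e-12)
  expect_equal(sum(od$counts), od$n_vectors)
  expect_warning(ordinal_distribution(rnorm(500), d = 5), "N >> d!")
  expect_silent(ordinal_distribution(rnorm(700), d = 3))
  expect_error(ordinal_distribution(c(1, 2), d = 4), "shorter")
  expect_error(ordinal_distribution(rep(NaN, 50), d = 3), "no finite")
})

test_that("NaN-containing windows are skipped, not imputed", {
  x <- c(1, 3, 2, NA, 5, 4, 6)
  od <- suppressWarnings(ordinal_distribution(x, d = 3))
  # windows overlapping the NA (3 of them) are dropped
  expect_equal(od$n_dropped, 3L)
  expect_equal(od$n_vectors, 2L)
  expect_equal(sum(od$probs), 1)
})

test_that("monotone series concentrates all mass on one pattern", {
  od <- suppressWarnings(ordinal_distribution(seq_len(1000), d = 6))
  expect_equal(sum(od$probs > 0), 1L)
  expect_equal(max(od$probs), 1)
})

test_that("i.i.d. noise gives equiprobable patterns", {
  set.seed(99)
  od <- ordinal_distribution(runif(2e5), d = 3)
  se <- sqrt((1 / 6) * (5 / 6) / od$n_vectors)
  expect_true(all(abs(od$probs - 1 / 6) < 3.5 * se))
})

test_that("symbolization is invariant under increasing monotone transforms", {
  set.seed(12)
  x <- rnorm(3000)
  a <- ordinal_distribution(x, d = 4)
  b <- ordinal_distribution(exp(x), d = 4)
  expect_identical(a$counts, b$counts)
})

test_that("chunked processing equals single-pass counting", {
  set.seed(8)
  x <- rnorm(5000)
  whole <- ordinal_distribution(x, d = 4, tau = 2)
  chunked <- ordinal_distribution(x, d = 4, tau = 2, chunk_size = 257)
  expect_identical(whole$counts, chunked$counts)
  expect_identical(whole$n_vectors, chunked$n_vectors)
})
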