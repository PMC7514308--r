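test_that("Shannon entropy handles the limiting distributions", {
  expect_equal(shannon_entropy(c(1, rep(0, 5))), 0)
  expect_equal(shannon_entropy(rep(1 / 24, 24)), log(24))
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), log(2))
  expect_error(shannon_entropy(c(0.7, 0.4)), "sum")
  expect_error(shannon_entropy(c(1.2, -0.2)), "negative")
  # agrees with the naive loop on random vectors
  set.seed(3)
  for (i in 1:20) {
    p <- random_prob(24)
    expect_equal(shannon_entropy(p), naive_entropy(p))
  }
})

test_that("normalized entropy spans [0, 1] with the right endpoints", {
  expect_equal(normalized_entropy(rep(1 / 120, 120)), 1)
  expect_equal(normalized_entropy(c(1, rep(0, 119))), 0)
  expect_error(normalized_entropy(1), "at least 2")
  set.seed(4)
  for (i in 1:50) {
    h <- normalized_entropy(random_prob(24))
    expect_true(h >= 0 && h <= 1)
  }
})

test_that("Jensen-Shannon divergence: identity, symmetry, non-negativity", {
  u <- rep(1 / 6, 6)
  expect_equal(jensen_shannon_divergence(u, u), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0.5, 0.5)), 0.2157616,
               tolerance = 1e-6)
  expect_error(jensen_shannon_divergence(u, rep(1 / 4, 4)), "length")
  set.seed(6)
  for (i in 1:200) {
    p <- random_prob(24); q <- random_prob(24)
    j1 <- jensen_shannon_divergence(p, q)
    expect_true(j1 >= 0)
    expect_equal(j1, jensen_shannon_divergence(q, p))
  }
})

test_that("delta distribution attains the closed-form divergence maximum", {
  for (M in c(2, 6, 24, 720)) {
    delta <- c(1, rep(0, M - 1)); pe <- rep(1 / M, M)
    jmax <- -0.5 * (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
    expect_equal(jensen_shannon_divergence(delta, pe), jmax, tolerance = 1e-12)
    expect_equal(disequilibrium(delta), 1, tolerance = 1e-12)
    expect_equal(disequilibrium(pe), 0)
  }
})

test_that("disequilibrium and complexity stay within their bounds", {
  set.seed(9)
  for (i in 1:300) {
    p <- random_prob(24)
    q <- disequilibrium(p)
    expect_true(q >= 0 && q <= 1)
    expect_equal(statistical_complexity(p),
                 q * normalized_entropy(p), tolerance = 1e-12)
  }
  expect_equal(statistical_complexity(rep(1 / 24, 24)), 0)
  expect_equal(statistical_complexity(c(1, rep(0, 23))), 0)
})

test_that("two alternating patterns give the closed-form C-H point", {
  # square-ish alternation visits exactly two ordinal patterns; pick the
  # length so both are hit an identical number of times
  for (d in c(3, 4)) {
    x <- rep_len(c(0, 1), (d - 1) + 1198)
    chp <- suppressWarnings(global_complexity(x, d = d))
    M <- factorial(d)
    p2 <- c(0.5, 0.5, rep(0, M - 2))
    expect_equal(chp$H, log(2) / log(M), tolerance = 1e-9)
    expect_equal(chp$C, statistical_complexity(p2), tolerance = 1e-9)
  }
})

test_that("a monotone ramp sits at the origin of the plane", {
  chp <- suppressWarnings(global_complexity(seq_len(2000), d = 5))
  expect_equal(chp$H, 0)
  expect_equal(chp$C, 0)
})

test_that("entropy of i.i.d. noise rises towards 1 with series length", {
  set.seed(14)
  hs <- vapply(c(1e3, 1e4, 1e5), function(n)
    suppressWarnings(global_complexity(rnorm(n), d = 4))$H, numeric(1))
  cs <- vapply(c(1e3, 1e4, 1e5), function(n)
    suppressWarnings(global_complexity(rnorm(n), d = 4))$C, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_true(all(diff(cs) < 0))
  expect_gt(hs[3], 0.99)
  expect_lt(cs[3], 0.02)
})

test_that("limit curves behave as plane boundaries", {
  pr <- limit_curves(4, n_grid = 800)
  expect_equal(pr$M, 24)
  expect_equal(pr$S_max, log(24))
  # both curves vanish at the extremes
  expect_equal(boundary_complexity(pr, c(0, 1), "min"), c(0, 0),
               tolerance = 1e-6)
  expect_equal(boundary_complexity(pr, c(0, 1), "max"), c(0, 0),
               tolerance = 1e-6)
  # min <= max everywhere
  Hg <- seq(0.01, 0.99, length.out = 200)
  expect_true(all(boundary_complexity(pr, Hg, "min") <=
                    boundary_complexity(pr, Hg, "max") + 1e-9))
  expect_error(limit_curves(1), ">= 2")
  expect_error(limit_curves(4, n_grid = 10), "n_grid")
  expect_error(limit_curves(8), "d <= 7")
})

test_that("random distributions are contained between the limit curves", {
  pr <- limit_curves(4, n_grid = 1500)
  set.seed(21)
  for (i in 1:500) {
    p <- random_prob(24)
    H <- normalized_entropy(p); C <- statistical_complexity(p)
    expect_gte(C, boundary_complexity(pr, H, "min") - 1e-3)
    expect_lte(C, boundary_complexity(pr, H, "max") + 1e-3)
  }
})

test_that("adding a periodic pulse train to noise lowers H and raises C", {
  set.seed(33)
  n <- 20000
  noise <- rnorm(n)
  t <- seq_len(n)
  pulses <- 3 * exp(-((t %% 40) / 6)) * sin(2 * pi * t / 7)
  a <- global_complexity(noise, d = 5)
  b <- global_complexity(noise + pulses, d = 5)
  expect_lt(b$H, a$H)
  expect_gt(b$C, a$C)
})

test_that("CSV export round-trips points and curves", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(window_id = 1:3, H = c(0.2, 0.5, 0.9), C = c(0.1, 0.3, 0.05))
  write_ch_csv(df, tmp)
  expect_equal(utils::read.csv(tmp), df)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_ch_csv(limit_curves(3, 200), tmp2)
  crv <- utils::read.csv(tmp2)
  expect_setequal(unique(crv$curve), c("min", "max"))
})
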