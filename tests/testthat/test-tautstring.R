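test_that("noise-scale estimator matches its closed form and recovers sigma", {
  expect_equal(estimate_sigma(rep(2, 10)), 0)
  expect_equal(estimate_sigma(c(0, 1, 0, 1, 0, 1)), 1.48 / sqrt(2))
  expect_error(estimate_sigma(1), "at least 2")

  # Monte-Carlo recovery on sparse-jump signals
  err <- vapply(1:20, function(s) {
    set.seed(s)
    sig <- rand_pcw_signal(20000, njumps = 5, noise = 0.2)
    abs(estimate_sigma(sig$r) - 0.2) / 0.2
  }, numeric(1))
  expect_true(all(err < 0.05))
})

test_that("default lambda follows c * sqrt(n) * sigma", {
  expect_equal(default_lambda(rep(1, 50)), 0)
  r <- c(0, 1, 0, 1)  # sigma = 1.48/sqrt(2), n = 4
  expect_equal(default_lambda(r, c = 0.3), 0.3 * 2 * 1.48 / sqrt(2))
  expect_equal(default_lambda(r, c = 0.6), 2 * default_lambda(r, c = 0.3))
  expect_error(default_lambda(r, c = 0), "positive")
})

test_that("taut string solves the small closed-form cases", {
  # tube collapse -> interpolation
  r <- c(1.2, -0.4, 3.3)
  expect_equal(taut_string(r, 0)$f_hat, r)
  # pairwise shrinkage: f = (r1 + t, r2 - t), t = min(theta, (r2-r1)/2)
  expect_equal(taut_string(c(0, 2), 0.5)$f_hat, c(0.5, 1.5))
  expect_equal(taut_string(c(0, 2), 5)$f_hat, c(1, 1))
  # huge tube -> constant at the mean
  set.seed(5)
  r <- rnorm(40)
  expect_equal(taut_string(r, 1e3)$f_hat, rep(mean(r), 40))
  expect_error(taut_string(r, -1), "negative")
})

test_that("taut string equals the exact TV minimizer (dense dual solver)", {
  set.seed(7)
  worst <- 0
  for (trial in 1:40) {
    n <- sample(5:200, 1)
    sig <- rand_pcw_signal(n, njumps = sample(0:6, 1), noise = runif(1, 0, 1))
    lam <- runif(1, 0.02, 3)
    f1 <- taut_string(sig$r, lam)$f_hat
    f2 <- tv_oracle(sig$r, lam)
    worst <- max(worst, max(abs(f1 - f2)))
  }
  expect_lt(worst, 1e-7)
})

test_that("variable-radius tubes match an independent QP string solver", {
  set.seed(17)
  for (trial in 1:5) {
    n <- sample(8:40, 1)
    r <- rand_pcw_signal(n, 2, 0.4)$r
    theta <- runif(n, 0.05, 1.5)
    f1 <- taut_string(r, theta)$f_hat
    f2 <- tube_string_oracle(r, theta)
    expect_lt(max(abs(f1 - f2)), 1e-6)
  }
})

test_that("tube feasibility and pinned endpoints hold", {
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(10:300, 1)
    sig <- rand_pcw_signal(n, 3, 0.5)
    theta <- runif(1, 0.1, 4)
    f <- taut_string(sig$r, theta)$f_hat
    R <- cumsum(sig$r); S <- cumsum(f)
    expect_true(all(abs(S[-n] - R[-n]) <= theta + 1e-9))
    expect_equal(S[n], R[n])  # right endpoint exact
  }
})

test_that("non-extremal constant runs equal the local data mean", {
  set.seed(29)
  for (trial in 1:10) {
    n <- sample(30:200, 1)
    sig <- rand_pcw_signal(n, 3, 0.4)
    res <- taut_string(sig$r, runif(1, 0.2, 2))
    runs <- rle(res$f_hat)
    ends <- cumsum(runs$lengths)
    starts <- c(1, ends[-length(ends)] + 1)
    k <- length(runs$values)
    if (k >= 3) {
      for (j in 2:(k - 1)) {
        v <- runs$values[j]
        is_ext <- (v > runs$values[j - 1] && v > runs$values[j + 1]) ||
          (v < runs$values[j - 1] && v < runs$values[j + 1])
        if (!is_ext)
          expect_equal(v, mean(sig$r[starts[j]:ends[j]]), tolerance = 1e-9)
      }
    }
  }
})

test_that("breakpoint count is non-increasing in lambda", {
  set.seed(37)
  for (trial in 1:50) {
    n <- sample(20:150, 1)
    r <- rand_pcw_signal(n, 4, 0.5)$r
    ks <- vapply(c(0.01, 0.05, 0.2, 0.5, 1, 2, 5), function(lam)
      length(taut_string(r, lam)$breakpoints), integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("denoising re-applied never increases total variation", {
  set.seed(43)
  for (trial in 1:10) {
    r <- rand_pcw_signal(500, 4, 0.3)$r
    f1 <- denoise(r)$f_hat
    f2 <- denoise(f1)$f_hat
    expect_lte(total_variation(f2), total_variation(f1) + 1e-12)
  }
})

test_that("local squeezing recovers a noiseless step exactly", {
  x <- c(rep(0, 50), rep(1, 50))
  res <- denoise(x, taut_string_params())
  expect_equal(res$breakpoints, 50L)
  expect_true(all(abs(res$f_hat - x) < 1e-6))
  expect_true(res$converged)
})

test_that("single-pass result is returned when residuals already pass", {
  set.seed(47)
  r <- rnorm(256, 0, 0.1)  # pure noise: first pass satisfies the criterion
  res <- denoise(r, taut_string_params())
  one_pass <- taut_string(r, 0.5 * default_lambda(r))
  expect_equal(res$squeeze_rounds, 1L)
  expect_equal(res$f_hat, one_pass$f_hat)
  # multiresolution off: exactly one pass at 0.5 * lambda by construction
  off <- denoise(r, taut_string_params(use_multiresolution = FALSE))
  expect_equal(off$f_hat, one_pass$f_hat)
})

test_that("gamma near 1 yields no more local extremes than small gamma", {
  set.seed(53)
  wins <- 0L
  for (trial in 1:20) {
    sig <- rand_pcw_signal(800, 5, 0.35)
    k_lo <- denoise(sig$r, taut_string_params(gamma = 0.1))$k
    k_hi <- denoise(sig$r, taut_string_params(gamma = 0.9))$k
    wins <- wins + (k_hi <= k_lo)
  }
  expect_gte(wins, 15L)  # holds in the clear majority of draws
})

test_that("taut string runtime scales linearly in n", {
  set.seed(59)
  ns <- c(1e3, 1e4, 1e5, 1e6)
  times <- vapply(ns, function(n) {
    r <- rand_pcw_signal(n, 10, 0.3)$r
    th <- 0.5 * default_lambda(r)
    median(vapply(1:3, function(i)
      system.time(taut_string(r, th))[["elapsed"]], numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(pmax(times, 1e-4)) ~ log(ns)))[2]
  expect_gt(slope, 0.6)
  expect_lt(slope, 1.4)
})
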