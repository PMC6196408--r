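test_that("outlier filtering trims strict percentile tails", {
  tr <- toy_track(1:100)
  res <- filter_outliers(tr, pct = 1)
  expect_equal(nrow(res$track), 98L)
  expect_equal(range(res$track$count), c(2, 99))
  expect_equal(res$report$n_removed_count_low, 1L)
  expect_equal(res$report$n_removed_count_high, 1L)

  # fully tied data loses nothing under the strict rule
  tied <- filter_outliers(toy_track(rep(7, 50)), pct = 1)
  expect_equal(nrow(tied$track), 50L)

  # pct = 0 is the identity
  expect_equal(nrow(filter_outliers(tr, pct = 0)$track), 100L)

  expect_error(filter_outliers(tr, pct = 50), "pct")
})

test_that("filtering is monotone in pct and applies GC jointly", {
  set.seed(11)
  tr <- toy_track(rpois(400, 40), gc = runif(400, 0.2, 0.7))
  kept_prev <- rep(TRUE, 400)
  for (pct in c(0, 1, 2, 5, 10)) {
    kept <- filter_outliers(tr, pct)$report$kept_mask
    expect_true(all(kept_prev | !kept))  # larger pct never resurrects
    kept_prev <- kept
  }
  # a window may trip several criteria; mask is the conjunction
  rep5 <- filter_outliers(tr, 5)$report
  expect_equal(sum(!rep5$kept_mask) <= rep5$n_removed_count_low +
                 rep5$n_removed_count_high + rep5$n_removed_gc_low +
                 rep5$n_removed_gc_high, TRUE)
})

test_that("GC bias fit recovers flat and unimodal response curves", {
  set.seed(21)
  # flat response: smooth curve is constant at the common mean
  gc <- runif(2000, 0.25, 0.65)
  flat <- toy_track(rep(10, 2000), gc = gc)
  cv <- fit_gc_bias(flat)
  expect_true(all(abs(cv$m_gc_smooth - 10) < 0.5))

  # unimodal synthetic bias, 200 windows per integer bin on 25..65
  bins <- rep(25:65, each = 200)
  mu <- 20 * exp(-(bins - 45)^2 / 200)
  counts <- rpois(length(bins), mu)
  tr <- toy_track(counts, gc = bins / 100)
  cv2 <- fit_gc_bias(tr)
  at <- cv2$gc_level >= 25 & cv2$gc_level <= 65
  gen <- 20 * exp(-(cv2$gc_level[at] - 45)^2 / 200)
  expect_true(all(abs(cv2$m_gc_smooth[at] - gen) < 0.1 * pmax(gen, 1)))

  expect_error(fit_gc_bias(toy_track(rep(5, 10), gc = rep(0.4, 10))),
               "2 populated")
  expect_error(fit_gc_bias(toy_track(1:5)), "no gc")
})

test_that("GC correction rescales counts and removes the GC trend", {
  # forced by the formula: count 10, smooth 5, center 10 -> 20
  cv <- structure(list(gc_level = c(40L, 50L), m_gc = c(5, 10),
                       m_gc_smooth = c(5, 10), n_windows = c(1L, 1L),
                       global_center = 10), class = "gc_bias_curve")
  tr <- toy_track(c(10, 10), gc = c(0.40, 0.50))
  out <- correct_gc_bias(tr, cv)
  expect_equal(out$count, c(20, 10))

  # flat curve at the center is the identity
  cvf <- structure(list(gc_level = c(40L, 50L), m_gc = c(10, 10),
                        m_gc_smooth = c(10, 10), n_windows = c(1L, 1L),
                        global_center = 10), class = "gc_bias_curve")
  expect_equal(correct_gc_bias(tr, cvf)$count, tr$count)

  # Monte-Carlo: unimodal bias induces a GC-count correlation that the
  # fitted correction removes
  set.seed(31)
  gc <- rbeta(6000, 20, 24)
  # bias peak on the upper flank of the GC distribution so the raw
  # counts carry a strong linear GC trend
  mu <- 60 * (0.2 + exp(-(100 * gc - 60)^2 / 800))
  tr2 <- toy_track(rpois(6000, mu), gc = gc)
  before <- abs(cor(tr2$count, tr2$gc))
  corr <- correct_gc_bias(tr2, fit_gc_bias(tr2))
  after <- abs(cor(corr$count, corr$gc))
  expect_gt(before, 0.5)
  expect_lt(after, 0.1)

  # order within one GC bin is preserved
  bin45 <- round(corr$gc * 100) == 45
  expect_equal(order(corr$count[bin45]), order(tr2$count[bin45]))
})

test_that("log2 ratio is zero for identical tracks and finite with zeros", {
  set.seed(41)
  tr <- toy_track(rpois(200, 50))
  r <- log2_ratio(tr, tr, median_center = FALSE)
  expect_equal(r$values, rep(0, 200))
  # regardless of centering
  expect_equal(log2_ratio(tr, tr)$values, rep(0, 200))

  # doubled sample at forced equal library sizes, no pseudocount
  tr2 <- tr; tr2$count <- 2 * tr$count
  r2 <- log2_ratio(tr2, tr, pseudocount = 0, median_center = FALSE,
                   lib_sizes = c(1, 1))
  expect_equal(r2$values, rep(1, 200))
  # with median centering the constant shift vanishes
  expect_equal(log2_ratio(tr2, tr, pseudocount = 0)$values, rep(0, 200))

  # zero count stays finite thanks to the pseudocount
  trz <- toy_track(c(50, 0, 50))
  expect_true(all(is.finite(log2_ratio(toy_track(c(50, 40, 50)), trz,
                                       pseudocount = 0.5)$values)))

  # ratio is computed on the window intersection
  half <- tr[1:100, ]
  attr(half, "window_width") <- 100L
  class(half) <- c("window_track", "data.frame")
  expect_equal(log2_ratio(tr, half)$n, 100L)
})
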