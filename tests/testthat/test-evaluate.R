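truth_from_segments <- function(n, starts, ends, vals) {
  f <- numeric(n)
  for (i in seq_along(starts)) f[starts[i]:ends[i]] <- vals[i]
  truth_set(f)
}

called <- function(starts, ends, vals)
  call_segments(cnv_segments(starts, ends, vals), thr = 0.2)

test_that("perfect detection attains ideal metrics", {
  tr <- truth_from_segments(1000, c(101, 501), c(200, 700), c(1, -1))
  det <- called(c(1, 101, 201, 501, 701), c(100, 200, 500, 700, 1000),
                c(0, 1, 0, -1, 0))
  ev <- segment_overlap_eval(det, tr)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$breakpoint_accuracy, 1)
  va <- value_agreement(det, tr)
  expect_equal(va$fraction_within, 1)
  expect_equal(va$mean_rel_diff, 0)
})

test_that("the 80 percent benchmark-overlap boundary is respected", {
  # detected covers 79 of 100 truth windows: no match, FN and FP both 1
  tr <- truth_from_segments(500, 101, 200, 1)
  det <- called(c(1, 101, 180), c(100, 179, 500), c(0, 1, 0))
  ev <- segment_overlap_eval(det, tr, min_frac = 0.8)
  expect_equal(c(ev$tp, ev$fn, ev$fp), c(0, 1, 1))

  # exactly 80 windows matches (>= rule)
  det80 <- called(c(1, 101, 181), c(100, 180, 500), c(0, 1, 0))
  ev80 <- segment_overlap_eval(det80, tr, min_frac = 0.8)
  expect_equal(c(ev80$tp, ev80$fn, ev80$fp), c(1, 0, 0))
})

test_that("direction mismatches and spurious calls are counted", {
  tr <- truth_from_segments(600, c(1, 201), c(100, 300), c(1, -1))
  det <- called(c(1, 91, 401, 451), c(90, 400, 450, 600), c(1, 0, 1, 0))
  ev <- segment_overlap_eval(det, tr)
  expect_equal(ev$tp, 1)   # the 90-window amplification (90% overlap)
  expect_equal(ev$fn, 1)   # the deletion is missed
  expect_equal(ev$fp, 1)   # the 401..450 call matches nothing

  # an amplification over a true deletion never matches
  flip <- called(c(1, 201, 301), c(200, 300, 600), c(0, 1, 0))
  evf <- segment_overlap_eval(flip, tr)
  expect_equal(evf$tp, 0)
  expect_equal(evf$fp, 1)
})

test_that("breakpoint accuracy demands exact boundaries", {
  tr <- truth_from_segments(400, c(11, 101, 201, 301), c(20, 150, 240, 350),
                            c(1, -1, 1, -1))
  exact <- called(tr$cnv$start_idx, tr$cnv$end_idx, tr$cnv$mean_value)
  expect_equal(breakpoint_accuracy(exact, tr), 1)
  shifted <- called(tr$cnv$start_idx + 1L, tr$cnv$end_idx + 1L,
                    tr$cnv$mean_value)
  expect_equal(breakpoint_accuracy(shifted, tr), 0)
  half <- called(tr$cnv$start_idx[1:2], tr$cnv$end_idx[1:2],
                 tr$cnv$mean_value[1:2])
  expect_equal(breakpoint_accuracy(half, tr), 0.5)
})

test_that("value agreement applies the relative tolerance", {
  tr <- truth_from_segments(300, 101, 200, 1)
  within <- called(101, 200, 0.85)
  expect_equal(value_agreement(within, tr)$fraction_within, 1)
  expect_equal(value_agreement(within, tr)$mean_rel_diff, 0.15)
  outside <- called(101, 200, 0.7)
  expect_equal(value_agreement(outside, tr)$fraction_within, 0)
  none <- called(1, 50, 0.9)
  expect_equal(value_agreement(none, tr)$n_pairs, 0L)
})

test_that("matching agrees with a brute-force oracle on random layouts", {
  set.seed(101)
  for (trial in 1:200) {
    n <- 300L
    k <- sample(1:4, 1)
    starts <- sort(sample(seq(1, n - 20, by = 20), k))
    ends <- starts + sample(5:15, k, replace = TRUE)
    tr <- truth_from_segments(n, starts, ends,
                              sample(c(-1, 1), k, replace = TRUE))
    m <- sample(0:4, 1)
    det_s <- if (m) sort(sample(seq(1, n - 20, by = 17), m)) else integer()
    det <- called(det_s, det_s + sample(4:18, m, replace = TRUE),
                  runif(m, -1.5, 1.5))
    ev <- segment_overlap_eval(det, tr)
    or <- overlap_oracle(det, tr)
    expect_equal(c(ev$tp, ev$fp, ev$fn), c(or$tp, or$fp, or$fn))
  }
})

test_that("loosening the overlap threshold never loses true positives", {
  set.seed(103)
  for (trial in 1:20) {
    n <- 400L
    sig <- rand_pcw_signal(n, 4, 0.3)
    tr <- truth_set(round(sig$f))
    det <- detect_cnvs(sig$r, "tautstring",
                       cbs = cbs_params(seed = trial))$segments
    tp_strict <- segment_overlap_eval(det, tr, min_frac = 0.8)$tp
    tp_loose <- segment_overlap_eval(det, tr, min_frac = 1e-6)$tp
    expect_gte(tp_loose, tp_strict)
  }
})

test_that("length-stratified metrics split by direction and length band", {
  tr <- truth_from_segments(1000, c(11, 101, 501), c(20, 180, 520),
                            c(1, 1, -1))
  # the 10-window amplification found, the 80-window one missed,
  # the 20-window deletion found plus one short false amplification
  det <- called(c(11, 301, 501), c(20, 310, 520), c(1.1, 0.9, -1.2))
  ev <- segment_overlap_eval(det, tr)
  amp <- length_stratified_metrics(ev, tr, "amplification", c(1, 20))
  expect_equal(amp$sensitivity, 1)      # only the 10-window truth is in band
  expect_equal(amp$fdr, 0.5)            # one matched, one false short call
  del <- length_stratified_metrics(ev, tr, "deletion", c(1, 20))
  expect_equal(del$sensitivity, 1)
  expect_equal(del$fdr, 0)
  wide <- length_stratified_metrics(ev, tr, "amplification", c(1, 100))
  expect_equal(wide$sensitivity, 0.5)

  pooled <- pooled_stratified_metrics(list(ev, ev), list(tr, tr),
                                      "amplification", c(1, 20))
  expect_equal(pooled$sensitivity, 1)
  expect_equal(pooled$n_truth, 2L)
})
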