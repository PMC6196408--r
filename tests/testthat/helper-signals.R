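# Shared fixture generators (all seeded by the caller).

# Random piecewise-constant signal plus Gaussian noise.
rand_pcw_signal <- function(n, njumps = 3L, noise = 0.3, amp = 1) {
  f <- numeric(n)
  njumps <- min(njumps, n - 1L)
  if (njumps > 0L) {
    pos <- sort(sample(seq_len(n - 1L), njumps))
    lev <- cumsum(c(0, runif(njumps, -amp, amp)))
    f <- lev[findInterval(seq_len(n), c(0, pos)) ]
  }
  list(f = f, r = f + rnorm(n, 0, noise))
}

# A small window track with optional GC column.
toy_track <- function(counts, gc = NULL, width = 100L) {
  n <- length(counts)
  window_track("chr1", (seq_len(n) - 1L) * width, seq_len(n) * width,
               counts, gc = gc, window_width = width)
}
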