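# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation configuration
#'
#' Describes one synthetic log2-ratio signal: a zero baseline of length `n`
#' carrying non-overlapping piecewise-constant CNV segments, plus i.i.d.
#' Gaussian noise.  Noise is given either directly as `sigma_N` or through
#' the signal-to-noise ratio `snr = P_signal / sigma_N^2`, where `P_signal`
#' is the mean square of the noiseless signal over CNV windows.
#'
#' @param n signal length in windows.
#' @param cnv a data frame with columns `start_idx` (1-based), `length`
#'   (windows) and `log2_amplitude` (nonzero); segments must not overlap.
#' @param sigma_N Gaussian noise standard deviation (give exactly one of
#'   `sigma_N`, `snr`).
#' @param snr signal-to-noise ratio alternative to `sigma_N`.
#' @param seed RNG seed for the noise draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, cnv, sigma_N = NULL, snr = NULL, seed = 1L) {
  if (is.null(sigma_N) == is.null(snr))
    stop("give exactly one of sigma_N or snr")
  stopifnot(n >= 1, all(cnv$length >= 1),
            all(cnv$start_idx >= 1),
            all(cnv$start_idx + cnv$length - 1 <= n))
  if (any(cnv$log2_amplitude == 0)) stop("CNV amplitudes must be nonzero")
  if (nrow(cnv) > 1L) {
    o <- order(cnv$start_idx)
    s <- cnv$start_idx[o]; e <- s + cnv$length[o] - 1L
    if (any(s[-1L] <= e[-length(e)])) stop("overlapping CNV segments")
  }
  structure(list(n = as.integer(n), cnv = cnv, sigma_N = sigma_N,
                 snr = snr, seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth CNV set
#'
#' @param f the noiseless per-window log2-ratio vector (0 = neutral).
#' @return A `truth_set`: list with the truth vector `f`, the CNV segment
#'   table `cnv` (a [cnv_segments()] with amplification/deletion calls and
#'   `mean_value` equal to the segment amplitude) and `n`.
#' @export
truth_set <- function(f) {
  runs <- piecewise_runs(f)
  is_cnv <- runs$values != 0
  segs <- cnv_segments(runs$starts[is_cnv], runs$ends[is_cnv],
                       runs$values[is_cnv],
                       ifelse(runs$values[is_cnv] > 0, "amplification",
                              "deletion"))
  structure(list(f = f, cnv = segs, n = length(f)), class = "truth_set")
}

#' Simulate a noisy log2-ratio signal
#'
#' Builds the noiseless signal `f` from the configured CNV segments over a
#' zero baseline and returns `r = f + eps` with `eps ~ N(0, sigma_N^2)`
#' i.i.d.  When the configuration specifies `snr`, the noise scale is
#' `sigma_N = sqrt(P_signal / snr)` with `P_signal` the mean square of `f`
#' over CNV windows.  Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return A list with `truth` (a [truth_set()]) and `signal` (a
#'   [ratio_signal()]).
#' @export
simulate_ratio_signal <- function(config) {
  f <- numeric(config$n)
  if (nrow(config$cnv)) {
    for (i in seq_len(nrow(config$cnv))) {
      s <- config$cnv$start_idx[i]
      e <- s + config$cnv$length[i] - 1L
      f[s:e] <- config$cnv$log2_amplitude[i]
    }
  }
  sigma <- config$sigma_N
  if (is.null(sigma)) {
    p_sig <- mean(f[f != 0]^2)
    if (!is.finite(p_sig)) stop("snr given but no CNV windows")
    sigma <- sqrt(p_sig / config$snr)
  }
  r <- with_seed(config$seed, f + rnorm(config$n, 0, sigma))
  list(truth = truth_set(f), signal = ratio_signal(r))
}

#' Simulate paired sample/normal readcount tracks
#'
#' End-to-end test input for the preprocessing chain: per-window GC drawn
#' from a Beta distribution, normal counts `Poisson(depth * b(gc))`, sample
#' counts `Poisson(depth * b(gc) * 2^f)` with `f` the configured CNV truth
#' and `b` an injected GC-bias multiplier.  Deterministic given the seed.
#'
#' @param config a [sim_config()] (its `sigma_N`/`snr` is ignored here; the
#'   noise is Poisson counting noise).
#' @param gc_bias `NULL` for a flat response, or a function mapping GC
#'   fraction to a positive multiplier, e.g.
#'   `function(gc) 0.2 + exp(-(100 * gc - 45)^2 / 288)` for a unimodal bias
#'   peaked at 45% GC.
#' @param mean_depth expected readcount of an unbiased neutral window
#'   (default 100).
#' @param window_width window width in base pairs (default 100).
#' @return A list with `sample` and `normal` ([window_track()]s with GC) and
#'   `truth` (a [truth_set()]).
#' @export
simulate_paired_tracks <- function(config, gc_bias = NULL, mean_depth = 100,
                                   window_width = 100L) {
  stopifnot(mean_depth > 0)
  n <- config$n
  f <- simulate_ratio_signal(config)$truth$f
  with_seed(config$seed, {
    gc <- rbeta(n, 20, 24)
    b <- if (is.null(gc_bias)) rep(1, n) else gc_bias(gc)
    if (any(b <= 0)) stop("gc_bias must return positive multipliers")
    normal_counts <- rpois(n, mean_depth * b)
    sample_counts <- rpois(n, mean_depth * b * 2^f)
    start <- (seq_len(n) - 1L) * window_width
    list(sample = window_track("chr1", start, start + window_width,
                               sample_counts, gc = gc,
                               window_width = window_width),
         normal = window_track("chr1", start, start + window_width,
                               normal_counts, gc = gc,
                               window_width = window_width),
         truth = truth_set(f))
  })
}

# Draw one random CNV layout: segment lengths log-uniform in [1, max_len],
# accepted while cumulative coverage stays within coverage_cap; amplitudes
# +/- amplitude; placements uniform with at least one neutral window between
# segments.
random_cnv_layout <- function(n, max_len = 10000L, coverage_cap = 0.3,
                              amplitude = 1) {
  budget <- floor(coverage_cap * n)
  lens <- integer(0)
  repeat {
    cand <- as.integer(round(10^runif(1, 0, log10(max_len))))
    cand <- max(1L, min(cand, max_len))
    if (sum(lens) + cand > budget) break
    lens <- c(lens, cand)
  }
  k <- length(lens)
  if (k == 0L) {
    lens <- 1L
    k <- 1L
  }
  slack <- n - sum(lens) - (k - 1L)
  gaps <- as.integer(rmultinom(1, slack, rep(1, k + 1L)))
  starts <- integer(k)
  pos <- gaps[1L] + 1L
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + lens[i] + 1L + gaps[i + 1L]
  }
  data.frame(start_idx = starts, length = lens,
             log2_amplitude = amplitude * sample(c(-1, 1), k, replace = TRUE))
}

#' Benchmark suite of simulated CNV signals
#'
#' Generates the simulation design used throughout the package's evaluation:
#' `n_signals` piecewise-constant log2-ratio signals of `n` windows each,
#' with CNV segment lengths drawn log-uniformly over `[1, max_len]` windows,
#' amplitudes of `+/-1` (amplifications and deletions mixed), total CNV
#' coverage at most `coverage_cap` of the signal, and Gaussian noise with
#' standard deviation swept over `sigma_grid`.  By default each signal is
#' paired with one grid value, cycling, so the grid is covered evenly; with
#' `full_grid = TRUE` every signal is replicated at every noise level.
#' Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param n_signals number of distinct truth signals (default 50).
#' @param sigma_grid noise-level grid (default 10 values from 0.47 down to
#'   0.05).
#' @param n signal length in windows (default 34000, the smallest round size
#'   at which a `max_len` segment respects the coverage cap).
#' @param max_len maximum CNV length in windows (default 10000).
#' @param coverage_cap maximum fraction of windows inside CNVs (default 0.3).
#' @param amplitude absolute log2 amplitude of simulated CNVs (default 1).
#' @param full_grid replicate every signal at every noise level.
#' @return A list of replicates, each a list with `truth`, `signal`,
#'   `sigma_N` and `replicate` (index of the underlying truth layout).
#' @export
cnv_benchmark_suite <- function(seed = 1L, n_signals = 50L,
                                sigma_grid = seq(0.47, 0.05,
                                                 length.out = 10),
                                n = 34000L, max_len = 10000L,
                                coverage_cap = 0.3, amplitude = 1,
                                full_grid = FALSE) {
  with_seed(seed, {
    layouts <- lapply(seq_len(n_signals), function(i)
      random_cnv_layout(n, max_len, coverage_cap, amplitude))
    noise_seeds <- sample.int(.Machine$integer.max, n_signals *
                                (if (full_grid) length(sigma_grid) else 1L))
    out <- list()
    idx <- 0L
    for (i in seq_len(n_signals)) {
      sigmas <- if (full_grid) sigma_grid
                else sigma_grid[(i - 1L) %% length(sigma_grid) + 1L]
      for (s in sigmas) {
        idx <- idx + 1L
        cfg <- sim_config(n, layouts[[i]], sigma_N = s,
                          seed = noise_seeds[idx])
        sim <- simulate_ratio_signal(cfg)
        out[[idx]] <- list(truth = sim$truth, signal = sim$signal,
                           sigma_N = s, replicate = i)
      }
    }
    out
  })
}
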