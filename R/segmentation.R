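#' Parameters of circular binary segmentation
#'
#' @param alpha significance level for accepting a split (default 0.01).
#' @param n_perm permutation count per tested split (default 1000, minimum
#'   100).
#' @param min_width minimum arc width in windows (default 2, guarding
#'   degenerate single-point splits).
#' @param seed integer seed for the permutation RNG; segmentation is
#'   deterministic given the seed and independent of R's RNG state.
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 1000L, min_width = 2L,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100L, min_width >= 1L)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = as.double(seed)),
            class = "cbs_params")
}

#' Circular binary segmentation
#'
#' Recursive changepoint search: on each current interval the circular arc
#' maximizing the two-sample mean-shift statistic against its complement is
#' located by an exact scan over all arc endpoints, and the split is accepted
#' when its permutation p-value is at most `alpha` (permuted maxima are
#' scanned over all short arcs plus a strided arc-length grid, with
#' sequential early stopping; see the methods vignette).  Accepted arcs add
#' both endpoints as changepoints and the recursion continues on the pieces
#' until no split is accepted.
#'
#' @param signal a [ratio_signal()] or numeric vector (typically the
#'   denoised log2-ratio signal).
#' @param params a [cbs_params()].
#' @return A [cnv_segments()] table partitioning `1..n`, with `mean_value`
#'   the mean of `signal` on each segment and `call` unset (`NA`).
#' @export
cbs_segment <- function(signal, params = cbs_params()) {
  x <- as_signal_values(signal)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  bks <- .cbs_changepoints(x, params$alpha, params$n_perm, params$min_width,
                           params$seed, 25L, 48L)
  starts <- c(1L, bks + 1L)  # 0-based boundaries -> 1-based starts
  ends <- c(bks, n)
  means <- vapply(seq_along(starts),
                  function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  cnv_segments(starts, ends, means)
}

#' Segments from a piecewise-constant signal
#'
#' Direct readout of the maximal constant runs of an already
#' piecewise-constant vector (e.g. a taut-string fit), one segment per run.
#' A fast alternative to [cbs_segment()] on denoised signals.
#'
#' @param f_hat a piecewise-constant numeric vector or [ratio_signal()].
#' @return A [cnv_segments()] table.
#' @export
segments_from_piecewise <- function(f_hat) {
  x <- as_signal_values(f_hat)
  if (!length(x)) stop("empty signal")
  runs <- piecewise_runs(x)
  cnv_segments(runs$starts, runs$ends, runs$values)
}

#' Threshold-based CNV calling
#'
#' Labels each segment by its mean log2 ratio: `amplification` when
#' `mean_value > thr`, `deletion` when `mean_value < -thr`, otherwise
#' `neutral`.  The inequalities are strict, so a mean exactly at the
#' threshold stays neutral.
#'
#' @param segments a [cnv_segments()] table with `mean_value` set.
#' @param thr positive calling threshold on the log2 ratio (0.2 for the
#'   simulated readcount benchmark; 0.5 is typical for gene-level calling).
#' @return The segment table with `call` filled in.
#' @export
call_segments <- function(segments, thr = 0.2) {
  if (thr <= 0) stop("thr must be positive")
  segments$call <- ifelse(segments$mean_value > thr, "amplification",
                   ifelse(segments$mean_value < -thr, "deletion", "neutral"))
  segments
}

#' Merge adjacent segments with the same call into CNV regions
#'
#' Consecutive segments carrying the same call collapse into one region
#' whose mean is the length-weighted mean of its parts.  Segmentation of a
#' denoised signal often splits the flanks of a large CNV into short
#' steps of the same direction; a contiguous run of equally-called segments
#' is one detected CNV region, and evaluation against benchmark regions
#' assumes this representation.
#'
#' @param segments a called [cnv_segments()] table sorted by `start_idx`.
#' @return A called [cnv_segments()] table with maximal same-call regions.
#' @export
merge_called_segments <- function(segments) {
  if (nrow(segments) < 2L) return(segments)
  o <- order(segments$start_idx)
  segments <- segments[o, , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(segments$call[-1L] !=
                                 segments$call[-nrow(segments)])))
  len <- segments$end_idx - segments$start_idx + 1L
  out <- do.call(rbind, lapply(split(seq_len(nrow(segments)), grp),
    function(ix) data.frame(
      start_idx = segments$start_idx[ix[1L]],
      end_idx = segments$end_idx[ix[length(ix)]],
      mean_value = sum(segments$mean_value[ix] * len[ix]) / sum(len[ix]),
      call = segments$call[ix[1L]],
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}
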