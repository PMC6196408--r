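#' Remove readcount and GC outlier windows
#'
#' Windows whose readcount falls strictly below the `pct`-th or strictly
#' above the `(100 - pct)`-th percentile of counts are treated as low-quality
#' outliers and removed; when GC fractions are present the same rule is
#' applied to GC and a window is kept only if it survives both criteria.
#' Percentiles use the linear-interpolation definition
#' (`quantile(type = 7)`), and the comparisons are strict, so a fully tied
#' track loses nothing.
#'
#' @param track a [window_track()].
#' @param pct percentage trimmed from each tail (default 1; `0 <= pct < 50`).
#' @return A list with elements `track` (the surviving windows) and `report`,
#'   a `filter_report` holding `kept_mask` and per-criterion removal tallies
#'   (`n_removed_count_low`, `n_removed_count_high`, `n_removed_gc_low`,
#'   `n_removed_gc_high`).
#' @export
filter_outliers <- function(track, pct = 1) {
  validate_window_track(track)
  if (nrow(track) == 0L) stop("empty track")
  if (pct < 0 || pct >= 50) stop("pct must lie in [0, 50)")
  tails <- function(x) {
    lo <- quantile(x, pct / 100, type = 7, names = FALSE)
    hi <- quantile(x, 1 - pct / 100, type = 7, names = FALSE)
    list(low = x < lo, high = x > hi)
  }
  cnt <- tails(track$count)
  if (!is.null(track$gc)) {
    gcf <- tails(track$gc)
  } else {
    gcf <- list(low = logical(nrow(track)), high = logical(nrow(track)))
  }
  kept <- !(cnt$low | cnt$high | gcf$low | gcf$high)
  if (!any(kept)) stop("all windows removed by outlier filtering")
  out <- track[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_width") <- attr(track, "window_width")
  class(out) <- c("window_track", "data.frame")
  report <- structure(list(kept_mask = kept,
                           n_removed_count_low = sum(cnt$low),
                           n_removed_count_high = sum(cnt$high),
                           n_removed_gc_low = sum(gcf$low),
                           n_removed_gc_high = sum(gcf$high)),
                      class = "filter_report")
  list(track = out, report = report)
}

#' Fit the GC-bias curve by weighted loess
#'
#' Windows are binned by integer GC percent; `m_gc`, the mean readcount of
#' each populated bin, is smoothed by a loess fit of `m_gc` on GC percent
#' weighted by bin occupancy, which pulls sparsely populated bins toward the
#' global trend.  The curve's `global_center` (median count over all windows)
#' is the level the correction rescales every bin to.
#'
#' @param track a [window_track()] with a `gc` column.
#' @param span loess span (default 0.3); automatically widened when fewer
#'   than `7 / span` bins are populated so the local fit stays determined.
#' @param degree loess polynomial degree (default 2).
#' @return A `gc_bias_curve`: list with `gc_level`, `m_gc`, `m_gc_smooth`,
#'   `n_windows` (per bin) and `global_center`.
#' @export
fit_gc_bias <- function(track, span = 0.3, degree = 2) {
  if (is.null(track$gc)) stop("track has no gc column")
  bin <- as.integer(round(track$gc * 100))
  tab <- tapply(track$count, bin, mean)
  gc_level <- as.integer(names(tab))
  if (length(gc_level) < 2L) stop("need at least 2 populated GC bins")
  m_gc <- as.numeric(tab)
  n_windows <- as.integer(table(bin)[names(tab)])
  eff_span <- min(1, max(span, 7 / length(gc_level)))
  fit <- loess(m_gc ~ gc_level, weights = n_windows, span = eff_span,
               degree = degree,
               control = loess.control(surface = "direct"))
  sm <- pmax(predict(fit, data.frame(gc_level = gc_level)), 0)
  structure(list(gc_level = gc_level, m_gc = m_gc, m_gc_smooth = sm,
                 n_windows = n_windows,
                 global_center = median(track$count)),
            class = "gc_bias_curve")
}

#' Correct readcounts for GC bias
#'
#' Rescales every window's count by `global_center / m_gc_smooth(gc)`: bins
#' reading high are shrunk, bins reading low are inflated, so the expected
#' count no longer depends on GC content.
#'
#' @param track a [window_track()] with a `gc` column.
#' @param curve a `gc_bias_curve` from [fit_gc_bias()].
#' @return The corrected [window_track()].
#' @export
correct_gc_bias <- function(track, curve) {
  if (is.null(track$gc)) stop("track has no gc column")
  bin <- as.integer(round(track$gc * 100))
  pos <- match(bin, curve$gc_level)
  if (anyNA(pos))
    stop("no smoothed value for GC bin ", bin[which(is.na(pos))[1L]])
  sm <- curve$m_gc_smooth[pos]
  if (any(sm <= 0))
    stop("non-positive smoothed mean at GC bin ",
         curve$gc_level[pos[which(sm <= 0)[1L]]])
  out <- track
  out$count <- track$count * curve$global_center / sm
  attr(out, "window_width") <- attr(track, "window_width")
  class(out) <- c("window_track", "data.frame")
  out
}

#' Sample/normal log2-ratio signal
#'
#' Computes `r_i = log2(((s_i + pseudocount) / S) / ((n_i + pseudocount) / N))`
#' over the windows common to both tracks, where `S` and `N` are the tracks'
#' total counts over those windows (library-size scaling; override with
#' `lib_sizes`).  The pseudocount keeps zero-count windows finite.  With
#' `median_center = TRUE` (default) the median of `r` is subtracted so that
#' copy-neutral regions sit at 0, which the `±thr` calling rule assumes.
#'
#' @param sample,normal [window_track()]s (GC-corrected in the standard
#'   pipeline); matched on (chrom, start).
#' @param pseudocount small positive value added to raw counts (default 0.5).
#' @param median_center subtract the median log2 ratio (default `TRUE`).
#' @param lib_sizes optional length-2 numeric `(S, N)` overriding the totals.
#' @return A [ratio_signal()]; `window_index` maps positions to rows of
#'   `sample`.
#' @export
log2_ratio <- function(sample, normal, pseudocount = 0.5,
                       median_center = TRUE, lib_sizes = NULL) {
  key_s <- paste(sample$chrom, sample$start)
  key_n <- paste(normal$chrom, normal$start)
  idx_s <- which(key_s %in% key_n)
  if (length(idx_s) == 0L) stop("sample and normal tracks share no windows")
  idx_n <- match(key_s[idx_s], key_n)
  s <- sample$count[idx_s]
  n <- normal$count[idx_n]
  if (is.null(lib_sizes)) lib_sizes <- c(sum(s), sum(n))
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  r <- log2((s + pseudocount) / lib_sizes[1L]) -
       log2((n + pseudocount) / lib_sizes[2L])
  if (!all(is.finite(r)))
    stop("non-finite log2 ratios; increase pseudocount")
  if (median_center) r <- r - median(r)
  ratio_signal(r, window_index = idx_s)
}
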