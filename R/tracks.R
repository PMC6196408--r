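#' Windowed readcount track
#'
#' A `window_track` is a data frame of fixed-width, non-overlapping genomic
#' windows with one readcount per window and (optionally) the window's GC
#' fraction.  Coordinates follow the BED convention: 0-based, half-open.
#' Windows must be sorted by (chrom, start), must not overlap, and every
#' window must span exactly `window_width` base pairs.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors of 0-based half-open window coordinates.
#' @param count non-negative readcounts, one per window.
#' @param gc optional GC fractions in `[0, 1]`, one per window.
#' @param window_width declared window width in base pairs (default 100).
#'
#' @return A data frame with class `window_track`, columns `chrom`, `start`,
#'   `end`, `count` and optionally `gc`, and a `window_width` attribute.
#' @export
#' @examples
#' window_track("chr1", c(0L, 100L, 200L), c(100L, 200L, 300L), c(12, 15, 9))
window_track <- function(chrom, start, end, count, gc = NULL,
                         window_width = 100L) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   count = as.numeric(count),
                   stringsAsFactors = FALSE)
  if (!is.null(gc)) df$gc <- as.numeric(gc)
  attr(df, "window_width") <- as.integer(window_width)
  class(df) <- c("window_track", "data.frame")
  validate_window_track(df)
  df
}

#' Validate a window track
#'
#' Checks the `window_track` invariants: sorted by (chrom, start),
#' non-overlapping, constant declared width, non-negative counts, GC
#' fractions in `[0, 1]`.  Called by [window_track()] and
#' [read_window_track()]; exported so externally assembled data frames can be
#' checked too.
#'
#' @param track a `window_track`.
#' @return `track`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_window_track <- function(track) {
  w <- attr(track, "window_width")
  if (is.null(w) || length(w) != 1L || is.na(w) || w <= 0)
    stop("window_track needs a positive 'window_width' attribute")
  if (nrow(track) == 0L) return(invisible(track))
  if (anyNA(track$start) || anyNA(track$end) || anyNA(track$count))
    stop("window_track contains missing values")
  bad_w <- which(track$end - track$start != w)
  if (length(bad_w))
    stop("window ", bad_w[1L], " spans ", track$end[bad_w[1L]] -
         track$start[bad_w[1L]], " bp but declared width is ", w)
  if (any(track$count < 0)) stop("negative readcounts")
  if (!is.null(track$gc)) {
    ok <- is.na(track$gc) | (track$gc >= 0 & track$gc <= 1)
    if (!all(ok)) stop("gc fractions must lie in [0, 1]")
  }
  # per-chromosome ordering and non-overlap; chromosome blocks contiguous
  ch <- track$chrom
  if (anyDuplicated(rle(ch)$values))
    stop("windows of one chromosome must be contiguous in the track")
  for (cc in unique(ch)) {
    idx <- which(ch == cc)
    s <- track$start[idx]; e <- track$end[idx]
    if (is.unsorted(s, strictly = TRUE))
      stop("windows unsorted on ", cc)
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)]))
      stop("overlapping windows on ", cc)
  }
  invisible(track)
}

#' Read a windowed readcount track from a tab-separated file
#'
#' Accepts two dialects: `bedgraph` (chrom, start, end, count) and `bed4+gc`
#' (chrom, start, end, count, gc fraction).  `dialect = "auto"` picks by
#' column count.  The parsed track is validated against the `window_track`
#' invariants, so unsorted, overlapping or wrong-width windows are rejected.
#'
#' @param path path to a tab-separated text file without header.
#' @param dialect one of `"auto"`, `"bedgraph"`, `"bed4+gc"`.
#' @param window_width declared window width in base pairs (default 100).
#' @return A [window_track()].
#' @export
read_window_track <- function(path, dialect = c("auto", "bedgraph", "bed4+gc"),
                              window_width = 100L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L)
    return(window_track(character(), integer(), integer(), numeric(),
                        window_width = window_width))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  want <- switch(dialect, bedgraph = 4L, `bed4+gc` = 5L, auto = ncol[1L])
  if (dialect == "auto" && !want %in% c(4L, 5L))
    stop("line 1: expected 4 or 5 tab-separated columns, got ", want)
  bad <- which(ncol != want)
  if (length(bad))
    stop("line ", bad[1L], ": expected ", want, " columns, got ", ncol[bad[1L]])
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x))
      stop("line ", which(is.na(x))[1L], ": cannot parse ", what)
    x
  }
  window_track(chrom = m[, 1L],
               start = num(2L, "start"),
               end   = num(3L, "end"),
               count = num(4L, "count"),
               gc    = if (want == 5L) num(5L, "gc") else NULL,
               window_width = window_width)
}

#' Write a window track as tab-separated text
#'
#' Emits `bedgraph` (4 columns) or `bed4+gc` (5 columns, when GC is present)
#' so that [read_window_track()] reproduces the track.
#'
#' @param track a [window_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, path) {
  cols <- c("chrom", "start", "end", "count", if (!is.null(track$gc)) "gc")
  df <- as.data.frame(track)[, cols, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Log2-ratio signal
#'
#' The 1-D signal consumed and produced by the denoisers: a vector of finite
#' log2-ratio observations plus the mapping of each position back to a window
#' of the originating track (`window_index`, 1-based row numbers; plain
#' `1..n` for synthetic signals).
#'
#' @param values numeric vector of finite log2 ratios.
#' @param window_index integer vector mapping positions to track rows;
#'   defaults to `seq_along(values)`.
#' @return An object of class `ratio_signal`: a list with elements `values`,
#'   `window_index` and `n`.
#' @export
ratio_signal <- function(values, window_index = seq_along(values)) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("ratio_signal values must be finite")
  window_index <- as.integer(window_index)
  if (length(window_index) != length(values))
    stop("window_index length mismatch")
  if (length(window_index) > 1L && any(diff(window_index) <= 0L))
    stop("window_index must be strictly increasing")
  structure(list(values = values, window_index = window_index,
                 n = length(values)),
            class = "ratio_signal")
}

#' @export
print.ratio_signal <- function(x, ...) {
  cat("<ratio_signal> n =", x$n, "\n")
  cat("  values: ", paste(signif(utils::head(x$values, 6L), 4L),
                          collapse = ", "),
      if (x$n > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Accept either a ratio_signal or a bare numeric vector.
as_signal_values <- function(r) {
  if (inherits(r, "ratio_signal")) r$values else as.numeric(r)
}

#' Segment table constructor
#'
#' Segments are rows of a data frame with 1-based inclusive signal-index
#' bounds `start_idx`/`end_idx`, the mean log2 ratio over the segment, and a
#' `call` in `{"amplification", "deletion", "neutral"}` (or `NA` before
#' calling).  A segmentation must partition `1..n` without gaps or overlap.
#'
#' @param start_idx,end_idx 1-based inclusive index bounds.
#' @param mean_value mean log2 ratio per segment.
#' @param call optional call labels.
#' @return A data frame with class `cnv_segments`.
#' @export
cnv_segments <- function(start_idx, end_idx, mean_value,
                         call = rep(NA_character_, length(start_idx))) {
  if (any(end_idx < start_idx)) stop("end_idx < start_idx")
  df <- data.frame(start_idx = as.integer(start_idx),
                   end_idx = as.integer(end_idx),
                   mean_value = as.numeric(mean_value),
                   call = as.character(call),
                   stringsAsFactors = FALSE)
  class(df) <- c("cnv_segments", "data.frame")
  df
}

# Check that segments partition 1..n.
check_partition <- function(segments, n) {
  if (nrow(segments) == 0L) stop("empty segmentation")
  o <- order(segments$start_idx)
  s <- segments$start_idx[o]; e <- segments$end_idx[o]
  if (s[1L] != 1L || e[length(e)] != n ||
      (length(s) > 1L && any(s[-1L] != e[-length(e)] + 1L)))
    stop("segments do not partition 1..", n)
  invisible(TRUE)
}

#' Write segment calls as BED5
#'
#' One row per segment: chrom, genomic start of the first window, genomic end
#' of the last window (0-based half-open), mean log2 ratio, call.  Segment
#' indices are resolved through the track rows referenced by the signal's
#' `window_index` when supplied.
#'
#' @param segments a [cnv_segments()] table.
#' @param track the [window_track()] the signal indices refer to.
#' @param path output file path.
#' @param window_index optional mapping from signal positions to track rows
#'   (default: positions are track rows).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, track, path,
                           window_index = seq_len(nrow(track))) {
  if (nrow(segments)) {
    rows_s <- window_index[segments$start_idx]
    rows_e <- window_index[segments$end_idx]
    if (anyNA(rows_s) || anyNA(rows_e) ||
        max(rows_e) > nrow(track) || min(rows_s) < 1L)
      stop("segment index outside track")
    ch_s <- track$chrom[rows_s]; ch_e <- track$chrom[rows_e]
    if (any(ch_s != ch_e)) stop("segment spans a chromosome boundary")
    df <- data.frame(chrom = ch_s,
                     start = track$start[rows_s],
                     end = track$end[rows_e],
                     mean_value = segments$mean_value,
                     call = ifelse(is.na(segments$call), "neutral",
                                   segments$call))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Read a BED5 segment-call file
#'
#' Inverse of [write_segments()]: maps genomic coordinates back to signal
#' indices through the track.
#'
#' @param path BED5 file written by [write_segments()].
#' @param track the [window_track()] used when writing.
#' @param window_index mapping from signal positions to track rows.
#' @return A [cnv_segments()] table.
#' @export
read_segments <- function(path, track, window_index = seq_len(nrow(track))) {
  if (file.size(path) == 0)
    return(cnv_segments(integer(), integer(), numeric(), character()))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "mean_value",
                                 "call"),
                   stringsAsFactors = FALSE)
  pos_of_row <- integer(nrow(track))
  pos_of_row[window_index] <- seq_along(window_index)
  row_s <- match(paste(df$chrom, df$start), paste(track$chrom, track$start))
  row_e <- match(paste(df$chrom, df$end), paste(track$chrom, track$end))
  if (anyNA(row_s) || anyNA(row_e))
    stop("segment coordinates not aligned to track windows")
  cnv_segments(pos_of_row[row_s], pos_of_row[row_e], df$mean_value, df$call)
}
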