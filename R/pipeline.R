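#' Denoise, segment and call a log2-ratio signal
#'
#' The in-memory core of the CNV pipeline: denoises the signal with the
#' chosen method (`"tautstring"`, `"dwt"`, `"ma"`, or `"none"` to segment
#' the raw signal), segments the denoised signal with circular binary
#' segmentation, and calls each segment by the `±thr` rule.
#'
#' @param r a [ratio_signal()] or numeric vector.
#' @param method denoising method.
#' @param ts_params a [taut_string_params()] (taut-string method).
#' @param base_params a [baseline_params()] (moving-average / wavelet
#'   methods).
#' @param cbs a [cbs_params()].
#' @param thr calling threshold on the mean log2 ratio (default 0.2).
#' @return A list with `segments` (called [cnv_segments()], means computed
#'   on the raw signal), `denoised` (the denoised vector) and `method`.
#' @export
detect_cnvs <- function(r, method = c("tautstring", "dwt", "ma", "none"),
                        ts_params = taut_string_params(),
                        base_params = baseline_params(),
                        cbs = cbs_params(), thr = 0.2) {
  method <- match.arg(method)
  x <- as_signal_values(r)
  den <- switch(method,
                tautstring = denoise(x, ts_params)$f_hat,
                dwt = dwt_denoise(x, base_params),
                ma = moving_average(x, base_params$ma_window),
                none = x)
  segs <- cbs_segment(den, cbs)
  # means (and hence calls) are taken on the segmented, i.e. denoised, signal:
  # the +/-thr rule is what the denoiser's amplitude shrinkage protects;
  # adjacent same-call segments collapse into one detected CNV region
  segs <- merge_called_segments(call_segments(segs, thr))
  list(segments = segs, denoised = den, method = method)
}

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] in one validated list.
#'
#' @param window_width window width in base pairs (default 100).
#' @param filter_pct percentile trimmed from each tail by
#'   [filter_outliers()] (default 1).
#' @param loess_span GC-bias loess span (default 0.3).
#' @param pseudocount pseudocount for [log2_ratio()] (default 0.5).
#' @param median_center median-center the log2 ratios (default `TRUE`).
#' @param method denoising method: `"tautstring"`, `"dwt"`, `"ma"`,
#'   `"none"`.
#' @param gamma,c taut-string squeezing factor and lambda scale.
#' @param ma_window moving-average window (odd).
#' @param alpha,n_perm CBS split acceptance level and permutation count.
#' @param thr calling threshold (default 0.2).
#' @param min_overlap benchmark-sided overlap fraction for evaluation
#'   (default 0.8).
#' @param seed RNG seed for CBS permutations.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_width = 100L, filter_pct = 1,
                            loess_span = 0.3, pseudocount = 0.5,
                            median_center = TRUE,
                            method = c("tautstring", "dwt", "ma", "none"),
                            gamma = 0.5, c = 0.25, ma_window = 9L,
                            alpha = 0.01, n_perm = 1000L, thr = 0.2,
                            min_overlap = 0.8, seed = 1L) {
  method <- match.arg(method)
  # validate method-specific parameters up front, before any stage runs
  ts <- taut_string_params(c = c, gamma = gamma)
  bp <- baseline_params(ma_window = ma_window)
  cb <- cbs_params(alpha = alpha, n_perm = n_perm, seed = seed)
  stopifnot(thr > 0, min_overlap > 0, min_overlap <= 1, pseudocount >= 0)
  structure(list(window_width = as.integer(window_width),
                 filter_pct = filter_pct, loess_span = loess_span,
                 pseudocount = pseudocount, median_center = median_center,
                 method = method, ts_params = ts, base_params = bp,
                 cbs = cb, thr = thr, min_overlap = min_overlap,
                 seed = seed),
            class = "pipeline_config")
}

# Map a truth BED5 file of CNV intervals onto the signal's window indexing.
truth_from_bed <- function(path, track, window_index, n) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  amp <- if (ncol(df) >= 5) df[[5]] == "amplification" else rep(TRUE,
                                                               nrow(df))
  val <- if (ncol(df) >= 4) as.numeric(df[[4]]) else ifelse(amp, 1, -1)
  f <- numeric(n)
  mid <- (track$start[window_index] + track$end[window_index]) / 2
  for (i in seq_len(nrow(df))) {
    inside <- track$chrom[window_index] == df$chrom[i] &
      mid >= df$start[i] & mid < df$end[i]
    f[inside] <- val[i]
  }
  truth_set(f)
}

#' Run the full file-based CNV pipeline
#'
#' Executes the fixed stage order filter -> GC-correct -> log2 ratio ->
#' denoise -> segment -> call on a sample/normal pair of windowed readcount
#' files, writes the calls as BED5, and, when a truth BED is supplied,
#' evaluates the calls and writes a `key=value` metrics file.  Every stage
#' logs its parameters and record counts via `message()`.  Deterministic
#' given the config's seed.
#'
#' @param sample_path,normal_path readcount files for
#'   [read_window_track()].
#' @param out_calls output BED5 path for the segment calls.
#' @param config a [pipeline_config()].
#' @param truth_path optional BED file of true CNV intervals.
#' @param out_metrics optional output path for evaluation metrics.
#' @return Invisibly, a list with `segments`, `signal`, `track` (filtered
#'   sample track) and, when truth was given, `evaluation`.
#' @export
run_pipeline <- function(sample_path, normal_path, out_calls,
                         config = pipeline_config(), truth_path = NULL,
                         out_metrics = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_msg <- function(...) message("[tautcnv] ", ...)

  smp <- stage("read", read_window_track(sample_path,
                                         window_width = config$window_width))
  nrm <- stage("read", read_window_track(normal_path,
                                         window_width = config$window_width))
  log_msg("read: sample ", nrow(smp), " windows, normal ", nrow(nrm),
          " windows (width ", config$window_width, " bp)")

  fs <- stage("filter", filter_outliers(smp, config$filter_pct))
  fn <- stage("filter", filter_outliers(nrm, config$filter_pct))
  log_msg("filter (pct=", config$filter_pct, "): sample kept ",
          nrow(fs$track), ", normal kept ", nrow(fn$track))

  if (!is.null(fs$track$gc)) {
    fs$track <- stage("gc_correct",
                      correct_gc_bias(fs$track,
                                      fit_gc_bias(fs$track,
                                                  span = config$loess_span)))
    fn$track <- stage("gc_correct",
                      correct_gc_bias(fn$track,
                                      fit_gc_bias(fn$track,
                                                  span = config$loess_span)))
    log_msg("gc_correct: loess span ", config$loess_span)
  } else {
    log_msg("gc_correct: skipped (no gc column)")
  }

  sig <- stage("ratio", log2_ratio(fs$track, fn$track,
                                   pseudocount = config$pseudocount,
                                   median_center = config$median_center))
  log_msg("ratio: ", sig$n, " common windows, pseudocount ",
          config$pseudocount, ", median_center ", config$median_center)

  res <- stage("detect",
               detect_cnvs(sig, method = config$method,
                           ts_params = config$ts_params,
                           base_params = config$base_params,
                           cbs = config$cbs, thr = config$thr))
  log_msg("denoise+segment (", config$method, "): ", nrow(res$segments),
          " segments, ",
          sum(res$segments$call != "neutral"), " CNV calls at thr ",
          config$thr)

  stage("write", write_segments(res$segments, fs$track, out_calls,
                                window_index = sig$window_index))
  log_msg("calls written to ", out_calls)

  out <- list(segments = res$segments, signal = sig, track = fs$track)
  if (!is.null(truth_path)) {
    truth <- stage("evaluate",
                   truth_from_bed(truth_path, fs$track, sig$window_index,
                                  sig$n))
    ev <- stage("evaluate",
                segment_overlap_eval(res$segments, truth,
                                     min_frac = config$min_overlap))
    out$evaluation <- ev
    if (!is.null(out_metrics)) {
      lines <- c(paste0("tp=", ev$tp), paste0("fp=", ev$fp),
                 paste0("fn=", ev$fn), paste0("tn=", ev$tn),
                 paste0("sensitivity=", ev$sensitivity),
                 paste0("fdr=", ev$fdr),
                 paste0("specificity=", ev$specificity),
                 paste0("breakpoint_accuracy=", ev$breakpoint_accuracy))
      writeLines(lines, out_metrics)
      log_msg("metrics written to ", out_metrics)
    }
  }
  invisible(out)
}
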