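#' Segment-overlap evaluation against a CNV truth set
#'
#' Matches detected CNV segments to benchmark CNV segments: a benchmark
#' segment validates a detected segment when the detected segment covers at
#' least `min_frac` of the benchmark segment's windows (benchmark-sided
#' overlap) and the call direction agrees.  Matching is one-to-one and
#' greedy by decreasing overlap (ties to the earlier segment).  TP counts
#' matched detected segments, FN benchmark segments without a match, FP
#' detected CNV segments without a match.  True negatives are counted at the
#' window level (windows neutral in both truth and detection), and
#' specificity uses window-level false positives, since a segment-level true
#' negative has no natural definition.
#'
#' @param detected a called [cnv_segments()] table (see [call_segments()])
#'   partitioning the same signal as the truth.
#' @param truth a [truth_set()].
#' @param min_frac minimum benchmark-sided overlap fraction in `(0, 1]`
#'   (default 0.8).
#' @param reciprocal additionally require the overlap to cover `min_frac` of
#'   the detected segment (default `FALSE`).
#' @return An `eval_result`: list with counts `tp`, `fp`, `fn`, `tn`
#'   (window-level), rates `sensitivity`, `fdr`, `specificity` (`NaN` when a
#'   denominator is 0), `breakpoint_accuracy`, the `matches` table
#'   (`truth_idx`, `det_idx`, `overlap` in windows), and logical vectors
#'   `truth_matched` / `det_matched` aligned to `truth$cnv` and the detected
#'   CNV rows (`det_cnv`).
#' @export
segment_overlap_eval <- function(detected, truth, min_frac = 0.8,
                                 reciprocal = FALSE) {
  stopifnot(min_frac > 0, min_frac <= 1)
  if (nrow(detected) && max(detected$end_idx) > truth$n)
    stop("detected segments extend past the truth signal length")
  det <- detected[!is.na(detected$call) & detected$call != "neutral", ,
                  drop = FALSE]
  tr <- truth$cnv
  det_len <- det$end_idx - det$start_idx + 1L
  tr_len <- tr$end_idx - tr$start_idx + 1L

  pairs <- NULL
  if (nrow(det) && nrow(tr)) {
    ir_det <- IRanges::IRanges(det$start_idx, det$end_idx)
    ir_tr <- IRanges::IRanges(tr$start_idx, tr$end_idx)
    hits <- IRanges::findOverlaps(ir_tr, ir_det)
    ti <- S4Vectors::queryHits(hits)
    di <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ir_tr[ti], ir_det[di]))
    dir_ok <- tr$call[ti] == det$call[di]
    frac_ok <- ov >= min_frac * tr_len[ti]
    if (reciprocal) frac_ok <- frac_ok & ov >= min_frac * det_len[di]
    keep <- dir_ok & frac_ok
    pairs <- data.frame(truth_idx = ti[keep], det_idx = di[keep],
                        overlap = ov[keep])
  }
  truth_matched <- logical(nrow(tr))
  det_matched <- logical(nrow(det))
  matches <- data.frame(truth_idx = integer(), det_idx = integer(),
                        overlap = integer())
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(-pairs$overlap, pairs$truth_idx, pairs$det_idx), ]
    for (p in seq_len(nrow(pairs))) {
      ti <- pairs$truth_idx[p]; di <- pairs$det_idx[p]
      if (!truth_matched[ti] && !det_matched[di]) {
        truth_matched[ti] <- TRUE
        det_matched[di] <- TRUE
        matches <- rbind(matches, pairs[p, ])
      }
    }
    rownames(matches) <- NULL
  }
  tp <- sum(det_matched)
  fp <- sum(!det_matched)
  fn <- sum(!truth_matched)
  # window-level neutrality for TN / specificity
  det_cnv_windows <- logical(truth$n)
  for (i in seq_len(nrow(det)))
    det_cnv_windows[det$start_idx[i]:det$end_idx[i]] <- TRUE
  truth_neutral <- truth$f == 0
  tn <- sum(truth_neutral & !det_cnv_windows)
  fp_windows <- sum(truth_neutral & det_cnv_windows)
  rate <- function(num, den) if (den == 0) NaN else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = rate(tp, tp + fn),
                 fdr = rate(fp, fp + tp),
                 specificity = rate(tn, tn + fp_windows),
                 breakpoint_accuracy = breakpoint_accuracy(detected, truth),
                 matches = matches,
                 truth_matched = truth_matched,
                 det_matched = det_matched,
                 det_cnv = det),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(paste0("<eval_result> TP %d  FP %d  FN %d | sensitivity %.3f",
                     "  FDR %.3f  specificity %.3f  breakpoints %.3f\n"),
              x$tp, x$fp, x$fn, x$sensitivity, x$fdr, x$specificity,
              x$breakpoint_accuracy))
  invisible(x)
}

#' Exact breakpoint accuracy
#'
#' Fraction of benchmark CNV segments for which some detected CNV segment
#' has exactly the same start and end index.
#'
#' @param detected a called [cnv_segments()] table.
#' @param truth a [truth_set()].
#' @return A fraction in `[0, 1]` (`NaN` when the truth has no CNVs).
#' @export
breakpoint_accuracy <- function(detected, truth) {
  tr <- truth$cnv
  if (nrow(tr) == 0L) return(NaN)
  det <- detected[!is.na(detected$call) & detected$call != "neutral", ,
                  drop = FALSE]
  if (nrow(det) == 0L) return(0)
  key_det <- paste(det$start_idx, det$end_idx)
  mean(paste(tr$start_idx, tr$end_idx) %in% key_det)
}

#' Copy-number value agreement on matched segments
#'
#' Over the TP-matched pairs of [segment_overlap_eval()], reports the
#' fraction of detected segments whose mean log2 ratio differs from the
#' benchmark amplitude by less than `tol_frac` of the benchmark value, and
#' the mean relative difference.
#'
#' @param detected a called [cnv_segments()] table.
#' @param truth a [truth_set()].
#' @param tol_frac relative tolerance (default 0.2).
#' @param eval_result optionally a precomputed [segment_overlap_eval()]
#'   result for these inputs.
#' @return A list with `fraction_within`, `mean_rel_diff` and `n_pairs`
#'   (`NaN` rates when no pairs matched).
#' @export
value_agreement <- function(detected, truth, tol_frac = 0.2,
                            eval_result = NULL) {
  if (is.null(eval_result))
    eval_result <- segment_overlap_eval(detected, truth)
  m <- eval_result$matches
  if (nrow(m) == 0L)
    return(list(fraction_within = NaN, mean_rel_diff = NaN, n_pairs = 0L))
  true_val <- truth$cnv$mean_value[m$truth_idx]
  det_val <- eval_result$det_cnv$mean_value[m$det_idx]
  rel <- abs(det_val - true_val) / abs(true_val)
  list(fraction_within = mean(rel < tol_frac),
       mean_rel_diff = mean(rel),
       n_pairs = nrow(m))
}

#' Length-stratified sensitivity and FDR
#'
#' Restricts the matched evaluation to a CNV length stratum and one call
#' direction: sensitivity is computed over benchmark segments whose true
#' length falls in `length_range`, and FDR over detected calls whose length
#' falls in `length_range`, following the convention that narrow-CNV
#' performance is reported per length band.
#'
#' @param eval_result a [segment_overlap_eval()] result.
#' @param truth the [truth_set()] that produced it.
#' @param direction `"amplification"` or `"deletion"`.
#' @param length_range inclusive `(min, max)` length bounds in windows.
#' @return A list with `sensitivity`, `fdr`, `n_truth` and `n_calls` for the
#'   stratum (`NaN` rates on empty strata).
#' @export
length_stratified_metrics <- function(eval_result, truth,
                                      direction = c("amplification",
                                                    "deletion"),
                                      length_range = c(1, 20)) {
  direction <- match.arg(direction)
  tr <- truth$cnv
  tr_len <- tr$end_idx - tr$start_idx + 1L
  in_tr <- tr$call == direction & tr_len >= length_range[1L] &
    tr_len <= length_range[2L]
  det <- eval_result$det_cnv
  det_len <- det$end_idx - det$start_idx + 1L
  in_det <- det$call == direction & det_len >= length_range[1L] &
    det_len <= length_range[2L]
  tp_sens <- sum(eval_result$truth_matched[in_tr])
  fn <- sum(!eval_result$truth_matched[in_tr])
  tp_fdr <- sum(eval_result$det_matched[in_det])
  fp <- sum(!eval_result$det_matched[in_det])
  rate <- function(num, den) if (den == 0) NaN else num / den
  list(sensitivity = rate(tp_sens, tp_sens + fn),
       fdr = rate(fp, fp + tp_fdr),
       n_truth = sum(in_tr), n_calls = sum(in_det))
}

#' Pool length-stratified counts over many evaluations
#'
#' Sums stratum TP/FN/FP counts across replicates (the usual way a benchmark
#' reports one sensitivity/FDR per length band) and returns the pooled rates.
#'
#' @param eval_results list of [segment_overlap_eval()] results.
#' @param truths list of matching [truth_set()]s.
#' @param direction `"amplification"` or `"deletion"`.
#' @param length_range inclusive length bounds in windows.
#' @return A list with pooled `sensitivity`, `fdr`, `n_truth`, `n_calls`.
#' @export
pooled_stratified_metrics <- function(eval_results, truths,
                                      direction = "amplification",
                                      length_range = c(1, 20)) {
  tp_s <- fn <- tp_f <- fp <- n_tr <- n_ca <- 0L
  for (i in seq_along(eval_results)) {
    ev <- eval_results[[i]]; tr <- truths[[i]]$cnv
    tr_len <- tr$end_idx - tr$start_idx + 1L
    in_tr <- tr$call == direction & tr_len >= length_range[1L] &
      tr_len <= length_range[2L]
    det <- ev$det_cnv
    det_len <- det$end_idx - det$start_idx + 1L
    in_det <- det$call == direction & det_len >= length_range[1L] &
      det_len <= length_range[2L]
    tp_s <- tp_s + sum(ev$truth_matched[in_tr])
    fn <- fn + sum(!ev$truth_matched[in_tr])
    tp_f <- tp_f + sum(ev$det_matched[in_det])
    fp <- fp + sum(!ev$det_matched[in_det])
    n_tr <- n_tr + sum(in_tr)
    n_ca <- n_ca + sum(in_det)
  }
  rate <- function(num, den) if (den == 0) NaN else num / den
  list(sensitivity = rate(tp_s, tp_s + fn), fdr = rate(fp, fp + tp_f),
       n_truth = n_tr, n_calls = n_ca)
}
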