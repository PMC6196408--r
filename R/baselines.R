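#' Parameters of the baseline denoisers
#'
#' @param ma_window odd moving-average window length (default 9).
#' @param wavelet wavelet family for [dwt_denoise()]; only `"haar"` is
#'   implemented.
#' @param dwt_level decomposition depth, or `NULL` for the maximal dyadic
#'   depth.
#' @param threshold_rule detail-coefficient threshold rule; `"universal"`
#'   (`sigma * sqrt(2 log n)`) is the only rule provided.
#' @param threshold_mode `"soft"` (shrink toward zero, default) or `"hard"`.
#' @return A `baseline_params` list.
#' @export
baseline_params <- function(ma_window = 9L, wavelet = "haar",
                            dwt_level = NULL,
                            threshold_rule = "universal",
                            threshold_mode = c("soft", "hard")) {
  threshold_mode <- match.arg(threshold_mode)
  if (ma_window < 1L || ma_window %% 2L == 0L)
    stop("ma_window must be an odd positive integer")
  if (!is.null(dwt_level) && dwt_level < 1L) stop("dwt_level must be >= 1")
  if (threshold_rule != "universal") stop("unsupported threshold rule")
  structure(list(ma_window = as.integer(ma_window), wavelet = wavelet,
                 dwt_level = dwt_level, threshold_rule = threshold_rule,
                 threshold_mode = threshold_mode),
            class = "baseline_params")
}

#' Centered moving-average denoiser
#'
#' Centered mean of window length `w`; near the edges the window shrinks
#' symmetrically (position `i` averages `r[i-h':i+h']` with
#' `h' = min((w-1)/2, i-1, n-i)`), so the output has length `n` and the first
#' and last values equal the input.
#'
#' @param r a [ratio_signal()] or numeric vector.
#' @param w odd window length, `1 <= w <= n`.
#' @return The smoothed numeric vector.
#' @export
#' @examples
#' moving_average(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
moving_average <- function(r, w = 9L) {
  x <- as_signal_values(r)
  n <- length(x)
  if (w %% 2L == 0L) stop("window length must be odd")
  if (w < 1L || w > n) stop("window length must lie in [1, n]")
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
}

# Orthonormal Haar analysis/synthesis on a length-2^J vector.
haar_forward <- function(x, levels) {
  detail <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    even <- a[seq(2L, length(a), by = 2L)]
    odd <- a[seq(1L, length(a), by = 2L)]
    detail[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, detail = detail)
}

haar_inverse <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_along(dec$detail))) {
    d <- dec$detail[[l]]
    odd <- (a + d) / sqrt(2)
    even <- (a - d) / sqrt(2)
    out <- numeric(2L * length(a))
    out[seq(1L, length(out), by = 2L)] <- odd
    out[seq(2L, length(out), by = 2L)] <- even
    a <- out
  }
  a
}

#' Wavelet-shrinkage denoiser
#'
#' Haar discrete wavelet transform with universal thresholding of the detail
#' coefficients: the signal is reflected symmetrically to the next power of
#' two, transformed, the detail coefficients are thresholded at
#' `sigma * sqrt(2 log n)` with `sigma` from [estimate_sigma()], and the
#' inverse transform is truncated back to length `n`.
#'
#' @param r a [ratio_signal()] or numeric vector, length at least 2.
#' @param params a [baseline_params()].
#' @return The denoised numeric vector, same length as the input.
#' @export
dwt_denoise <- function(r, params = baseline_params()) {
  x <- as_signal_values(r)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  if (!identical(params$wavelet, "haar"))
    stop("unsupported wavelet: ", params$wavelet)
  n2 <- 2L^ceiling(log2(n))
  if (n2 > n) {
    pad <- rev(x)[seq_len(n2 - n)]  # symmetric reflection
    xp <- c(x, pad)
  } else {
    xp <- x
  }
  maxlev <- as.integer(log2(n2))
  levels <- if (is.null(params$dwt_level)) maxlev
            else min(as.integer(params$dwt_level), maxlev)
  dec <- haar_forward(xp, levels)
  thr <- estimate_sigma(x) * sqrt(2 * log(n))
  dec$detail <- lapply(dec$detail, function(d) {
    if (params$threshold_mode == "soft") sign(d) * pmax(abs(d) - thr, 0)
    else d * (abs(d) > thr)
  })
  haar_inverse(dec)[seq_len(n)]
}
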