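#' Noise-scale estimate from successive differences
#'
#' `sigma = (1.48 / sqrt(2)) * median(|r[i+1] - r[i]|)`: the median absolute
#' successive difference, rescaled so that for i.i.d. Gaussian noise riding on
#' a sparse piecewise-constant signal the estimate converges to the noise
#' standard deviation (differencing removes the constant signal; a pair of
#' Gaussians differs with scale `sigma * sqrt(2)`, and 1.48 is the usual
#' MAD-to-sigma factor).
#'
#' @param r a [ratio_signal()] or numeric vector, length at least 2.
#' @return The non-negative noise scale.
#' @export
#' @examples
#' estimate_sigma(c(0, 1, 0, 1, 0, 1))  # 1.48 / sqrt(2)
estimate_sigma <- function(r) {
  x <- as_signal_values(r)
  if (length(x) < 2L) stop("need at least 2 observations")
  1.48 / sqrt(2) * median(abs(diff(x)))
}

#' Default total-variation regularization scale
#'
#' `lambda = c * sqrt(n) * sigma(r)`, the scale from which the taut-string
#' tube radius `0.5 * lambda` is built.
#'
#' @param r a [ratio_signal()] or numeric vector.
#' @param c positive scale constant (default 0.25).
#' @return The regularization scale `lambda`.
#' @export
default_lambda <- function(r, c = 0.25) {
  if (c <= 0) stop("c must be positive")
  x <- as_signal_values(r)
  c * sqrt(length(x)) * estimate_sigma(x)
}

#' Parameters of the taut-string denoiser
#'
#' @param c scale constant in `lambda = c * sqrt(n) * sigma` (default 0.25).
#' @param gamma local squeezing factor in (0, 1) (default 0.5): tube radii on
#'   intervals failing the multiresolution criterion are multiplied by
#'   `gamma` and the string is recomputed.
#' @param max_squeeze_iters cap on squeezing rounds (default 50).
#' @param mr_threshold_const constant `C` in the multiresolution bound
#'   `|sum w| <= sigma * sqrt(C * |I| * log n)` (default 2.5).
#' @param use_multiresolution run the squeezing loop (default `TRUE`); when
#'   `FALSE`, [denoise()] is a single taut-string pass at radius
#'   `0.5 * lambda`.
#' @return A `taut_string_params` list.
#' @export
taut_string_params <- function(c = 0.25, gamma = 0.5, max_squeeze_iters = 50L,
                               mr_threshold_const = 2.5,
                               use_multiresolution = TRUE) {
  stopifnot(c > 0, gamma > 0, gamma < 1, max_squeeze_iters >= 1,
            mr_threshold_const > 0)
  structure(list(c = c, gamma = gamma,
                 max_squeeze_iters = as.integer(max_squeeze_iters),
                 mr_threshold_const = mr_threshold_const,
                 use_multiresolution = isTRUE(use_multiresolution)),
            class = "taut_string_params")
}

# Runs, breakpoints and local-extreme count of a piecewise-constant vector.
piecewise_runs <- function(f) {
  rl <- rle(f)
  ends <- cumsum(rl$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  list(starts = starts, ends = ends, values = rl$values)
}

count_local_extremes <- function(f) {
  v <- piecewise_runs(f)$values
  k <- length(v)
  if (k < 3L) return(0L)
  mid <- v[2:(k - 1L)]
  sum((mid > v[1:(k - 2L)] & mid > v[3:k]) |
      (mid < v[1:(k - 2L)] & mid < v[3:k]))
}

make_denoise_result <- function(r, f_hat, theta, squeeze_rounds, converged) {
  runs <- piecewise_runs(f_hat)
  structure(list(f_hat = f_hat,
                 breakpoints = runs$ends[-length(runs$ends)],
                 k = count_local_extremes(f_hat),
                 squeeze_rounds = squeeze_rounds,
                 converged = converged,
                 theta = theta,
                 residuals = r - f_hat),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat("<denoise_result> n =", length(x$f_hat),
      "| segments =", length(x$breakpoints) + 1L,
      "| local extremes =", x$k,
      "| squeeze rounds =", x$squeeze_rounds,
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Taut-string solution of 1-D total-variation denoising
#'
#' Computes the shortest string through the tube of half-width `theta` around
#' the running-sum curve `R_i = sum_{u<=i} r_u`, pinned at `(0, 0)` and
#' `(n, R_n)`, via the greatest convex minorant / least concave majorant
#' construction (single left-to-right pass, restarting after each knot, time
#' linear in `n` in practice).  The differenced string `f_i = s_i - s_{i-1}`
#' is piecewise constant; for a constant scalar `theta` it is the exact
#' minimizer of
#' \deqn{\frac12 \sum_i (r_i - f_i)^2 + \vartheta \sum_i |f_{i+1} - f_i|,}
#' i.e. the total-variation solution with penalty equal to the tube radius.
#' `theta = 0` collapses the tube and returns `r` itself; a per-position
#' `theta` vector expresses locally squeezed tubes (see [denoise()]).
#'
#' @param r a [ratio_signal()] or numeric vector.
#' @param theta tube radius: non-negative scalar, or vector of length `n`
#'   giving the radius at each running-sum position (the last entry is
#'   overridden by the endpoint pinning).
#' @return A `denoise_result`: list with the piecewise-constant `f_hat`,
#'   `breakpoints` (indices `i` with `f_hat[i] != f_hat[i+1]`), `k` (number
#'   of local extreme values), `squeeze_rounds`, `converged`, the `theta`
#'   used, and `residuals`.
#' @export
#' @examples
#' taut_string(c(0, 2), theta = 0.5)$f_hat  # c(0.5, 1.5)
taut_string <- function(r, theta) {
  x <- as_signal_values(r)
  n <- length(x)
  if (n < 1L) stop("empty signal")
  if (length(theta) == 1L) theta <- rep(as.numeric(theta), n)
  if (length(theta) != n) stop("theta must be scalar or length n")
  if (any(theta < 0)) stop("negative tube radius")
  f <- .taut_string_tube(x, theta)
  make_denoise_result(x, f, theta, squeeze_rounds = 1L, converged = TRUE)
}

# Dyadic interval family over 1..n: the aligned partition at each scale
# (intervals [j*2^m + 1, (j+1)*2^m]) with truncated tails kept, the scheme
# the cited local-squeezing smoother checks its residuals on.  Returned as a
# matrix with columns start, end.
dyadic_intervals <- function(n) {
  out <- list()
  m <- 0L
  len <- 2L
  while (len <= n) {
    starts <- seq.int(1L, n, by = len)
    ends <- pmin(starts + len - 1L, n)
    keep <- ends > starts
    if (any(keep)) {
      m <- m + 1L
      out[[m]] <- cbind(starts[keep], ends[keep])
    }
    len <- len * 2L
  }
  if (!length(out)) return(cbind(1L, n))
  unique(do.call(rbind, out))
}

#' Taut-string denoising with local squeezing
#'
#' The full denoiser: starts from a tube of constant radius
#' `0.5 * lambda` with `lambda = c * sqrt(n) * sigma(r)`, runs the taut
#' string, and tests the residuals `w = r - f_hat` against a multiresolution
#' criterion on the dyadic interval family: every interval `I` must satisfy
#' `|sum_{i in I} w_i| <= sigma * sqrt(C |I| log n)`.  Where an interval
#' violates the bound the tube radius is multiplied by `gamma` on exactly
#' that index range (local squeezing) and the string is recomputed, up to
#' `max_squeeze_iters` rounds.  Squeezing sharpens local extremes that a
#' global radius would flatten.  If the loop hits the iteration cap the
#' current fit is returned with `converged = FALSE` rather than an error.
#'
#' @param r a [ratio_signal()] or numeric vector, length at least 2.
#' @param params a [taut_string_params()].
#' @return A `denoise_result` (see [taut_string()]).
#' @export
denoise <- function(r, params = taut_string_params()) {
  x <- as_signal_values(r)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  sigma <- estimate_sigma(x)
  lambda <- params$c * sqrt(n) * sigma
  theta <- rep(0.5 * lambda, n)
  if (!params$use_multiresolution) {
    res <- taut_string(x, theta)
    return(res)
  }
  iv <- dyadic_intervals(n)
  bound <- sigma * sqrt(params$mr_threshold_const *
                        (iv[, 2L] - iv[, 1L] + 1L) * log(n))
  rounds <- 0L
  converged <- FALSE
  f <- NULL
  repeat {
    rounds <- rounds + 1L
    f <- .taut_string_tube(x, theta)
    w <- x - f
    cw <- c(0, cumsum(w))
    # 1e-10 guards the sigma = 0 case, where the bound is exactly zero and
    # machine rounding in the residuals must not count as a violation
    viol <- which(abs(cw[iv[, 2L] + 1L] - cw[iv[, 1L]]) > bound + 1e-10)
    if (!length(viol)) {
      converged <- TRUE
      break
    }
    if (rounds >= params$max_squeeze_iters) break
    # squeeze each position at most once per round, over the union of
    # violating intervals (positions under several violating scales must not
    # be squeezed multiplicatively in a single round); the residual sum over
    # (a..b] is bracketed by the tube radii at positions a-1 and b, so the
    # left bracket is squeezed along with the interval
    mask <- logical(n)
    for (v in viol) mask[max(1L, iv[v, 1L] - 1L):iv[v, 2L]] <- TRUE
    theta[mask] <- theta[mask] * params$gamma
  }
  if (!converged)
    warning("local squeezing did not converge in ",
            params$max_squeeze_iters, " rounds; returning current fit")
  make_denoise_result(x, f, theta, rounds, converged)
}

#' Total variation of a signal
#'
#' `sum(|x[i+1] - x[i]|)`, the roughness the denoiser penalizes.
#'
#' @param x numeric vector or [ratio_signal()].
#' @return The total variation.
#' @export
total_variation <- function(x) sum(abs(diff(as_signal_values(x))))
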