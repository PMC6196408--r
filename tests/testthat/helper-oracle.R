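# Independent oracles used by the tests.  These deliberately take different
# algorithmic routes from the package (dense convex solvers, brute-force
# loops) so agreement is evidence of correctness rather than repetition.

# Exact 1-D total-variation minimizer at penalty `lam` via FISTA with
# adaptive restart on the box-constrained dual, run to a duality-gap
# certificate.  min_f .5||r-f||^2 + lam * sum|f_{i+1}-f_i|.
tv_oracle <- function(r, lam, max_iters = 60000L, gap_tol = 1e-16) {
  n <- length(r)
  if (n < 2L || lam <= 0) return(r)
  Dt <- function(z) c(0, z) - c(z, 0)           # D^T z
  Dr <- diff(r)
  z <- numeric(n - 1L)
  y <- z
  t <- 1
  scale <- max(1, sum(r^2))
  f_prev <- NULL
  for (k in seq_len(max_iters)) {
    g <- diff(Dt(y) - r)
    zn <- pmin(lam, pmax(-lam, y - 0.25 * g))
    tn <- (1 + sqrt(1 + 4 * t^2)) / 2
    yn <- zn + (t - 1) / tn * (zn - z)
    if (sum((y - zn) * (zn - z)) > 0) {  # adaptive restart
      yn <- zn
      tn <- 1
    }
    z <- zn; y <- yn; t <- tn
    if (k %% 250L == 0L) {
      f <- r - Dt(z)
      gap <- (0.5 * sum((r - f)^2) + lam * sum(abs(diff(f)))) -
        (sum(z * Dr) - 0.5 * sum(Dt(z)^2))
      # certified by the duality gap, or by a stalled iterate (the gap
      # computation itself carries ~1e-13 * scale rounding noise)
      if (gap < gap_tol * scale) break
      if (!is.null(f_prev) && max(abs(f - f_prev)) < 1e-12) break
      f_prev <- f
    }
  }
  r - Dt(z)
}

# Taut string through a variable tube, solved as a box-constrained quadratic
# program on the string values s (projected gradient): the shortest string
# minimizes any strictly convex symmetric function of the slopes, here
# sum (s_i - s_{i-1})^2, subject to |s_i - R_i| <= theta_i and pinned ends.
tube_string_oracle <- function(r, theta, iters = 200000L) {
  n <- length(r)
  R <- cumsum(r)
  lo <- c(R[-n] - theta[-n], R[n])
  hi <- c(R[-n] + theta[-n], R[n])
  s <- pmin(hi, pmax(lo, R))  # feasible start
  full <- c(0, s)
  for (k in seq_len(iters)) {
    g <- 2 * full[2:(n + 1)] - full[1:n] - c(full[3:(n + 1)], NA)
    g[n] <- 0  # pinned
    snew <- pmin(hi, pmax(lo, full[2:(n + 1)] - 0.25 * g))
    if (max(abs(snew - full[2:(n + 1)])) < 1e-14 && k > 100) {
      full[2:(n + 1)] <- snew
      break
    }
    full[2:(n + 1)] <- snew
  }
  diff(c(0, full[2:(n + 1)]))
}

# Brute-force segment-overlap evaluation: plain loops over all
# (benchmark, detected) pairs with greedy largest-overlap matching.
overlap_oracle <- function(detected, truth, min_frac = 0.8) {
  det <- detected[!is.na(detected$call) & detected$call != "neutral", ,
                  drop = FALSE]
  tr <- truth$cnv
  nt <- nrow(tr); nd <- nrow(det)
  ov <- matrix(0L, nt, nd)
  if (nt && nd) {
    for (i in seq_len(nt)) for (j in seq_len(nd)) {
      o <- min(tr$end_idx[i], det$end_idx[j]) -
        max(tr$start_idx[i], det$start_idx[j]) + 1L
      len_t <- tr$end_idx[i] - tr$start_idx[i] + 1L
      if (o > 0 && tr$call[i] == det$call[j] && o >= min_frac * len_t)
        ov[i, j] <- o
    }
  }
  tm <- logical(nt); dm <- logical(nd)
  repeat {
    if (!any(ov > 0)) break
    best <- which(ov == max(ov), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    tm[best[1]] <- TRUE; dm[best[2]] <- TRUE
    ov[best[1], ] <- 0L; ov[, best[2]] <- 0L
  }
  list(tp = sum(dm), fp = sum(!dm), fn = sum(!tm))
}
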