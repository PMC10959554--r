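# Signal utilities shared by event detection and turn segmentation.

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth run forward and backward (`signal::filtfilt`),
#' i.e. a fourth-order zero-phase response. The series is extended by
#' end-point reflection before filtering so that edge transients do not
#' leak into the retained samples.
#'
#' @param x numeric series.
#' @param rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz; values >= Nyquist disable filtering.
#' @param order filter order of the one-way design (default 2).
#' @return filtered series, same length as `x`.
#' @export
lowpass <- function(x, rate, cutoff = 6, order = 2) {
  n <- length(x)
  if (n < 8L || cutoff <= 0 || cutoff >= rate / 2) return(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  npad <- min(n - 1L, as.integer(ceiling(3 * rate / cutoff)))
  xp <- c(2 * x[1L] - x[(npad + 1L):2L],
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1L):(npad + n)]
}

#' Central-difference derivative
#'
#' One-sided differences at the end points.
#'
#' @param x numeric series.
#' @param h sample spacing (s).
#' @return derivative series, same length as `x`.
#' @export
central_diff <- function(x, h) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  v <- numeric(n)
  if (n > 2L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * h)
  v[1L] <- (x[2L] - x[1L]) / h
  v[n] <- (x[n] - x[n - 1L]) / h
  v
}

# Local minima of x with a prominence floor and a refractory interval.
# A candidate is a sample strictly below its left neighbour and not above
# its right neighbour (plateaus keep the earlier frame). Prominence is the
# smaller of the rises to the left and right before a deeper sample is met.
# Candidates closer than `refractory` frames to an already kept (earlier)
# candidate are dropped.
local_minima <- function(x, min_prominence = 0, refractory = 0L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] < x[1:(n - 2L)] & x[2:(n - 1L)] <= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmax <- -Inf
    j <- i - 1L
    while (j >= 1L && x[j] >= x[i]) {
      if (x[j] > lmax) lmax <- x[j]
      j <- j - 1L
    }
    if (j >= 1L) lmax <- max(lmax, x[i])  # deeper point found; rise so far counts
    rmax <- -Inf
    j <- i + 1L
    while (j <= n && x[j] >= x[i]) {
      if (x[j] > rmax) rmax <- x[j]
      j <- j + 1L
    }
    min(lmax, rmax) - x[i]
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (refractory > 0L && length(keep) > 1L) {
    out <- keep[1L]
    for (k in keep[-1L]) {
      if (k - out[length(out)] > refractory) out <- c(out, k)
    }
    keep <- out
  }
  keep
}

# Shift each candidate frame to the arg-min of the raw (unfiltered) signal
# within +/- halfwin frames. Filtering is kept for candidate robustness;
# the raw extremum restores frame-exact timing on clean signals.
refine_to_raw_min <- function(idx, raw, halfwin = 4L) {
  n <- length(raw)
  vapply(idx, function(i) {
    lo <- max(1L, i - halfwin)
    hi <- min(n, i + halfwin)
    lo + which.min(raw[lo:hi]) - 1L
  }, integer(1))
}

# Unwrap a phase series (radians) so it has no +/- pi jumps.
unwrap_rad <- function(theta) {
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}
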