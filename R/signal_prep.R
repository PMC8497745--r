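#' Zero-phase Butterworth low-pass filter
#'
#' Conditions a uniformly sampled signal with the conventional biomechanics
#' reading of an "n-th order Butterworth low-pass": a forward-backward
#' (zero-phase) pass of a half-order filter, so the net magnitude response has
#' the requested order and the net phase is zero. Edges are padded by odd
#' reflection over `3 * order` samples and each pass starts from the filter's
#' steady state for the edge value, so constants pass through exactly (DC gain
#' is exactly 1) and startup transients are suppressed.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @param order Net filter order (default 4, i.e. a dual-pass 2nd-order
#'   filter when `zero_phase = TRUE`).
#' @param zero_phase If `TRUE` (default) apply the dual-pass zero-phase
#'   scheme; if `FALSE`, a single causal pass of the full requested order.
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, rate, cutoff, order = 4L,
                                zero_phase = TRUE) {
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz)")
  }
  if (length(x) <= 3L * order) {
    stop("signal too short to filter: need more than ", 3L * order,
         " samples")
  }
  if (zero_phase && order %% 2L != 0L) {
    stop("zero-phase filtering needs an even net order (half-order per pass)")
  }
  pad <- 3L * order
  xp <- odd_reflect_pad(x, pad)
  # one causal pass started from the steady state for the first sample
  # (valid because a Butterworth low-pass has unit DC gain)
  iir_pass <- function(bf, z) {
    k <- length(bf$a) - 1L
    as.numeric(signal::filter(bf$b, bf$a, z,
                              init.x = rep(z[1], k),
                              init.y = rep(z[1], k)))
  }
  if (zero_phase) {
    bf <- signal::butter(order / 2, 2 * cutoff / rate, type = "low")
    y <- iir_pass(bf, xp)
    y <- rev(iir_pass(bf, rev(y)))
  } else {
    bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
    y <- iir_pass(bf, xp)
  }
  y[(pad + 1):(pad + length(x))]
}

# Odd (point-symmetric) reflection about the end samples: continuous in value
# and slope, the usual transient guard for zero-phase filtering.
odd_reflect_pad <- function(x, pad) {
  n <- length(x)
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  c(head_pad, x, tail_pad)
}

#' Detect the stance phase from vertical ground reaction force
#'
#' Stance is the longest contiguous run of samples with vertical GRF at or
#' above the threshold (default 30 N, closed comparison). The longest-run
#' rule discards spurious supra-threshold blips outside the true contact.
#'
#' @param grf_z Vertical GRF in N.
#' @param rate Sampling rate in Hz.
#' @param threshold Contact threshold in N (default 30).
#' @return A `stance_segment`: list with 1-based `start` and `end` indices
#'   (inclusive), `rate`, and `duration = (end - start) / rate` seconds.
#' @export
detect_stance <- function(grf_z, rate, threshold = 30) {
  above <- grf_z >= threshold
  if (!any(above)) stop("no stance: no sample reaches the ", threshold,
                        " N threshold")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lens <- r$lengths[runs]
  best <- which(lens == max(lens))
  if (length(best) > 1L) {
    stop("multiple stances: ", length(best),
         " supra-threshold runs of equal maximal length")
  }
  i <- runs[best]
  structure(
    list(start = starts[i], end = ends[i], rate = rate,
         duration = (ends[i] - starts[i]) / rate),
    class = "stance_segment"
  )
}

#' Time-normalize a stance-phase signal to a fixed number of points
#'
#' Linear interpolation of the segment onto `n` equally spaced points
#' spanning its first and last samples (percent-stance 0 to 100 for the
#' default `n = 101`). Endpoints are preserved exactly.
#'
#' @param x Signal over the stance segment (length >= 2).
#' @param n Number of output points (default 101).
#' @return A `normalized_curve`: list with `values` (length `n`) and
#'   `percent` (the 0..100 axis).
#' @export
time_normalize <- function(x, n = 101L) {
  m <- length(x)
  if (m < 2L) stop("segment must have at least 2 samples")
  xout <- seq(1, m, length.out = n)
  vals <- stats::approx(seq_len(m), x, xout = xout, method = "linear")$y
  vals[1] <- x[1]
  vals[n] <- x[m]
  structure(
    list(values = vals, percent = seq(0, 100, length.out = n)),
    class = "normalized_curve"
  )
}
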