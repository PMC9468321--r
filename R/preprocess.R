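# Signal conditioning: zero-phase Butterworth low-pass for force/torque
# channels, and half-open time windowing of any sampled signal.

# Digital Butterworth low-pass as second-order sections. The analytic
# continuous-time prototype poles exp(i*pi*(2k + n - 1) / (2n)) are pre-warped
# and mapped pair-wise through the bilinear transform; each section's
# numerator is rescaled so its DC gain is exactly 1 in floating point. The
# cascade form stays numerically exact where the expanded transfer-function
# polynomial of a 10th-order design loses ~1e-8.
butter_lowpass_sos <- function(order, cutoff_hz, rate) {
  if (!is_scalar_number(order) || order < 1 || order != round(order))
    abort_validation("filter order must be a positive integer")
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    abort_validation("cutoff frequency must lie in (0, rate/2)")
  c0 <- tan(pi * cutoff_hz / rate)  # pre-warped analog cutoff
  sections <- list()
  npairs <- order %/% 2
  if (npairs > 0) {
    k <- seq_len(npairs)
    re <- Re(exp(1i * pi * (2 * k + order - 1) / (2 * order)))
    for (r in re) {
      a0 <- 1 - 2 * r * c0 + c0^2
      a <- c(2 * (c0^2 - 1) / a0, (1 + 2 * r * c0 + c0^2) / a0)
      b <- c0^2 * c(1, 2, 1) / a0
      b <- b * ((1 + sum(a)) / sum(b))
      sections[[length(sections) + 1L]] <- c(b, a)
    }
  }
  if (order %% 2 == 1) {  # odd order: one real pole at -c0
    a0 <- 1 + c0
    a <- c((c0 - 1) / a0, 0)
    b <- c0 * c(1, 1, 0) / a0
    b <- b * ((1 + sum(a)) / sum(b))
    sections[[length(sections) + 1L]] <- c(b, a)
  }
  do.call(rbind, sections)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass of the stated order forward and then
#' backward over the signal, cancelling phase distortion. Edges are handled by
#' odd (point-symmetric) reflection padding of length `3 * order` on each
#' side, with steady-state initial conditions, so a constant signal is
#' preserved exactly and the combined DC gain is 1 within 1e-9. The
#' forward-backward pass squares the magnitude response of the designed
#' filter.
#'
#' @param x A [sampled_signal()].
#' @param order Filter order of the designed Butterworth (default 10).
#' @param cutoff_hz Cutoff frequency in Hz (default 50); must be below the
#'   Nyquist frequency `rate / 2`.
#' @return A `sampled_signal` on the same grid.
#' @export
zero_phase_lowpass <- function(x, order = 10, cutoff_hz = 50) {
  if (!inherits(x, "sampled_signal"))
    abort_validation("zero_phase_lowpass expects a sampled_signal")
  sos <- butter_lowpass_sos(order, cutoff_hz, x$rate)
  npad <- 3L * as.integer(order)
  n <- length(x$values)
  if (n <= npad)
    abort_validation("signal too short for reflection padding (need > 3 * order samples)")
  v <- x$values
  xp <- c(2 * v[1L] - v[seq(npad + 1L, 2L)],
          v,
          2 * v[n] - v[seq(n - 1L, n - npad)])
  y <- sos_filter_steady(xp, sos)
  y <- rev(sos_filter_steady(rev(y), sos))
  sampled_signal(y[(npad + 1L):(npad + n)], x$rate, x$t0, x$name, x$unit)
}

#' Filter all six force/torque channels of a stream
#' @param stream A [force_stream()].
#' @inheritParams zero_phase_lowpass
#' @return A `force_stream` with every channel filtered.
#' @export
filter_force_stream <- function(stream, order = 10, cutoff_hz = 50) {
  if (!inherits(stream, "force_stream"))
    abort_validation("filter_force_stream expects a force_stream")
  ch <- lapply(stream$channels, function(v)
    zero_phase_lowpass(sampled_signal(v, stream$rate, stream$t0),
                       order, cutoff_hz)$values)
  new_stream(ch, stream$rate, stream$t0, "force_stream")
}

# Index range [k1, k2] (1-based) of samples with t_start <= t < t_end, with a
# 1e-9-sample snap so boundaries that coincide with grid points are resolved
# deterministically by the half-open convention.
window_indices <- function(t0, rate, n, t_start, t_end) {
  r1 <- (t_start - t0) * rate
  r2 <- (t_end - t0) * rate
  k1 <- as.integer(ceiling(r1 - 1e-9)) + 1L
  k2 <- as.integer(ceiling(r2 - 1e-9))      # last sample strictly before t_end
  c(max(k1, 1L), min(k2, n))
}

#' Extract a half-open time window of a signal
#'
#' Returns the samples with `t_start <= t < t_end`. The half-open convention
#' means consecutive suture cycles partition the sample grid without double
#' counting; a boundary falling between grid points starts at the first grid
#' point at or after `t_start`.
#'
#' @param x A [sampled_signal()].
#' @param t_start,t_end Window bounds in seconds; must lie within the signal
#'   span with `t_start < t_end`.
#' @param min_samples Smallest acceptable number of samples in the window
#'   (default 2).
#' @return A `sampled_signal` covering the window.
#' @export
signal_window <- function(x, t_start, t_end, min_samples = 2L) {
  if (!inherits(x, "sampled_signal"))
    abort_validation("signal_window expects a sampled_signal")
  if (!(t_start < t_end))
    abort_validation("empty window: t_start must be < t_end")
  if (t_start < x$t0 - 1e-9 || t_end > signal_span_end(x) + 1e-9)
    abort_validation("window [%g, %g) is outside the signal span", t_start, t_end)
  n <- length(x$values)
  kk <- window_indices(x$t0, x$rate, n, t_start, t_end)
  if (kk[2L] - kk[1L] + 1L < min_samples)
    abort_validation("window [%g, %g) contains fewer than %d samples",
                     t_start, t_end, min_samples)
  sampled_signal(x$values[kk[1L]:kk[2L]], x$rate,
                 x$t0 + (kk[1L] - 1L) / x$rate, x$name, x$unit)
}
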