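# Skill-metric functionals and per-session metric extraction.
#
# Five scalar functionals of a windowed signal X(t):
#   PEAK+(X)  = max X                (largest value, e.g. upward force)
#   PEAK-(X)  = -min X               (magnitude of the most negative value;
#                                     applied literally, so it can itself be
#                                     negative for an all-positive signal)
#   PP(X)     = PEAK+ + PEAK-        (peak-to-peak amplitude)
#   INTABS(X) = int |X| dt           (impulse-like for forces)
#   DER(X)    = int (dX/dt)^2 dt     (consistency / smoothness surrogate)
# Integrals use trapezoidal quadrature on the sample grid; dX/dt uses central
# differences with one-sided stencils at the window edges.

maybe_window <- function(x, interval, min_samples) {
  if (is.null(interval)) {
    if (length(x$values) < min_samples)
      abort_validation("signal has fewer than %d samples", min_samples)
    x
  } else {
    signal_window(x, interval[1L], interval[2L], min_samples = min_samples)
  }
}

#' Peak functionals of a windowed signal
#'
#' @param x A [sampled_signal()].
#' @param interval Optional `c(t_start, t_end)` half-open window; `NULL` uses
#'   the whole signal.
#' @return Scalar metric value.
#' @export
peak_pos <- function(x, interval = NULL) {
  max(maybe_window(x, interval, 1L)$values)
}

#' @rdname peak_pos
#' @export
peak_neg <- function(x, interval = NULL) {
  -min(maybe_window(x, interval, 1L)$values)
}

#' @rdname peak_pos
#' @export
peak_to_peak <- function(x, interval = NULL) {
  v <- maybe_window(x, interval, 1L)$values
  max(v) - min(v)
}

#' Integral of the absolute signal (impulse-like quantity)
#' @inheritParams peak_pos
#' @return Scalar, in unit-seconds.
#' @export
int_abs <- function(x, interval = NULL) {
  w <- maybe_window(x, interval, 2L)
  trapz_uniform(abs(w$values), 1 / w$rate)
}

#' Integral of the squared derivative (signal consistency)
#' @inheritParams peak_pos
#' @return Scalar, in unit^2 per second.
#' @export
der <- function(x, interval = NULL) {
  w <- maybe_window(x, interval, 3L)
  v <- w$values
  n <- length(v)
  dt <- 1 / w$rate
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  trapz_uniform(d^2, dt)
}

#' Stitch-aligned coordinate frame from entry/exit points
#'
#' The tangential unit vector points from the needle-entry point to the exit
#' point in the vision frame; the orthogonal unit vector is its +90-degree
#' counter-clockwise rotation. The sign of the orthogonal direction is a
#' convention (the underlying geometry only fixes it up to reflection), so
#' PEAK+/PEAK- of the orthogonal force are side-sensitive while its
#' peak-to-peak amplitude is not.
#'
#' @param entry_point,exit_point Numeric 2-vectors in vision-frame
#'   coordinates; must be distinct (separation > 1e-9).
#' @return A `stitch_frame` with unit vectors `e_t` and `e_o`.
#' @export
stitch_frame <- function(entry_point, exit_point) {
  d <- as.numeric(exit_point) - as.numeric(entry_point)
  len <- sqrt(sum(d^2))
  if (!is.finite(len) || len <= 1e-9)
    abort_validation("entry and exit points coincide; stitch direction undefined")
  e_t <- d / len
  structure(list(e_t = e_t, e_o = c(-e_t[2L], e_t[1L])),
            class = "stitch_frame")
}

#' Decompose horizontal sensor forces into stitch-frame components
#'
#' Change of basis from the force-sensor x/y axes to the stitch frame: the
#' total horizontal force is `Fx * e_x + Fy * e_y` in the vision frame (with
#' `e_x`, `e_y` from the rig calibration), and is re-expressed as
#' `Fo * e_o + Ft * e_t` in the stitch frame, i.e.
#' `[Fo; Ft] = [e_o e_t]^-1 [e_x e_y] [Fx; Fy]` per sample. For orthonormal
#' bases the per-sample Euclidean norm is conserved.
#'
#' @param Fx,Fy [sampled_signal()]s on a common grid.
#' @param cal A [calibration()].
#' @param frame A [stitch_frame()].
#' @return List with `Fo` and `Ft` sampled signals (orthogonal and tangential
#'   to the stitch direction).
#' @export
decompose_forces <- function(Fx, Fy, cal, frame) {
  if (!inherits(cal, "calibration")) abort_validation("cal must be a calibration")
  if (!inherits(frame, "stitch_frame")) abort_validation("frame must be a stitch_frame")
  if (length(Fx$values) != length(Fy$values) || Fx$rate != Fy$rate ||
      abs(Fx$t0 - Fy$t0) > 1e-12)
    abort_validation("Fx and Fy must share the same sample grid")
  M_ot <- cbind(frame$e_o, frame$e_t)
  M_xy <- cbind(cal$e_x, cal$e_y)
  M <- solve(M_ot, M_xy)
  fo <- M[1L, 1L] * Fx$values + M[1L, 2L] * Fy$values
  ft <- M[2L, 1L] * Fx$values + M[2L, 2L] * Fy$values
  list(Fo = sampled_signal(fo, Fx$rate, Fx$t0, "Fo", "N"),
       Ft = sampled_signal(ft, Fx$rate, Fx$t0, "Ft", "N"))
}

#' The closed vocabulary of metric names
#'
#' 30 force/torque metrics (5 functionals x 6 channels), 6 vision-enabled
#' force metrics (3 peak functionals x orthogonal/tangential), 3 motion
#' ranges, and the touch count: 40 names in fixed order.
#'
#' @return Character vector of length 40.
#' @export
metric_vocabulary <- function() {
  ft <- as.vector(vapply(c("Fx", "Fy", "Fz", "Tx", "Ty", "Tz"), function(ch)
    sprintf(c("PEAK+(%s)", "PEAK-(%s)", "PP(%s)", "INTABS(%s)", "DER(%s)"), ch),
    character(5)))
  vis <- as.vector(vapply(c("Fo", "Ft"), function(ch)
    sprintf(c("PEAK+(%s)", "PEAK-(%s)", "PP(%s)"), ch), character(3)))
  c(ft, vis, sprintf("PP(theta_%s)", c("yaw", "pitch", "roll")), "Cn")
}

five_functionals <- function(x, interval) {
  c(peak_pos(x, interval), peak_neg(x, interval), peak_to_peak(x, interval),
    int_abs(x, interval), der(x, interval))
}

#' Touch counts per suture cycle
#'
#' A touch is a rising edge (0 to 1 transition) of the contact stream. Edges
#' are counted over the whole cycle — from one active start to the next
#' active start (stream end for the last cycle) — so contacts during idle
#' time are attributed to the preceding stitch. A contact already high at
#' cycle start is not counted. `scope = "active"` restricts counting to the
#' active suturing time instead.
#'
#' @param touch A [touch_stream()].
#' @param cycles Cycles from [partition_cycles()].
#' @param scope `"cycle"` (default) or `"active"`.
#' @return Integer vector, one count per cycle.
#' @export
touch_counts <- function(touch, cycles, scope = c("cycle", "active")) {
  scope <- match.arg(scope)
  v <- touch$channels$contact
  idx <- which(diff(v) == 1) + 1L           # first high sample of each contact
  edge_t <- touch$t0 + (idx - 1L) / touch$rate
  n <- length(cycles)
  vapply(seq_len(n), function(k) {
    lo <- cycles[[k]]$active[1L]
    hi <- if (scope == "active") cycles[[k]]$active[2L]
          else if (k < n) cycles[[k + 1L]]$active[1L]
          else stream_span_end(touch)
    sum(edge_t >= lo - 1e-9 & edge_t < hi - 1e-9)
  }, numeric(1))
}

metric_rows <- function(s, stitch_index, names, values) {
  tibble::tibble(subject_id = s$subject_id, group = s$group, depth = s$depth,
                 stitch_index = as.integer(stitch_index),
                 metric = names, value = as.numeric(values))
}

#' Extract all skill metrics from one session
#'
#' Runs the full per-session pipeline: zero-phase low-pass filtering of the
#' six force/torque channels (motion and touch are used raw), segmentation
#' into suture cycles, and computation of all 40 metrics per stitch over its
#' active suturing time (the touch count uses the whole cycle). Horizontal
#' forces are decomposed into stitch-frame components using the session
#' calibration and each stitch's entry/exit points.
#'
#' @param s A [suture_session()].
#' @param lowpass Apply the zero-phase low-pass to force/torque first
#'   (default TRUE).
#' @param filter_order,cutoff_hz Filter parameters, see
#'   [zero_phase_lowpass()].
#' @param touch_scope Counting window for the touch metric, see
#'   [touch_counts()].
#' @return Long-format tibble with columns `subject_id`, `group`, `depth`,
#'   `stitch_index`, `metric`, `value`; exactly `40 x nrow(stitches)` rows.
#' @export
session_metrics <- function(s, lowpass = TRUE, filter_order = 10,
                            cutoff_hz = 50, touch_scope = c("cycle", "active")) {
  s <- validate_session(s)
  touch_scope <- match.arg(touch_scope)
  force <- if (lowpass) filter_force_stream(s$force, filter_order, cutoff_hz)
           else s$force
  cycles <- partition_cycles(s$stitches)
  cn <- touch_counts(s$touch, cycles, scope = touch_scope)
  chans <- c("Fx", "Fy", "Fz", "Tx", "Ty", "Tz")
  fsig <- lapply(chans, function(ch) stream_signal(force, ch))
  names(fsig) <- chans
  msig <- lapply(c("yaw", "pitch", "roll"),
                 function(ch) stream_signal(s$motion, ch))
  out <- vector("list", length(cycles))
  for (k in seq_along(cycles)) {
    cyc <- cycles[[k]]
    iv <- cyc$active
    ann <- s$stitches[k, ]
    ftv <- unlist(lapply(fsig, five_functionals, interval = iv),
                  use.names = FALSE)
    frame <- stitch_frame(c(ann$entry_u, ann$entry_v),
                          c(ann$exit_u, ann$exit_v))
    dec <- decompose_forces(signal_window(fsig$Fx, iv[1L], iv[2L]),
                            signal_window(fsig$Fy, iv[1L], iv[2L]),
                            s$calibration, frame)
    vis <- c(peak_pos(dec$Fo), peak_neg(dec$Fo), peak_to_peak(dec$Fo),
             peak_pos(dec$Ft), peak_neg(dec$Ft), peak_to_peak(dec$Ft))
    mot <- vapply(msig, peak_to_peak, numeric(1), interval = iv)
    out[[k]] <- metric_rows(s, cyc$stitch_index, metric_vocabulary(),
                            c(ftv, vis, mot, cn[k]))
  }
  dplyr::bind_rows(out)
}

#' Extract metrics from a list of sessions
#' @param sessions List of [suture_session()] objects.
#' @param ... Passed to [session_metrics()].
#' @return Combined long-format tibble.
#' @export
cohort_metrics <- function(sessions, ...) {
  dplyr::bind_rows(lapply(sessions, session_metrics, ...))
}
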