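#' Uniformly sampled scalar signal
#'
#' The elementary container for one sensor channel: samples on a uniform time
#' grid, where sample `k` (0-based) is taken at `t0 + k / rate` seconds.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, seconds on the shared session clock.
#' @param name Channel label (e.g. `"Fz"`).
#' @param unit Physical unit string (e.g. `"N"`).
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, rate, t0 = 0, name = "signal", unit = "") {
  values <- as.numeric(values)
  if (!is_scalar_number(rate) || rate <= 0)
    abort_validation("sampling rate must be a positive finite scalar")
  if (!is_scalar_number(t0))
    abort_validation("t0 must be a finite scalar")
  if (length(values) < 1L)
    abort_validation("channel '%s' has no samples", name)
  if (!all(is.finite(values)))
    abort_validation("channel '%s' contains non-finite samples", name)
  structure(list(name = as.character(name), unit = as.character(unit),
                 t0 = as.numeric(t0), rate = as.numeric(rate),
                 values = values),
            class = "sampled_signal")
}

#' Sample timestamps of a signal
#' @param x A [sampled_signal()].
#' @return Numeric vector of times, seconds.
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$rate

# End of the half-open span [t0, t0 + n/rate) covered by the signal.
signal_span_end <- function(x) x$t0 + length(x$values) / x$rate

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s [%s], %d samples @ %g Hz, t0 = %g s\n",
              x$name, x$unit, length(x$values), x$rate, x$t0))
  invisible(x)
}

channel_unit <- function(ch) {
  switch(ch,
         Fx = , Fy = , Fz = "N",
         Tx = , Ty = , Tz = "N.m",
         yaw = , pitch = , roll = "deg",
         contact = "",
         "")
}

new_stream <- function(channels, rate, t0, class) {
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    abort_validation("all channels of a %s must have the same length", class)
  if (!is_scalar_number(rate) || rate <= 0)
    abort_validation("stream rate must be a positive finite scalar")
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!all(is.finite(v)))
      abort_validation("channel '%s' contains non-finite samples", nm)
    channels[[nm]] <- as.numeric(v)
  }
  structure(list(t0 = as.numeric(t0), rate = as.numeric(rate),
                 channels = channels),
            class = c(class, "sensor_stream"))
}

#' Six-channel force/torque stream
#'
#' Forces in newtons, torques in newton-meters, all channels on one grid
#' (nominally 1 kHz). The +z axis points upward out of the membrane, so
#' positive `Fz` is force applied upward on the membrane.
#'
#' @param Fx,Fy,Fz Force samples (N).
#' @param Tx,Ty,Tz Torque samples (N.m).
#' @param rate Common sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @return A `force_stream` object.
#' @export
force_stream <- function(Fx, Fy, Fz, Tx, Ty, Tz, rate = 1000, t0 = 0) {
  new_stream(list(Fx = Fx, Fy = Fy, Fz = Fz, Tx = Tx, Ty = Ty, Tz = Tz),
             rate, t0, "force_stream")
}

#' Three-channel wrist-orientation stream
#'
#' Yaw/pitch/roll in degrees on one grid (nominally 200 Hz). Pitch is
#' restricted to \[-90, 90\], yaw and roll to (-180, 180\].
#'
#' @param yaw,pitch,roll Angle samples, degrees.
#' @param rate Common sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @return A `motion_stream` object.
#' @export
motion_stream <- function(yaw, pitch, roll, rate = 200, t0 = 0) {
  if (any(pitch < -90 | pitch > 90))
    abort_validation("pitch samples must lie in [-90, 90] degrees")
  for (nm in c("yaw", "roll")) {
    v <- get(nm)
    if (any(v <= -180 | v > 180))
      abort_validation("%s samples must lie in (-180, 180] degrees", nm)
  }
  new_stream(list(yaw = yaw, pitch = pitch, roll = roll),
             rate, t0, "motion_stream")
}

#' Binary touch-contact stream
#'
#' @param contact Samples in \{0, 1\}: 1 while the subject contacts the
#'   platform, 0 otherwise.
#' @param rate Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @return A `touch_stream` object.
#' @export
touch_stream <- function(contact, rate = 100, t0 = 0) {
  if (!all(contact %in% c(0, 1)))
    abort_validation("touch contact samples must be 0 or 1")
  new_stream(list(contact = contact), rate, t0, "touch_stream")
}

#' Extract one channel of a stream as a [sampled_signal()]
#' @param stream A sensor stream.
#' @param channel Channel name, e.g. `"Fz"`.
#' @return A `sampled_signal`.
#' @export
stream_signal <- function(stream, channel) {
  if (!channel %in% names(stream$channels))
    abort_validation("stream has no channel '%s'", channel)
  sampled_signal(stream$channels[[channel]], stream$rate, stream$t0,
                 name = channel, unit = channel_unit(channel))
}

stream_length <- function(stream) length(stream$channels[[1L]])
stream_span_end <- function(stream) stream$t0 + stream_length(stream) / stream$rate

#' Sensor-to-vision calibration
#'
#' Unit vectors giving the force-sensor x and y axes expressed in the vision
#' (camera) coordinate frame. Precomputed once per rig by a calibration
#' experiment; constant across stitches.
#'
#' @param e_x,e_y Numeric 2-vectors, unit norm within 1e-9.
#' @return A `calibration` object.
#' @export
calibration <- function(e_x, e_y) {
  e_x <- as.numeric(e_x); e_y <- as.numeric(e_y)
  if (length(e_x) != 2L || length(e_y) != 2L)
    abort_validation("calibration vectors must have length 2")
  if (abs(sqrt(sum(e_x^2)) - 1) > 1e-9 || abs(sqrt(sum(e_y^2)) - 1) > 1e-9)
    abort_validation("calibration vectors must be unit norm within 1e-9")
  det <- e_x[1] * e_y[2] - e_x[2] * e_y[1]
  if (abs(det) <= 1e-6)
    abort_validation("calibration matrix is singular (|det| <= 1e-6)")
  structure(list(e_x = e_x, e_y = e_y), class = "calibration")
}

#' Rotation calibration helper
#' @param angle_deg Rotation of the sensor frame relative to the vision frame,
#'   degrees counter-clockwise.
#' @return A [calibration()].
#' @export
rotation_calibration <- function(angle_deg) {
  a <- angle_deg * pi / 180
  calibration(c(cos(a), sin(a)), c(-sin(a), cos(a)))
}

#' Validate a table of per-stitch event annotations
#'
#' One row per stitch, temporally ordered, carrying the vision-derived event
#' times (needle entry, needle-tip exit, complete pull-out, optionally thread
#' entry) and the entry/exit points in the vision frame.
#'
#' @param df data.frame with columns `stitch_index`, `t_entry`, `t_exit`,
#'   `t_pullout`, `entry_u`, `entry_v`, `exit_u`, `exit_v` and optionally
#'   `t_thread` (NA when not annotated).
#' @return The validated data.frame (with a `t_thread` column added if absent).
#' @export
stitch_annotations <- function(df) {
  req <- c("stitch_index", "t_entry", "t_exit", "t_pullout",
           "entry_u", "entry_v", "exit_u", "exit_v")
  miss <- setdiff(req, names(df))
  if (length(miss))
    abort_validation("stitch annotations lack column(s): %s",
                     paste(miss, collapse = ", "))
  if (!"t_thread" %in% names(df)) df$t_thread <- NA_real_
  df <- as.data.frame(df)[c(req, "t_thread")]
  n <- nrow(df)
  if (n < 1L) abort_validation("at least one stitch annotation is required")
  if (any(df$stitch_index != round(df$stitch_index)) ||
      any(df$stitch_index < 1 | df$stitch_index > 12))
    abort_validation("stitch_index must be an integer clock position in 1..12")
  for (k in seq_len(n)) {
    if (!(df$t_entry[k] < df$t_exit[k] && df$t_exit[k] < df$t_pullout[k]))
      abort_validation(
        "stitch %d: event times must satisfy t_entry < t_exit < t_pullout",
        df$stitch_index[k])
    if (df$entry_u[k] == df$exit_u[k] && df$entry_v[k] == df$exit_v[k])
      abort_validation("stitch %d: entry and exit points coincide",
                       df$stitch_index[k])
    tt <- df$t_thread[k]
    if (!is.na(tt) && !(tt >= df$t_exit[k] && tt <= df$t_pullout[k]))
      abort_validation("stitch %d: t_thread must lie in [t_exit, t_pullout]",
                       df$stitch_index[k])
  }
  if (n > 1L && any(df$t_pullout[-n] >= df$t_entry[-1L]))
    abort_validation("stitch annotations overlap: t_pullout(k) must precede t_entry(k+1)")
  df
}

#' Assemble and validate a suturing session
#'
#' One session is one subject suturing the full 12-stitch clock face at one
#' membrane depth, with all sensor streams on a shared clock starting at 0.
#'
#' @param subject_id Character scalar.
#' @param group `"attending"` or `"resident"`.
#' @param depth `"surface"` (membrane at cavity top) or `"depth"` (recessed).
#' @param force A [force_stream()].
#' @param motion A [motion_stream()].
#' @param touch A [touch_stream()].
#' @param stitches A [stitch_annotations()] table.
#' @param calibration A [calibration()].
#' @param provenance List; free-text `text` and/or integer `seed` for
#'   synthetic sessions.
#' @return A `suture_session` object.
#' @export
suture_session <- function(subject_id, group, depth, force, motion, touch,
                           stitches, calibration, provenance = list()) {
  s <- structure(list(subject_id = as.character(subject_id),
                      group = group, depth = depth,
                      force = force, motion = motion, touch = touch,
                      stitches = stitch_annotations(stitches),
                      calibration = calibration,
                      provenance = provenance),
                 class = "suture_session")
  validate_session(s)
}

#' Validate all session invariants
#' @param s A `suture_session`.
#' @return `s`, invisibly re-validated.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "suture_session"))
    abort_validation("not a suture_session object")
  if (!s$group %in% c("attending", "resident"))
    abort_validation("group must be 'attending' or 'resident'")
  if (!s$depth %in% c("surface", "depth"))
    abort_validation("depth must be 'surface' or 'depth'")
  if (!inherits(s$force, "force_stream") ||
      !inherits(s$motion, "motion_stream") ||
      !inherits(s$touch, "touch_stream"))
    abort_validation("force/motion/touch streams have the wrong type")
  if (!inherits(s$calibration, "calibration"))
    abort_validation("calibration record has the wrong type")
  s$stitches <- stitch_annotations(s$stitches)
  t_lo <- min(s$stitches$t_entry); t_hi <- max(s$stitches$t_pullout)
  for (nm in c("force", "motion", "touch")) {
    st <- s[[nm]]
    if (t_lo < st$t0 || t_hi > stream_span_end(st))
      abort_validation("stitch event times fall outside the %s stream span", nm)
  }
  s
}

#' @export
print.suture_session <- function(x, ...) {
  cat(sprintf(paste0("<suture_session> subject %s (%s, %s): %d stitches, ",
                     "force %d @ %g Hz, motion %d @ %g Hz, touch %d @ %g Hz\n"),
              x$subject_id, x$group, x$depth, nrow(x$stitches),
              stream_length(x$force), x$force$rate,
              stream_length(x$motion), x$motion$rate,
              stream_length(x$touch), x$touch$rate))
  invisible(x)
}
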