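# Synthetic-bench generator: cohorts of sessions with the statistical
# structure the analysis assumes — phase-structured force bumps,
# skill-dependent amplitudes, stitch-aligned horizontal forces mapped through
# the rig calibration, bounded wrist sweeps, sparse touch contacts — plus
# exact per-stitch ground truth for recovery testing.
#
# Timing model per stitch (fractions of the drawn active time T):
#   entry bump (downward Fz)   [0, 0.30 T]
#   driving window (Fo/Ft/Tz+) [0.25 T, 0.70 T]
#   needle-tip exit event      0.60 T
#   pull-out bump (upward Fz, Tz-) [0.65 T, T]
# Event times are snapped to a 10 ms grid (common multiple of the force,
# motion and touch sampling periods) and every bump window to an odd sample
# count, so noise-free ground truth is recovered to machine precision.

TOUCH_PULSE_S <- 0.05  # contact dwell per touch event

#' Per-group simulator parameterization
#'
#' Each amplitude/duration parameter is a `(mean, sd)` pair, drawn per stitch
#' from a normal truncated at zero. Amplitudes are bump peak heights; ranges
#' are wrist sweep extents during active time; `touch_rate` is the expected
#' Poisson count of contacts per suture cycle.
#'
#' @param A_push,A_pull Downward puncture / upward pull-out force amplitude, N.
#' @param A_o,A_t Orthogonal / tangential horizontal force amplitude, N.
#' @param A_Tz z-torque amplitude, N.m (applied with both signs: driving
#'   twist and pull-out untwist).
#' @param R_yaw,R_pitch,R_roll Wrist sweep ranges, degrees.
#' @param touch_rate Expected contacts per cycle.
#' @param t_active,t_idle Active / idle durations, s.
#' @param sigma_F,sigma_T,sigma_theta Additive white measurement-noise sd for
#'   force (N), torque (N.m) and orientation (deg) channels.
#' @return A `skill_preset` object.
#' @export
skill_preset <- function(A_push = c(3.0, 0.5), A_pull = c(2.0, 0.4),
                         A_o = c(1.0, 0.25), A_t = c(1.0, 0.25),
                         A_Tz = c(0.05, 0.012),
                         R_yaw = c(40, 8), R_pitch = c(30, 6),
                         R_roll = c(60, 12),
                         touch_rate = 1.0,
                         t_active = c(5, 0.8), t_idle = c(3, 0.5),
                         sigma_F = 0.05, sigma_T = 5e-4, sigma_theta = 0.5) {
  p <- list(A_push = A_push, A_pull = A_pull, A_o = A_o, A_t = A_t,
            A_Tz = A_Tz, R_yaw = R_yaw, R_pitch = R_pitch, R_roll = R_roll,
            touch_rate = touch_rate, t_active = t_active, t_idle = t_idle,
            sigma_F = sigma_F, sigma_T = sigma_T, sigma_theta = sigma_theta)
  for (nm in c("A_push", "A_pull", "A_o", "A_t", "A_Tz",
               "R_yaw", "R_pitch", "R_roll", "t_active", "t_idle")) {
    v <- p[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] < 0 || v[2] < 0)
      abort_validation("preset field %s must be c(mean >= 0, sd >= 0)", nm)
  }
  for (nm in c("touch_rate", "sigma_F", "sigma_T", "sigma_theta"))
    if (!is_scalar_number(p[[nm]]) || p[[nm]] < 0)
      abort_validation("preset field %s must be a nonnegative scalar", nm)
  structure(p, class = "skill_preset")
}

#' Default resident preset
#' @return A [skill_preset()].
#' @export
skill_preset_resident <- function() skill_preset()

#' Default attending preset
#'
#' Derived from the resident preset by the default effect ratios: 0.6 on
#' puncture/pull-out force, orthogonal force, z-torque, yaw/roll sweep and
#' touch rate; 1.3 on tangential force. Pitch sweep, durations and noise are
#' shared. The orthogonal and tangential resident means are equal by design,
#' so the group difference largely cancels in the sensor x/y channels (which
#' mix the two by stitch direction) while remaining fully visible in the
#' stitch frame.
#'
#' @return A [skill_preset()].
#' @export
skill_preset_attending <- function() {
  r <- skill_preset_resident()
  skill_preset(A_push = r$A_push * c(0.6, 1), A_pull = r$A_pull * c(0.6, 1),
               A_o = r$A_o * c(0.6, 1), A_t = r$A_t * c(1.3, 1),
               A_Tz = r$A_Tz * c(0.6, 1),
               R_yaw = r$R_yaw * c(0.6, 1), R_pitch = r$R_pitch,
               R_roll = r$R_roll * c(0.6, 1),
               touch_rate = r$touch_rate * 0.6,
               t_active = r$t_active, t_idle = r$t_idle,
               sigma_F = r$sigma_F, sigma_T = r$sigma_T,
               sigma_theta = r$sigma_theta)
}

#' Clock-face membrane geometry
#'
#' The radial suturing task: a circular "incision" on the membrane with 12
#' needle-entry marks on radial lines spaced 30 degrees apart (a clock face).
#' Stitches cross the incision radially inward.
#'
#' @param center Circle center, vision-frame units.
#' @param r_entry Radius of the entry marks.
#' @param r_exit Radius of the exit points (inside the incision).
#' @return A `membrane_geometry` object.
#' @export
membrane_geometry <- function(center = c(0, 0), r_entry = 45, r_exit = 25) {
  if (r_entry <= 0 || r_exit <= 0 || r_entry == r_exit)
    abort_validation("entry and exit radii must be positive and distinct")
  structure(list(center = as.numeric(center), r_entry = r_entry,
                 r_exit = r_exit), class = "membrane_geometry")
}

# Clock hours in suturing order: start at 10 o'clock, proceed
# counter-clockwise at each hour. Hour h sits at angle 90 - 30 h degrees.
clock_hours <- function() c(10:1, 12, 11)

snap10ms <- function(t) round(t * 100) / 100

# Truncated-normal draw (truncation at 0) via inverse CDF; sd = 0 degenerates
# to the mean.
rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

# Add a raised-cosine bump of peak `amp` to `values` in place-ish: window
# starts at t_start, lasts `dur`, snapped to the signal grid with an odd
# sample count so the peak lands exactly on a sample.
add_bump <- function(values, rate, t_start, dur, amp) {
  i0 <- round(t_start * rate) + 1
  m <- round(dur * rate) + 1
  if (m %% 2 == 0) m <- m + 1
  if (m < 5) abort_validation("bump window too short (%g s at %g Hz)", dur, rate)
  if (i0 < 1 || i0 + m - 1 > length(values))
    abort_validation("bump window falls outside the signal span")
  k <- seq_len(m) - 1
  values[i0:(i0 + m - 1)] <- values[i0:(i0 + m - 1)] +
    amp * sin(pi * k / (m - 1))^2
  values
}

place_touches <- function(n_events, i_lo, i_hi, pulse_len) {
  # choose non-overlapping pulse start indices in [i_lo, i_hi - pulse_len],
  # separated by at least one zero sample; rejection with a bounded retry
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n_events && tries < 200L) {
    cand <- i_lo + floor(stats::runif(1) * (i_hi - pulse_len - i_lo + 1))
    if (!length(starts) ||
        all(abs(starts - cand) > pulse_len)) starts <- c(starts, cand)
    tries <- tries + 1L
  }
  sort(starts)
}

#' Generate one synthetic session with ground truth
#'
#' Synthesizes all sensor streams for one subject at one depth: 12 radial
#' stitches (clock face, 30-degree spacing, sutured counter-clockwise from 10
#' o'clock), phase-structured z-force bumps (downward puncture, upward
#' pull-out), stitch-frame orthogonal/tangential horizontal bumps mapped to
#' sensor x/y through the inverse calibration, bipolar z-torque, smooth wrist
#' sweeps during active time, Poisson touch contacts, and additive white
#' Gaussian measurement noise.
#'
#' @param preset A [skill_preset()].
#' @param subject_id,group,depth Session identity.
#' @param seed Integer RNG seed (mandatory; sessions are reproducible).
#' @param geometry A [membrane_geometry()].
#' @param cal A [calibration()]; defaults to a 20-degree rotation so tests
#'   never silently assume identity calibration.
#' @param n_stitches Number of stitches (default 12; entry marks are placed
#'   at the first `n_stitches` clock positions).
#' @param rate_force,rate_motion,rate_touch Sampling rates, Hz.
#' @return List with `session` (a [suture_session()]) and `truth` (list with
#'   `seed` and a per-stitch data.frame of every drawn amplitude, range,
#'   contact count and event time).
#' @export
generate_session <- function(preset, subject_id, group, depth, seed,
                             geometry = membrane_geometry(),
                             cal = rotation_calibration(20),
                             n_stitches = 12,
                             rate_force = 1000, rate_motion = 200,
                             rate_touch = 100) {
  if (!inherits(preset, "skill_preset"))
    abort_validation("preset must be a skill_preset")
  if (!is_scalar_number(seed)) abort_validation("a numeric seed is required")
  if (n_stitches < 1 || n_stitches > 12)
    abort_validation("n_stitches must be in 1..12")
  withr::with_seed(as.integer(seed), {
    n <- n_stitches
    T_act <- snap10ms(rtrunc0(n, preset$t_active[1], preset$t_active[2]))
    T_idle <- snap10ms(rtrunc0(n, preset$t_idle[1], preset$t_idle[2]))
    if (any(T_act < 0.5))
      abort_validation("drawn active time below 0.5 s; phase windows degenerate")
    if (any(T_idle < 0.2))
      abort_validation("drawn idle time below 0.2 s")
    lead_in <- 2
    t_entry <- lead_in + c(0, cumsum((T_act + T_idle)[-n]))
    t_pullout <- t_entry + T_act
    t_exit <- snap10ms(t_entry + 0.6 * T_act)
    duration <- ceiling((t_pullout[n] + 2) * 10) / 10
    # amplitude draws (per stitch)
    draw <- function(f) rtrunc0(n, f[1], f[2])
    A_push <- draw(preset$A_push); A_pull <- draw(preset$A_pull)
    A_o <- draw(preset$A_o); A_t <- draw(preset$A_t)
    A_Tz_drive <- draw(preset$A_Tz); A_Tz_pull <- draw(preset$A_Tz)
    R_yaw <- draw(preset$R_yaw); R_pitch <- draw(preset$R_pitch)
    R_roll <- draw(preset$R_roll)
    # geometry: entry/exit points per clock position, stitched radially inward
    hours <- clock_hours()[seq_len(n)]
    ang <- (90 - 30 * hours) * pi / 180
    dir <- cbind(cos(ang), sin(ang))
    entry <- sweep(geometry$r_entry * dir, 2, geometry$center, "+")
    exit <- sweep(geometry$r_exit * dir, 2, geometry$center, "+")
    # force/torque channels
    nf <- round(duration * rate_force)
    Fx <- Fy <- Fz <- Tz <- numeric(nf)
    M_xy <- cbind(cal$e_x, cal$e_y)
    for (k in seq_len(n)) {
      Fz <- add_bump(Fz, rate_force, t_entry[k], 0.30 * T_act[k], -A_push[k])
      Fz <- add_bump(Fz, rate_force, t_pullout[k] - 0.35 * T_act[k],
                     0.35 * T_act[k], A_pull[k])
      drive0 <- t_entry[k] + 0.25 * T_act[k]
      driveT <- 0.45 * T_act[k]
      fo <- add_bump(numeric(nf), rate_force, drive0, driveT, A_o[k])
      ft <- add_bump(numeric(nf), rate_force, drive0, driveT, A_t[k])
      e_t <- (exit[k, ] - entry[k, ]) / sqrt(sum((exit[k, ] - entry[k, ])^2))
      e_o <- c(-e_t[2], e_t[1])
      # vision-frame horizontal force, then sensor frame via Eq.-style inverse
      idx <- which(fo != 0 | ft != 0)
      if (length(idx)) {
        Fvis <- rbind(fo[idx], ft[idx])
        Fsen <- solve(M_xy, cbind(e_o, e_t) %*% Fvis)
        Fx[idx] <- Fx[idx] + Fsen[1, ]
        Fy[idx] <- Fy[idx] + Fsen[2, ]
      }
      Tz <- add_bump(Tz, rate_force, drive0, driveT, A_Tz_drive[k])
      Tz <- add_bump(Tz, rate_force, t_pullout[k] - 0.35 * T_act[k],
                     0.35 * T_act[k], -A_Tz_pull[k])
    }
    Tx <- Ty <- numeric(nf)
    if (preset$sigma_F > 0) {
      Fx <- Fx + stats::rnorm(nf, 0, preset$sigma_F)
      Fy <- Fy + stats::rnorm(nf, 0, preset$sigma_F)
      Fz <- Fz + stats::rnorm(nf, 0, preset$sigma_F)
    }
    if (preset$sigma_T > 0) {
      Tx <- Tx + stats::rnorm(nf, 0, preset$sigma_T)
      Ty <- Ty + stats::rnorm(nf, 0, preset$sigma_T)
      Tz <- Tz + stats::rnorm(nf, 0, preset$sigma_T)
    }
    # wrist orientation: smooth sweep of the drawn range during active time
    nm <- round(duration * rate_motion)
    yaw <- rep(-10, nm); pitch <- rep(-20, nm); roll <- rep(-30, nm)
    for (k in seq_len(n)) {
      yaw <- add_bump(yaw, rate_motion, t_entry[k], T_act[k], R_yaw[k])
      pitch <- add_bump(pitch, rate_motion, t_entry[k], T_act[k], R_pitch[k])
      roll <- add_bump(roll, rate_motion, t_entry[k], T_act[k], R_roll[k])
    }
    if (preset$sigma_theta > 0) {
      yaw <- yaw + stats::rnorm(nm, 0, preset$sigma_theta)
      pitch <- pitch + stats::rnorm(nm, 0, preset$sigma_theta)
      roll <- roll + stats::rnorm(nm, 0, preset$sigma_theta)
    }
    pitch <- pmin(pmax(pitch, -90), 90)
    # touch contacts: Poisson count per cycle, 50 ms pulses
    nt <- round(duration * rate_touch)
    contact <- numeric(nt)
    pulse_len <- round(TOUCH_PULSE_S * rate_touch)
    n_touch <- integer(n)
    for (k in seq_len(n)) {
      lo <- round(t_entry[k] * rate_touch) + 2          # edge strictly inside
      hi <- if (k < n) round(t_entry[k + 1] * rate_touch)
            else round(t_pullout[k] * rate_touch)
      want <- stats::rpois(1, preset$touch_rate)
      starts <- place_touches(want, lo, hi, pulse_len)
      for (s0 in starts) contact[s0:(s0 + pulse_len - 1)] <- 1
      n_touch[k] <- length(starts)
    }
    stitches <- data.frame(stitch_index = hours,
                           t_entry = t_entry, t_exit = t_exit,
                           t_pullout = t_pullout,
                           entry_u = entry[, 1], entry_v = entry[, 2],
                           exit_u = exit[, 1], exit_v = exit[, 2],
                           t_thread = NA_real_)
    session <- suture_session(
      subject_id = subject_id, group = group, depth = depth,
      force = force_stream(Fx, Fy, Fz, Tx, Ty, Tz, rate = rate_force),
      motion = motion_stream(yaw, pitch, roll, rate = rate_motion),
      touch = touch_stream(contact, rate = rate_touch),
      stitches = stitches, calibration = cal,
      provenance = list(seed = as.integer(seed), text = "synthetic"))
    truth <- list(seed = as.integer(seed),
                  stitches = data.frame(
                    stitch_index = hours,
                    t_entry = t_entry, t_exit = t_exit, t_pullout = t_pullout,
                    A_push = A_push, A_pull = A_pull, A_o = A_o, A_t = A_t,
                    A_Tz_drive = A_Tz_drive, A_Tz_pull = A_Tz_pull,
                    R_yaw = R_yaw, R_pitch = R_pitch, R_roll = R_roll,
                    n_touches = n_touch))
    list(session = session, truth = truth)
  })
}

#' Cohort configuration
#'
#' @param n_attending,n_resident Subjects per group (>= 1).
#' @param depths Depth conditions to simulate for every subject.
#' @param preset_attending,preset_resident Group presets.
#' @param geometry A [membrane_geometry()].
#' @param cal A [calibration()] shared by all sessions (one physical rig).
#' @param seed Global seed; per-session seeds are derived deterministically.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_attending = 5, n_resident = 7,
                          depths = c("surface", "depth"),
                          preset_attending = skill_preset_attending(),
                          preset_resident = skill_preset_resident(),
                          geometry = membrane_geometry(),
                          cal = rotation_calibration(20),
                          seed) {
  if (missing(seed) || !is_scalar_number(seed))
    abort_validation("cohort_config requires a numeric seed (reproducibility is mandatory)")
  if (n_attending < 1 || n_resident < 1)
    abort_validation("each group needs at least one subject")
  if (!all(depths %in% c("surface", "depth")) || !length(depths))
    abort_validation("depths must be drawn from 'surface', 'depth'")
  structure(list(n_attending = n_attending, n_resident = n_resident,
                 depths = depths, preset_attending = preset_attending,
                 preset_resident = preset_resident, geometry = geometry,
                 cal = cal, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' One session per subject and depth condition, with per-session seeds derived
#' deterministically from the global seed: the same configuration and seed
#' reproduce the cohort bit for bit.
#'
#' @param config A [cohort_config()].
#' @return List of `list(session, truth)` entries, attendings first.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    abort_validation("config must be a cohort_config")
  subjects <- rbind(
    data.frame(id = sprintf("att%02d", seq_len(config$n_attending)),
               group = "attending",
               preset = "preset_attending", stringsAsFactors = FALSE),
    data.frame(id = sprintf("res%02d", seq_len(config$n_resident)),
               group = "resident",
               preset = "preset_resident", stringsAsFactors = FALSE))
  if (anyDuplicated(subjects$id))
    abort_validation("duplicate subject_ids in cohort")
  out <- list()
  unit <- 0L
  for (i in seq_len(nrow(subjects))) {
    for (d in config$depths) {
      unit <- unit + 1L
      out[[length(out) + 1L]] <- generate_session(
        preset = config[[subjects$preset[i]]],
        subject_id = subjects$id[i], group = subjects$group[i], depth = d,
        seed = derive_seed(config$seed, unit),
        geometry = config$geometry, cal = config$cal)
    }
  }
  out
}
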