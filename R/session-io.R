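# On-disk session format: a directory with force.csv, motion.csv, touch.csv,
# events.json, calibration.json, session.json. CSVs carry a header row and a
# time column; JSON records use fixed key order so identical sessions produce
# byte-identical files.

SESSION_FILES <- c("force.csv", "motion.csv", "touch.csv",
                   "events.json", "calibration.json", "session.json")

write_stream_csv <- function(stream, path) {
  t <- stream$t0 + (seq_len(stream_length(stream)) - 1) / stream$rate
  cols <- c(list(t = t), stream$channels)
  txt <- do.call(paste, c(lapply(cols, fmt_num), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(cols), collapse = ","), txt), con, sep = "\n")
}

json_write <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                              null = "null"),
             con, sep = "\n")
}

#' Write a session directory
#'
#' Emits the canonical on-disk layout (`force.csv`, `motion.csv`, `touch.csv`,
#' `events.json`, `calibration.json`, `session.json`). Numeric fields are
#' written with 15 significant digits, so a write/read round trip is lossless
#' well below 1e-12 relative, and field order and formatting are fixed, so two
#' writes of the same session are byte-identical.
#'
#' @param s A validated [suture_session()].
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    abort_validation("cannot create session directory '%s'", path)
  write_stream_csv(s$force, file.path(path, "force.csv"))
  write_stream_csv(s$motion, file.path(path, "motion.csv"))
  write_stream_csv(s$touch, file.path(path, "touch.csv"))
  ev <- lapply(seq_len(nrow(s$stitches)), function(k) {
    r <- s$stitches[k, ]
    rec <- list(stitch_index = as.integer(r$stitch_index),
                t_entry = r$t_entry, t_exit = r$t_exit,
                t_pullout = r$t_pullout,
                entry_point = c(r$entry_u, r$entry_v),
                exit_point = c(r$exit_u, r$exit_v))
    if (!is.na(r$t_thread)) rec$t_thread <- r$t_thread
    rec
  })
  json_write(ev, file.path(path, "events.json"))
  json_write(list(e_x = s$calibration$e_x, e_y = s$calibration$e_y),
             file.path(path, "calibration.json"))
  meta <- list(subject_id = s$subject_id, group = s$group, depth = s$depth,
               duration_s = stream_length(s$force) / s$force$rate,
               rates = list(force = s$force$rate, motion = s$motion$rate,
                            touch = s$touch$rate),
               units = list(force = "N", torque = "N.m", angle = "deg"))
  if (!is.null(s$provenance$seed)) meta$seed <- s$provenance$seed
  if (!is.null(s$provenance$text)) meta$provenance <- s$provenance$text
  json_write(meta, file.path(path, "session.json"))
  invisible(path)
}

read_stream_csv <- function(path, expected_cols, declared_rate, duration_s) {
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (!identical(names(df), expected_cols))
    abort_validation("%s: expected columns %s", basename(path),
                     paste(expected_cols, collapse = ","))
  n <- nrow(df)
  expected_n <- declared_rate * duration_s
  if (abs(n - expected_n) > 0.001 * expected_n)
    abort_validation(
      "%s: %d rows but session.json declares %g s at %g Hz (%g rows, >0.1%% off)",
      basename(path), n, duration_s, declared_rate, expected_n)
  t0 <- df$t[1L]
  grid <- t0 + (seq_len(n) - 1) / declared_rate
  if (max(abs(df$t - grid)) > 1e-6)
    abort_validation("%s: time column deviates from a uniform %g Hz grid (gap or jitter)",
                     basename(path), declared_rate)
  list(t0 = t0, data = df)
}

#' Read and validate a session directory
#'
#' Reads the layout written by [write_session()], cross-checking declared
#' sampling rates against row counts (0.1% tolerance), the uniformity of every
#' time grid, and all data-model invariants. Any violation raises a typed
#' validation error; a missing file raises a missing-component error naming it.
#'
#' @param path Session directory.
#' @return A validated [suture_session()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path))
    abort_missing_file("session directory '%s' does not exist", path)
  for (f in SESSION_FILES)
    if (!file.exists(file.path(path, f)))
      abort_missing_file("missing session component: %s", f)
  meta <- jsonlite::read_json(file.path(path, "session.json"))
  for (f in c("subject_id", "group", "depth", "duration_s", "rates", "units"))
    if (is.null(meta[[f]]))
      abort_validation("session.json lacks field '%s'", f)
  u <- meta$units
  if (!identical(u$force, "N") || !identical(u$torque, "N.m") ||
      !identical(u$angle, "deg"))
    abort_validation(
      "unsupported units: this pipeline requires N / N.m / deg (no conversion layer)")
  dur <- as.numeric(meta$duration_s)
  fr <- read_stream_csv(file.path(path, "force.csv"),
                        c("t", "Fx", "Fy", "Fz", "Tx", "Ty", "Tz"),
                        as.numeric(meta$rates$force), dur)
  mo <- read_stream_csv(file.path(path, "motion.csv"),
                        c("t", "yaw", "pitch", "roll"),
                        as.numeric(meta$rates$motion), dur)
  to <- read_stream_csv(file.path(path, "touch.csv"), c("t", "contact"),
                        as.numeric(meta$rates$touch), dur)
  ev <- jsonlite::read_json(file.path(path, "events.json"))
  stitches <- do.call(rbind, lapply(ev, function(r) {
    data.frame(stitch_index = r$stitch_index,
               t_entry = r$t_entry, t_exit = r$t_exit, t_pullout = r$t_pullout,
               entry_u = r$entry_point[[1]], entry_v = r$entry_point[[2]],
               exit_u = r$exit_point[[1]], exit_v = r$exit_point[[2]],
               t_thread = if (is.null(r$t_thread)) NA_real_ else r$t_thread)
  }))
  cal <- jsonlite::read_json(file.path(path, "calibration.json"),
                             simplifyVector = TRUE)
  prov <- list()
  if (!is.null(meta$seed)) prov$seed <- meta$seed
  if (!is.null(meta$provenance)) prov$text <- meta$provenance
  suture_session(
    subject_id = meta$subject_id, group = meta$group, depth = meta$depth,
    force = force_stream(fr$data$Fx, fr$data$Fy, fr$data$Fz,
                         fr$data$Tx, fr$data$Ty, fr$data$Tz,
                         rate = as.numeric(meta$rates$force), t0 = fr$t0),
    motion = motion_stream(mo$data$yaw, mo$data$pitch, mo$data$roll,
                           rate = as.numeric(meta$rates$motion), t0 = mo$t0),
    touch = touch_stream(to$data$contact,
                         rate = as.numeric(meta$rates$touch), t0 = to$t0),
    stitches = stitches,
    calibration = calibration(cal$e_x, cal$e_y),
    provenance = prov)
}
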