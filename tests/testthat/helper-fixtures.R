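# Shared fixtures and independent oracles for the test suite.

# Short-session preset: same structure as the defaults but quick to simulate.
fast_preset <- function(t_active = c(1.5, 0.2), t_idle = c(0.8, 0.1), ...) {
  skill_preset(t_active = t_active, t_idle = t_idle, ...)
}

fast_attending <- function() {
  r <- fast_preset()
  skill_preset(A_push = r$A_push * c(0.6, 1), A_pull = r$A_pull * c(0.6, 1),
               A_o = r$A_o * c(0.6, 1), A_t = r$A_t * c(1.3, 1),
               A_Tz = r$A_Tz * c(0.6, 1),
               R_yaw = r$R_yaw * c(0.6, 1), R_pitch = r$R_pitch,
               R_roll = r$R_roll * c(0.6, 1),
               touch_rate = r$touch_rate * 0.6,
               t_active = r$t_active, t_idle = r$t_idle)
}

tiny_session <- function(seed = 11, preset = fast_preset(), ...) {
  generate_session(preset, subject_id = paste0("s", seed),
                   group = "resident", depth = "surface", seed = seed, ...)
}

# --- Independent brute-force oracles (naive loops, same quadrature rule) ----

oracle_peak_pos <- function(v) {
  m <- -Inf
  for (x in v) if (x > m) m <- x
  m
}

oracle_peak_neg <- function(v) {
  m <- Inf
  for (x in v) if (x < m) m <- x
  -m
}

oracle_int_abs <- function(v, dt) {
  s <- 0
  for (k in seq_len(length(v) - 1L))
    s <- s + dt * (abs(v[k]) + abs(v[k + 1L])) / 2
  s
}

oracle_der <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  if (n > 2L) for (k in 2:(n - 1L)) d[k] <- (v[k + 1L] - v[k - 1L]) / (2 * dt)
  s <- 0
  for (k in seq_len(n - 1L)) s <- s + dt * (d[k]^2 + d[k + 1L]^2) / 2
  s
}

# Full enumeration of the rank-sum null (tie-free samples): two-sided
# probability of a rank sum at least as far from its null mean as observed.
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  W_obs <- sum(r[seq_len(nx)])
  EW <- nx * (length(pooled) + 1) / 2
  Ws <- utils::combn(length(pooled), nx, function(i) sum(r[i]))
  mean(abs(Ws - EW) >= abs(W_obs - EW) - 1e-9)
}

md5_of_dir <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)), basename(files))
}
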