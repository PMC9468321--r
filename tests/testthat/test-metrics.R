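sig <- function(v, rate = 10) sampled_signal(v, rate)

test_that("peak functionals match their definitions and edge cases", {
  x <- sig(c(1, -3, 2))
  expect_identical(peak_pos(x), 2)
  expect_identical(peak_neg(x), 3)
  expect_identical(peak_to_peak(x), 5)
  # the negated minimum is applied literally: negative for all-positive input
  expect_identical(peak_neg(sig(c(1, 2))), -1)
  expect_identical(peak_to_peak(sig(rep(4, 10))), 0)
  # sampled sinusoid peak within grid resolution
  t <- seq(0, 1, by = 1e-3)
  s <- sampled_signal(sin(2 * pi * t), 1000)
  expect_lt(abs(peak_pos(s) - 1), 1e-4)
})

test_that("functionals agree with brute-force oracles on random signals", {
  withr::local_seed(5)
  for (i in 1:300) {
    n <- sample(3:60, 1)
    rate <- stats::runif(1, 1, 2000)
    v <- rnorm(n, sd = stats::runif(1, 0.1, 10))
    x <- sampled_signal(v, rate)
    dt <- 1 / rate
    expect_equal(peak_pos(x), oracle_peak_pos(v), tolerance = 1e-9)
    expect_equal(peak_neg(x), oracle_peak_neg(v), tolerance = 1e-9)
    expect_equal(peak_to_peak(x), oracle_peak_pos(v) + oracle_peak_neg(v),
                 tolerance = 1e-9)
    expect_equal(int_abs(x), oracle_int_abs(v, dt), tolerance = 1e-9)
    expect_equal(der(x), oracle_der(v, dt), tolerance = 1e-9)
  }
})

test_that("integral functionals reproduce closed forms", {
  # trapezoid is exact for a linear integrand: ramp t on [0,1] -> 1/2
  n <- 1000
  ramp <- sampled_signal(seq(0, 1, length.out = n + 1), n)
  expect_equal(int_abs(ramp), 0.5, tolerance = 1e-6)
  # DER of a ramp with slope m over duration T is m^2 T (derivative exact)
  m <- -3.7; T <- 2
  r2 <- sampled_signal(m * seq(0, T, by = 1e-3), 1000)
  expect_equal(der(r2), m^2 * T, tolerance = 1e-6 * m^2 * T)
  # |sin| over [0, 2*pi] integrates to 4
  t <- seq(0, 2 * pi, length.out = 6284)
  s <- sampled_signal(sin(t), 1 / (t[2] - t[1]))
  expect_equal(int_abs(s), 4, tolerance = 0.001 * 4)
  # DER of sin(2 pi f t) over one period is 2 pi^2 f
  f <- 5
  ts <- seq(0, 1 / f, by = 1 / (200 * f))
  s2 <- sampled_signal(sin(2 * pi * f * ts), 200 * f)
  expect_equal(der(s2), 2 * pi^2 * f, tolerance = 0.005 * 2 * pi^2 * f)
})

test_that("stitch frames follow the +90 degree CCW convention", {
  fr <- stitch_frame(c(0, 0), c(1, 0))
  expect_equal(fr$e_t, c(1, 0))
  expect_equal(fr$e_o, c(0, 1))
  fr2 <- stitch_frame(c(0, 0), c(0, 2))
  expect_equal(fr2$e_t, c(0, 1))
  expect_equal(fr2$e_o, c(-1, 0))
  expect_error(stitch_frame(c(1, 1), c(1, 1)),
               class = "sutureskill_validation_error")
})

test_that("force decomposition solves the stated change of basis", {
  id <- calibration(c(1, 0), c(0, 1))
  one <- function(v) sampled_signal(v, 100)
  # stitch along +x: a pure x-force is tangential
  d <- decompose_forces(one(1), one(0), id, stitch_frame(c(0, 0), c(1, 0)))
  expect_equal(c(d$Fo$values, d$Ft$values), c(0, 1), tolerance = 1e-12)
  # stitch along +y: a pure x-force is orthogonal with negative sign
  d2 <- decompose_forces(one(1), one(0), id, stitch_frame(c(0, 0), c(0, 2)))
  expect_equal(c(d2$Fo$values, d2$Ft$values), c(-1, 0), tolerance = 1e-12)
})

test_that("orthonormal decomposition conserves the per-sample norm", {
  withr::local_seed(9)
  for (i in 1:20) {
    cal <- rotation_calibration(stats::runif(1, -180, 180))
    fr <- stitch_frame(rnorm(2), rnorm(2))
    fx <- rnorm(50); fy <- rnorm(50)
    d <- decompose_forces(sampled_signal(fx, 100), sampled_signal(fy, 100),
                          cal, fr)
    expect_lt(max(abs(d$Fo$values^2 + d$Ft$values^2 - fx^2 - fy^2)), 1e-12)
  }
})

test_that("decomposition inverts its analytic inverse for skew calibrations", {
  withr::local_seed(10)
  a1 <- 15 * pi / 180; a2 <- 80 * pi / 180   # unit but non-orthogonal axes
  cal <- calibration(c(cos(a1), sin(a1)), c(cos(a2), sin(a2)))
  fr <- stitch_frame(c(1, 2), c(-2, 5))
  fo <- rnorm(100); ft <- rnorm(100)
  Fvis <- cbind(fr$e_o, fr$e_t) %*% rbind(fo, ft)
  Fsen <- solve(cbind(cal$e_x, cal$e_y), Fvis)
  d <- decompose_forces(sampled_signal(Fsen[1, ], 100),
                        sampled_signal(Fsen[2, ], 100), cal, fr)
  expect_lt(max(abs(d$Fo$values - fo)), 1e-9)
  expect_lt(max(abs(d$Ft$values - ft)), 1e-9)
})

test_that("touch counting uses rising edges within the cycle", {
  cyc <- partition_cycles(data.frame(
    stitch_index = 1:2, t_entry = c(0.1, 2), t_exit = c(0.5, 2.5),
    t_pullout = c(1, 3), entry_u = 0, entry_v = 1:2, exit_u = 1, exit_v = 1:2))
  v <- numeric(400)                      # 4 s at 100 Hz
  v[31:35] <- 1; v[61:65] <- 1           # two contacts in cycle 1
  v[251:255] <- 1                        # one contact in cycle 2
  expect_equal(touch_counts(touch_stream(v, 100), cyc), c(2, 1))
  expect_equal(touch_counts(touch_stream(numeric(400), 100), cyc), c(0, 0))
  # a contact already high at cycle start is not counted
  v2 <- numeric(400); v2[1:20] <- 1
  expect_equal(touch_counts(touch_stream(v2, 100), cyc), c(0, 0))
})

test_that("a full session yields the complete 40 x n_stitches metric table", {
  g <- tiny_session(seed = 33)
  m <- session_metrics(g$session)
  expect_identical(nrow(m), 480L)
  expect_identical(sort(unique(m$metric)), sort(metric_vocabulary()))
  counts <- table(m$metric)
  expect_true(all(counts == 12))
  # PP identity holds row-wise
  wide <- split(m$value, m$metric)
  expect_equal(wide[["PP(Fz)"]], wide[["PEAK+(Fz)"]] + wide[["PEAK-(Fz)"]])
  expect_equal(wide[["PP(Tx)"]], wide[["PEAK+(Tx)"]] + wide[["PEAK-(Tx)"]])
})
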