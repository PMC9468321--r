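test_that("noise-free injected amplitudes are recovered downstream", {
  p <- fast_preset(A_o = c(2, 0), sigma_F = 0, sigma_T = 0, sigma_theta = 0)
  g <- generate_session(p, "x", "resident", "surface", seed = 7)
  m <- session_metrics(g$session)
  tr <- g$truth$stitches
  val <- function(nm) m$value[m$metric == nm]
  expect_equal(val("PEAK+(Fo)"), rep(2, 12), tolerance = 1e-6)
  rel <- function(nm, truth) max(abs(val(nm) - truth) / abs(truth))
  expect_lt(rel("PEAK-(Fz)", tr$A_push), 1e-6)
  expect_lt(rel("PEAK+(Fz)", tr$A_pull), 1e-6)
  expect_lt(rel("PP(Fz)", tr$A_push + tr$A_pull), 1e-6)
  expect_lt(rel("PEAK+(Ft)", tr$A_t), 1e-6)
  expect_lt(rel("PEAK+(Tz)", tr$A_Tz_drive), 1e-6)
  expect_lt(rel("PEAK-(Tz)", tr$A_Tz_pull), 1e-6)
  expect_lt(rel("PP(theta_yaw)", tr$R_yaw), 1e-6)
  expect_lt(rel("PP(theta_pitch)", tr$R_pitch), 1e-6)
  expect_lt(rel("PP(theta_roll)", tr$R_roll), 1e-6)
  expect_identical(val("Cn"), as.numeric(tr$n_touches))
})

test_that("entry points sit on the clock face 30 degrees apart", {
  g <- tiny_session(seed = 41)
  st <- g$session$stitches
  ang <- atan2(st$entry_v, st$entry_u) * 180 / pi
  gaps <- diff(ang) %% 360
  expect_equal(gaps, rep(30, 11), tolerance = 1e-9)
  # entry -> exit crosses the incision circle radially (inward)
  r_entry <- sqrt(st$entry_u^2 + st$entry_v^2)
  r_exit <- sqrt(st$exit_u^2 + st$exit_v^2)
  expect_true(all(r_exit < r_entry))
  dir_stitch <- atan2(st$exit_v - st$entry_v, st$exit_u - st$entry_u)
  dir_radial <- atan2(-st$entry_v, -st$entry_u)
  wrapped <- (dir_stitch - dir_radial + pi) %% (2 * pi) - pi
  expect_equal(wrapped, rep(0, 12), tolerance = 1e-9)
})

test_that("identical seed and config reproduce byte-identical sessions", {
  g1 <- tiny_session(seed = 42)
  g2 <- tiny_session(seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(g1$session, d1)
  write_session(g2$session, d2)
  expect_identical(unname(md5_of_dir(d1)), unname(md5_of_dir(d2)))
  g3 <- tiny_session(seed = 43)
  expect_false(identical(g1$session$force$channels$Fz,
                         g3$session$force$channels$Fz))
})

test_that("cohort generation is shaped and seeded deterministically", {
  cfg <- cohort_config(n_attending = 5, n_resident = 7,
                       preset_attending = fast_attending(),
                       preset_resident = fast_preset(), seed = 99)
  coh <- generate_cohort(cfg)
  expect_length(coh, 24)   # 12 subjects x 2 depths
  ids <- vapply(coh, function(e) e$session$subject_id, character(1))
  expect_identical(sort(unique(ids)),
                   sort(c(sprintf("att%02d", 1:5), sprintf("res%02d", 1:7))))
  depths <- vapply(coh, function(e) e$session$depth, character(1))
  expect_identical(sort(unique(depths)), c("depth", "surface"))
  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)
})

test_that("lower attending force presets shift cohort medians down", {
  # directional Monte Carlo over cohort replicates
  lower <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_attending = 2, n_resident = 2, depths = "surface",
                         preset_attending = fast_attending(),
                         preset_resident = fast_preset(), seed = 7000 + r)
    rec <- cohort_metrics(lapply(generate_cohort(cfg), `[[`, "session"))
    pn <- rec[rec$metric == "PEAK-(Fz)", ]
    med <- tapply(pn$value, pn$group, stats::median)
    if (med[["attending"]] < med[["resident"]]) lower <- lower + 1L
  }
  expect_gte(lower, 18L)
})

test_that("degenerate presets are rejected", {
  expect_error(skill_preset(A_push = c(-1, 0.1)),
               class = "sutureskill_validation_error")
  expect_error(skill_preset(sigma_F = -0.1),
               class = "sutureskill_validation_error")
  p <- fast_preset(t_active = c(0.01, 0))
  expect_error(generate_session(p, "x", "resident", "surface", seed = 1),
               class = "sutureskill_validation_error")
  expect_error(cohort_config(seed = 1, depths = "bench"),
               class = "sutureskill_validation_error")
  expect_error(cohort_config(n_attending = 0, seed = 1),
               class = "sutureskill_validation_error")
})
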