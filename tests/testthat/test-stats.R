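test_that("rank-sum test is exact for small tie-free samples", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_identical(w$method, "exact-enumeration")
  # identical samples: maximal overlap, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # agreement with a full-enumeration oracle on random small samples
  withr::local_seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:8, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are symmetric and rank-invariant", {
  withr::local_seed(4)
  for (i in 1:10) {
    x <- rnorm(15, 0.3); y <- rnorm(20)
    p_xy <- wilcoxon_rank_sum(x, y)$p_value
    expect_equal(p_xy, wilcoxon_rank_sum(y, x)$p_value)
    # strictly increasing transform applied to both groups
    expect_equal(p_xy, wilcoxon_rank_sum(exp(x), exp(y))$p_value)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3),
               class = "sutureskill_validation_error")
})

test_that("large-sample method switches to the tie-corrected approximation", {
  withr::local_seed(6)
  x <- round(rnorm(40), 1); y <- round(rnorm(40), 1)  # forced ties
  w <- wilcoxon_rank_sum(x, y)
  expect_identical(w$method, "normal-approximation")
  expect_true(w$p_value >= 0 && w$p_value <= 1)
})

test_that("Lilliefors screen is calibrated and detects non-normality", {
  withr::local_seed(12)
  rej <- mean(replicate(1000, lilliefors_test(rnorm(500))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
  power <- mean(replicate(200, lilliefors_test(rexp(100))$p_value < 0.05))
  expect_gte(power, 0.95)
  expect_error(lilliefors_test(rep(1, 10)), "variance",
               class = "sutureskill_validation_error")
  expect_error(lilliefors_test(c(1, 2)), class = "sutureskill_validation_error")
})

fake_records <- function(att_shift = 0, metric = "PEAK-(Fz)", seed = 1) {
  withr::with_seed(seed, dplyr::bind_rows(
    tibble::tibble(subject_id = rep(sprintf("att%02d", 1:5), each = 12),
                   group = "attending", depth = "surface",
                   stitch_index = rep(1:12, 5), metric = metric,
                   value = rnorm(60, att_shift)),
    tibble::tibble(subject_id = rep(sprintf("res%02d", 1:7), each = 12),
                   group = "resident", depth = "surface",
                   stitch_index = rep(1:12, 7), metric = metric,
                   value = rnorm(84))))
}

test_that("group comparison pools stitches as trials and reports methods", {
  cmp <- compare_groups(fake_records())
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$n_attending, 60L)
  expect_identical(cmp$n_resident, 84L)
  expect_identical(cmp$test, "wilcoxon-rank-sum")
  expect_identical(cmp$method, "normal-approximation")
  expect_true(is.finite(cmp$lilliefors_p_attending))
  big <- compare_groups(fake_records(att_shift = -2))
  expect_true(big$significant)
  expect_lt(big$p_value, 1e-6)
})

test_that("a cell missing one group is flagged, not dropped", {
  rec <- fake_records()
  rec <- rec[rec$group == "resident", ]
  cmp <- compare_groups(rec)
  expect_identical(nrow(cmp), 1L)
  expect_false(cmp$testable)
  expect_true(is.na(cmp$p_value))
  expect_false(cmp$significant)
  expect_error(compare_groups(dplyr::mutate(rec, metric = "BOGUS")),
               class = "sutureskill_validation_error")
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  rec <- dplyr::bind_rows(fake_records(metric = "PEAK-(Fz)", att_shift = -2),
                          fake_records(metric = "PP(Fz)", seed = 2))
  cmp <- compare_groups(rec, adjust = "BH")
  expect_true("p_adjusted" %in% names(cmp))
  expect_true(all(cmp$p_adjusted >= cmp$p_value, na.rm = TRUE))
  expect_identical(cmp$significant, !is.na(cmp$p_adjusted) & cmp$p_adjusted < 0.05)
  # default output carries raw p-values only
  expect_false("p_adjusted" %in% names(compare_groups(rec)))
})

test_that("box-plot summaries use type-7 quantiles and extreme whiskers", {
  rec <- tibble::tibble(subject_id = "s", group = "resident",
                        depth = "surface", stitch_index = 1:5,
                        metric = "Cn", value = c(1, 2, 3, 4, 5))
  sm <- summarize_boxplot(rec)
  expect_equal(sm$median, 3)
  expect_equal(sm$q1, 2)
  expect_equal(sm$q3, 4)
  expect_equal(sm$whisker_low, 1)
  expect_equal(sm$whisker_high, 5)
  one <- summarize_boxplot(dplyr::slice(rec, 1))
  expect_true(all(unlist(one[c("whisker_low", "q1", "median",
                               "q3", "whisker_high")]) == 1))
  # sort-based oracle on random data: with n = 37 the type-7 quartile
  # positions (n-1)*p + 1 are whole numbers, so quartiles are order statistics
  withr::local_seed(8)
  v <- rnorm(37)
  sm2 <- summarize_boxplot(dplyr::mutate(rec[rep(1, 37), ], value = v))
  expect_equal(sm2$q1, sort(v)[10])
  expect_equal(sm2$median, sort(v)[19])
  expect_equal(sm2$q3, sort(v)[28])
  expect_equal(c(sm2$whisker_low, sm2$whisker_high), range(v))
})
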