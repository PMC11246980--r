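records_with_durations <- function(d) {
  data.frame(participant = "x", condition = "conventional",
             duration_s = d, max_angle_deg = 10, distortion = 100,
             base_cm = 40, end_cm = 20)
}

test_that("trial filtering excludes only strictly-over-cutoff durations", {
  flt <- filter_trials(records_with_durations(c(3, 5, 9.9)), 10)
  expect_equal(nrow(flt$retained), 3L)
  expect_equal(nrow(flt$excluded), 0L)

  flt10 <- filter_trials(records_with_durations(c(10.0, 10.0001)), 10)
  expect_equal(flt10$retained$duration_s, 10.0)   # exactly 10 s is retained
  expect_equal(flt10$excluded$duration_s, 10.0001)

  flt3 <- filter_trials(records_with_durations(c(4, 11, 12)), 10)
  expect_equal(nrow(flt3$retained), 1L)
  expect_equal(nrow(flt3$excluded), 2L)
  expect_equal(nrow(flt3$retained) + nrow(flt3$excluded), 3L)
})

test_that("slow-trial flags use a strict 4-second threshold", {
  recs <- records_with_durations(c(3.9, 4.68, 4.0))
  expect_identical(flag_slow_trials(recs), c(FALSE, TRUE, FALSE))
  expect_identical(flag_slow_trials(records_with_durations(c(1, 2))),
                   c(FALSE, FALSE))
})

test_that("condition differences reproduce report-precision arithmetic", {
  expect_equal(condition_difference(45.1, 22.2), 22.9)
  expect_equal(condition_difference(32.3, 22.8), 9.50)
  expect_equal(condition_difference(12.3, 12.3), 0)
})

test_that("t test variants handle degenerate and textbook cases", {
  x <- c(3, 1, 4, 1.5)
  same <- t_test(x, x, "paired")
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_equal(same$df, 3)

  expect_error(t_test(c(1, 2, 3, 4), c(2, 3, 4, 5), "paired"),
               "zero variance")

  # pooled-variance closed form computed by hand
  a <- c(10, 12, 14); b <- c(11, 15, 19)
  got <- t_test(a, b, "pooled")
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_hand, tolerance = 1e-9)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-9)

  w <- t_test(a, b, "welch")
  expect_lt(w$df, 4 + 1e-9)  # Welch-Satterthwaite df <= pooled df here
  expect_error(t_test(1, c(1, 2), "welch"), "at least 2")
  expect_error(t_test(c(1, 2), c(1, 2, 3), "paired"), "equal lengths")
})

test_that("distortion histograms bin at rank width 50 with moment overlays", {
  set.seed(18)
  vals <- abs(rnorm(37, 190, 60))
  h <- distortion_histogram(vals)
  expect_equal(h$bin_width, 50)
  expect_equal(sum(h$counts), 37L)
  expect_equal(h$fit_mean, mean(vals), tolerance = 1e-12)
  expect_equal(h$fit_sd, sd(vals), tolerance = 1e-12)
  expect_equal(h$breaks[1], 0)
  expect_gte(h$breaks[length(h$breaks)], max(vals))

  # bin membership is right-open: a value on a boundary counts upward
  h2 <- distortion_histogram(c(49.999, 50, 100), bin_width = 50)
  expect_equal(h2$counts[1:3], c(1L, 1L, 1L))
  expect_error(distortion_histogram(numeric(0)), "no values")
})

test_that("throughput counts completions inside the window", {
  expect_equal(throughput(numeric(0)), 0L)
  expect_equal(throughput(cumsum(rep(6, 10))), 5L)   # every 6 s -> 5 in 30 s
  expect_equal(throughput(cumsum(rep(6, 10)), window = 12), 2L)
  expect_error(throughput(1:3, window = 0), "positive")
})
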