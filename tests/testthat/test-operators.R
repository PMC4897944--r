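DAYS <- 86400

test_that("summary, count and presence operators on simple windows", {
  t <- c(10, 20, 30) * DAYS
  v <- c("1", "3", "2")
  w <- c(0, 100 * DAYS)
  expect_equal(as.numeric(apply_operator("mean", t, v, w)), 2.0)
  expect_equal(as.numeric(apply_operator("min", t, v, w)), 1)
  expect_equal(as.numeric(apply_operator("max", t, v, w)), 3)
  expect_equal(as.numeric(apply_operator("count", t, v, w)), 3)
  expect_equal(as.numeric(apply_operator("presence", t, v, w)), 1)
  expect_equal(as.numeric(apply_operator("presence", numeric(), character(), w)), 0)
  expect_equal(as.numeric(apply_operator("most_recent", t, v, w)), 2)
})

test_that("trend and change operators follow their strict definitions", {
  w <- c(0, 10 * DAYS)
  t3 <- c(1, 2, 3) * DAYS
  expect_equal(as.numeric(apply_operator("mono_increasing", t3, c("1", "2", "3"), w)), 1)
  expect_equal(as.numeric(apply_operator("mono_increasing", t3, c("3", "1", "2"), w)), 0)
  expect_equal(as.numeric(apply_operator("mono_increasing", DAYS, "5", w)), 0)
  expect_equal(as.numeric(apply_operator("change", c(DAYS, 2 * DAYS), c("2.0", "3.0"), w)), 1.0)
  expect_equal(as.numeric(apply_operator("relative_change", c(DAYS, 2 * DAYS), c("2.0", "3.0"), w)), 0.5)
  expect_true(is.na(apply_operator("relative_change", c(DAYS, 2 * DAYS), c("0", "3.0"), w)))
})

test_that("monthly frequency binning matches the brute-force binning oracle", {
  ev <- c(5, 35, 40, 65, 70, 75) * DAYS
  w <- c(0, 90 * DAYS)
  expect_equal(as.numeric(apply_operator("freq_increasing", ev, rep("1", 6), w,
                                         list(bin = "month"))), 1)
  expect_equal(brute_operator("freq_increasing", ev, rep("1", 6), w,
                              list(bin = "month")), 1)
  # a 45-day window has a single complete monthly bin: no trend decidable
  expect_equal(as.numeric(apply_operator("freq_increasing", ev, rep("1", 6),
                                         c(0, 45 * DAYS), list(bin = "month"))), 0)
})

test_that("window is half-open: start excluded, end included", {
  w <- c(10 * DAYS, 20 * DAYS)
  at_start <- 10 * DAYS
  at_end <- 20 * DAYS
  expect_equal(as.numeric(apply_operator("count", c(at_start), "1", w)), 0)
  expect_equal(as.numeric(apply_operator("count", c(at_end), "1", w)), 1)
})

test_that("empty windows follow the missing-value policy", {
  w <- c(0, 10 * DAYS)
  expect_true(is.na(apply_operator("mean", numeric(), character(), w)))
  expect_equal(as.numeric(apply_operator("count", numeric(), character(), w)), 0)
  expect_equal(as.numeric(apply_operator("duration_days", numeric(), character(), w)), 0)
  expect_equal(as.numeric(apply_operator("mono_increasing", numeric(), character(), w)), 0)
})

test_that("value-fraction operators need their reference parameters", {
  w <- c(0, 10 * DAYS)
  t <- c(1, 2, 3, 4) * DAYS
  v <- c("5", "10", "15", "20")
  expect_equal(as.numeric(apply_operator("frac_high", t, v, w, list(high = 12))), 0.5)
  expect_equal(as.numeric(apply_operator("frac_low", t, v, w, list(low = 8))), 0.25)
  expect_equal(as.numeric(apply_operator("frac_normal", t, v, w,
                                         list(low = 8, high = 16))), 0.5)
  expect_equal(as.numeric(apply_operator("frac_equal", t, v, w, list(value = 10))), 0.25)
  expect_error(apply_operator("frac_high", t, v, w), "requires parameter")
})

test_that("non-numeric values are skipped by numeric operators and counted", {
  w <- c(0, 10 * DAYS)
  r <- apply_operator("mean", c(1, 2, 3) * DAYS, c("1", "junk", "3"), w)
  expect_equal(as.numeric(r), 2)
  expect_equal(attr(r, "n_skipped"), 1L)
})

test_that("undefined medication-regimen operators refuse to run", {
  expect_error(apply_operator("med_switched", 1, "1", c(0, 10)), "not implemented")
  expect_error(aggregation_spec("rx", 30, "med_multi_therapy"), "not implemented")
})

test_that("medication-before-abnormal-lab operator honors window and gap", {
  w <- c(0, 60 * DAYS)
  expect_equal(event_before_event(10 * DAYS, 15 * DAYS, gap_days = 7, w), 1)
  expect_equal(event_before_event(10 * DAYS, 30 * DAYS, gap_days = 7, w), 0)
  expect_equal(event_before_event(10 * DAYS, numeric(), gap_days = 7, w), 0)
  # B before A never qualifies
  expect_equal(event_before_event(15 * DAYS, 10 * DAYS, gap_days = 7, w), 0)
})

test_that("every operator matches the independent brute-force loop on random fixtures", {
  ops <- c("min", "max", "mean", "most_recent", "presence", "count",
           "duration_days", "mono_increasing", "mono_decreasing", "change",
           "relative_change", "frac_high", "frac_low", "frac_normal",
           "frac_equal", "freq_increasing", "freq_decreasing",
           "med_intensified", "med_deintensified")
  params <- list(high = 12, low = 8, value = 10, bin = "month")
  for (seed in 1:120) {
    fx <- random_event_fixture(seed)
    for (op in ops) {
      got <- as.numeric(apply_operator(op, fx$times, fx$values, fx$window, params))
      want <- as.numeric(brute_operator(op, fx$times, fx$values, fx$window, params))
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("%s (seed %d)", op, seed))
    }
  }
})
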