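test_that("curve recording keeps the running maximum and strict time order", {
  crv <- accuracy_curve()
  crv <- record_point(crv, 1, 0.6)
  crv <- record_point(crv, 2, 0.55)
  expect_equal(crv$y, c(0.6, 0.6))
  expect_equal(crv$h, 2L)
  expect_error(record_point(crv, 2, 0.7), "strictly increasing")
})

test_that("noiseless inverse-power-law parameters are recovered to 1e-3", {
  tr <- generate_accuracy_trace(0.9, 0.4, 0.7, times = 1:40, noise_sd = 0)
  crv <- list(t = tr$t, y = tr$y, g = 40L, h = 40L)
  fit <- fit_inverse_power(crv, seed = 1, shift = 0)
  expect_equal(fit$a, 0.9, tolerance = 1e-3)
  expect_equal(fit$b, 0.4, tolerance = 1e-3)
  expect_equal(fit$c, 0.7, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-8)
})

test_that("only the last min(g, h) points are fitted, weighted i/n", {
  tr <- generate_accuracy_trace(0.85, 0.3, 0.5, times = 1:50, noise_sd = 0)
  crv <- list(t = tr$t, y = tr$y, g = 20L, h = 50L)
  fit <- fit_inverse_power(crv, seed = 1)
  expect_equal(nrow(fit$window), 20L)
  expect_equal(fit$window$t, 31:50)
  expect_equal(fit$window$w, (1:20) / 20)
})

test_that("the fit tracks the recent law when the regime changes", {
  # early points from one law, last 20 from another; weighted fit follows
  # the recent law
  early <- generate_accuracy_trace(0.7, 0.3, 0.4, times = 1:30, noise_sd = 0)
  late_law <- function(t) 0.95 - 0.5 * t^(-0.8)
  t_all <- 1:50
  y_all <- c(early$y, late_law(31:50))
  y_all <- cummax(y_all)  # keep it a best-so-far curve
  crv <- list(t = t_all, y = y_all, g = 20L, h = 50L)
  fit <- fit_inverse_power(crv, seed = 2)
  sse_of <- function(a, b, c) {
    idx <- 31:50
    w <- (1:20) / 20
    sum(w * ((a - b * (idx + 1)^(-c)) - y_all[idx])^2)
  }
  # the fitted curve beats the early law on the weighted recent window
  expect_lt(fit$sse, sse_of(0.7, 0.3, 0.4))
})

test_that("projection is monotone, bounded by its asymptote, and NA when unavailable", {
  tr <- generate_accuracy_trace(0.88, 0.35, 0.6, times = 1:25, noise_sd = 0)
  fit <- fit_inverse_power(list(t = tr$t, y = tr$y, g = 25L, h = 25L), seed = 1)
  ts <- seq(25, 2000, length.out = 50)
  proj <- project_accuracy(fit, ts)
  expect_true(all(diff(proj) >= 0))
  expect_true(all(proj <= fit$a + 1e-12))
  expect_equal(project_accuracy(fit, 1e9), fit$a, tolerance = 1e-3)
  # plug-in at the last observed time stays near the last observation
  expect_equal(project_accuracy(fit, 25), tr$y[25], tolerance = 0.01)
  expect_true(is.na(project_accuracy(NULL, 10)))
  # fewer than 3 points: projection unavailable
  expect_null(fit_inverse_power(list(t = 1:2, y = c(0.5, 0.6), g = 20L, h = 2L)))
})

test_that("noisy recovery: asymptote within 0.02 in at least 90% of replicates", {
  hits <- 0L
  for (s in 1:100) {
    tr <- generate_accuracy_trace(0.9, 0.4, 0.7, times = 1:40, noise_sd = 0.01,
                                  seed = s)
    fit <- fit_inverse_power(list(t = tr$t, y = tr$y, g = 40L, h = 40L),
                             seed = s, shift = 0)
    if (abs(fit$a - 0.9) <= 0.02) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("class-pair curves recover planted confusion laws and renormalize rows", {
  t <- 1:40
  p11 <- 0.95 - 0.4 * (t + 1)^(-0.6)
  p22 <- 0.90 - 0.3 * (t + 1)^(-0.5)
  hist <- rbind(
    data.frame(t = t, c1 = "a", c2 = "a", p = p11),
    data.frame(t = t, c1 = "a", c2 = "b", p = 1 - p11),
    data.frame(t = t, c1 = "b", c2 = "b", p = p22),
    data.frame(t = t, c1 = "b", c2 = "a", p = 1 - p22))
  fits <- fit_class_pair_curves(hist, g = 40L, seed = 3)
  expect_equal(fits[["a->a"]]$direction, "increasing")
  expect_equal(fits[["a->b"]]$direction, "decreasing")
  # recovery within 0.02 RMSE on the observed window
  pred <- project_accuracy(fits[["a->a"]], t)
  expect_lt(sqrt(mean((pred - p11)^2)), 0.02)
  p <- project_confusion(fits, 100)
  expect_equal(rowSums(p), c(a = 1, b = 1))
  # perfect-classifier history projects the identity
  hist_perfect <- hist
  hist_perfect$p <- ifelse(hist_perfect$c1 == hist_perfect$c2, 1, 0)
  p_id <- project_confusion(fit_class_pair_curves(hist_perfect, seed = 1), 50)
  expect_equal(unname(diag(p_id)), c(1, 1), tolerance = 1e-4)
})

test_that("expected outcome reproduces the q * p * o plug-in formula", {
  id2 <- diag(2); dimnames(id2) <- list(c("a", "b"), c("a", "b"))
  spec <- outcome_spec(c("a", "b"), q = c(0.5, 0.5),
                       o = matrix(c(0, 1, 1, 0), 2))
  expect_equal(project_outcome(spec, id2), 0)
  unif <- matrix(0.5, 2, 2, dimnames = dimnames(id2))
  expect_equal(project_outcome(spec, unif), 0.5)
  spec2 <- outcome_spec(c("a", "b"), q = c(0.3, 0.7),
                        o = matrix(c(2, 0, 0, 10), 2))
  expect_equal(project_outcome(spec2, id2), 7.6)
})

test_that("continuous targets project through quantile discretization", {
  y <- c(rnorm(500, 0), rnorm(500, 10))
  h <- handle_continuous_target(y, o = matrix(c(1, 5, 5, 1), 2), bins = 2)
  expect_equal(as.numeric(h$spec$q), c(0.5, 0.5))
  h1 <- handle_continuous_target(y, o = matrix(3), bins = 1)
  id1 <- matrix(1, 1, 1)
  expect_equal(project_outcome(h1$spec, id1), 3)
  expect_identical(h$breaks, handle_continuous_target(y, diag(2), 2)$breaks)
})
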