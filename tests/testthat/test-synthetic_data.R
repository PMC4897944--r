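test_that("generators are bit-identical under a fixed seed", {
  s <- small_cohort_spec(n = 40, seed = 4)
  expect_identical(generate_eav_cohort(s), generate_eav_cohort(s))
  b <- benchmark_spec(100, 4, "linear", seed = 4)
  expect_identical(generate_benchmark(b), generate_benchmark(b))
  tr <- generate_accuracy_trace(0.9, 0.4, 0.7, 1:20, noise_sd = 0.01, seed = 4)
  expect_identical(tr, generate_accuracy_trace(0.9, 0.4, 0.7, 1:20,
                                               noise_sd = 0.01, seed = 4))
})

test_that("noiseless cohort target is exactly the thresholded planted aggregate", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 150, noise = 0, seed = 8))
  agg <- pivot_aggregate(coh$eav, list(small_cohort_spec()$planted), coh$instances)
  z <- agg[["ed_visit.count.90d"]]
  expect_identical(as.integer(coh$instances$outcome) - 1L,
                   as.integer(z > coh$truth$threshold))
})

test_that("empty cohort degenerates cleanly", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 0))
  expect_equal(nrow(coh$eav), 0L)
  expect_equal(nrow(coh$instances), 0L)
})

test_that("planted operator must be applicable to the planted attribute", {
  expect_error(cohort_spec(
    10, list(dx = list(type = "event", rate_per_month = 1)),
    planted = aggregation_spec("dx", 90, "mean")), "not applicable")
})

test_that("label noise degrades the learnable signal", {
  # Monte-Carlo: holdout AUC of the planted feature under noise 0.5 vs 0
  auc_at <- function(noise, seed) {
    coh <- generate_eav_cohort(small_cohort_spec(n = 200, noise = noise,
                                                 seed = seed))
    z <- coh$truth$aggregate
    model_quality(coh$instances$outcome, (z - min(z)) / (max(z) - min(z) + 1e-9))
  }
  wins <- sum(vapply(1:10, function(s) auc_at(0, s) > auc_at(0.5, s), logical(1)))
  expect_gte(wins, 9)
})

test_that("rule-family benchmark is a pure function of its rule at noise 0", {
  tbl <- generate_benchmark(benchmark_spec(1000, 5, "rule", rule_depth = 1, seed = 2))
  expect_identical(tbl$y, factor(as.integer(tbl$x1 > 0), levels = c(0, 1)))
  tbl1 <- generate_benchmark(benchmark_spec(50, 1, "rule", rule_depth = 1, seed = 2))
  expect_equal(feature_names <- setdiff(names(tbl1), c(".instance_id", "y")), "x1")
})

test_that("generative family determines which learner family wins", {
  holdout_auc <- function(tbl, train_fun) {
    n <- nrow(tbl)
    idx <- seq_len(floor(n * 0.7))
    X <- as.matrix(tbl[, paste0("x", 1:4)])
    y <- tbl$y
    train_fun(X[idx, ], y[idx], X[-idx, ], y[-idx])
  }
  tree_fun <- function(Xtr, ytr, Xte, yte) {
    fit <- rpart::rpart(y ~ ., data = data.frame(Xtr, y = ytr), method = "class",
                        control = rpart::rpart.control(maxdepth = 2, cp = 0, xval = 0))
    model_quality(yte, predict(fit, data.frame(Xte), type = "prob"))
  }
  lin_fun <- function(Xtr, ytr, Xte, yte) {
    fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", lambda = 1e-4)
    model_quality(yte, predict(fit, Xte, type = "response")[, 1])
  }
  lin_wins <- 0; tree_wins <- 0
  for (s in 1:10) {
    lin <- generate_benchmark(benchmark_spec(800, 4, "linear", label_noise = 0.05,
                                             seed = s))
    if (holdout_auc(lin, lin_fun) > holdout_auc(lin, tree_fun)) lin_wins <- lin_wins + 1
    rule <- generate_benchmark(benchmark_spec(800, 4, "rule", label_noise = 0.05,
                                              seed = s))
    if (holdout_auc(rule, tree_fun) > holdout_auc(rule, lin_fun)) tree_wins <- tree_wins + 1
  }
  expect_gte(lin_wins, 8)
  expect_gte(tree_wins, 6)
})

test_that("accuracy traces plug into the law and approach the asymptote", {
  tr <- generate_accuracy_trace(0.9, 0.4, 0.7, times = 1, noise_sd = 0)
  expect_equal(tr$y, 0.5)
  tr2 <- generate_accuracy_trace(0.9, 0.4, 0.7, times = c(1, 10, 100, 1e4, 1e6),
                                 noise_sd = 0)
  expect_true(all(diff(tr2$y) > 0))
  expect_true(all(tr2$y < 0.9))
  expect_equal(tr2$y[5], 0.9, tolerance = 1e-4)
})

test_that("planted pair maximizes information gain among all enumerated pairs at noise 0", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 300, noise = 0, seed = 23))
  periods <- enumerate_periods(30, 360)
  scores <- vapply(periods, function(p) {
    w <- pivot_aggregate(coh$eav, list(aggregation_spec("ed_visit", p, "count")),
                         coh$instances)
    information_gain(w[[4]], coh$instances$outcome)
  }, numeric(1))
  # the maximum sits at a window covering the planted 90 days
  expect_gte(periods[which.max(scores)], 90)
})
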