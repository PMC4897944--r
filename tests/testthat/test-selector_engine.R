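small_control <- function(...) {
  args <- utils::modifyList(
    list(n_random = 4, min_tests = 4, random_pool = 300, screen_n = 8,
         library_size = 5, ensemble_iterations = 10),
    list(...))
  do.call(search_control, args)
}

test_that("prefilter keeps the signal and mandatory features, drops constants", {
  set.seed(1)
  n <- 300
  X <- cbind(signal = rnorm(n), noise = rnorm(n), constant = rep(1, n))
  y <- factor(as.integer(X[, "signal"] > 0))
  kept <- prefilter_features(X, y, seed = 2)
  expect_true("signal" %in% kept)
  expect_false("constant" %in% kept)
  kept_m <- prefilter_features(X, y, mandatory = "constant", seed = 2)
  expect_true("constant" %in% kept_m)
})

test_that("algorithm elimination applies the halving margin and the final-round argmax", {
  pot <- c(A = 0.80, B = 0.78, C = 0.55)
  expect_setequal(eliminate_algorithms(pot, round = 1, n_rounds = 5), c("A", "B"))
  expect_setequal(eliminate_algorithms(c(A = 0.7, B = 0.7, C = 0.7), 1, 5),
                  c("A", "B", "C"))
  expect_equal(eliminate_algorithms(c(A = 0.9), 1, 5), "A")
  # margin halves: at round 2 the window is 0.05
  expect_setequal(eliminate_algorithms(pot, round = 2, n_rounds = 6), c("A", "B"))
  expect_equal(eliminate_algorithms(c(A = 0.80, B = 0.74), 2, 6)[1], "A")
  # >= 2 survivors are forced outside the final two rounds
  expect_length(eliminate_algorithms(c(A = 0.9, B = 0.5, C = 0.4), 1, 6), 2L)
  # entrant of the final round is exactly the argmax
  expect_equal(eliminate_algorithms(pot, round = 4, n_rounds = 5), "A")
})

test_that("evaluator elimination waits for enough tests then drops one per call", {
  mk <- function(ev, q, status = "completed") {
    list(config = list(fs = list(evaluator = ev)), status = status, quality = q)
  }
  evs <- c("a", "b", "c", "d", "e", "f")
  trials <- unlist(lapply(evs, function(e) {
    lapply(1:5, function(i) mk(e, q = ifelse(e == "f", 0.4, 0.7 + i / 100)))
  }), recursive = FALSE)
  # all six have 5 >= min_tests = 5: worst ("f") is dropped, one per call
  out <- eliminate_evaluators(trials, evs, max_keep = 4, min_tests = 5)
  expect_setequal(out, c("a", "b", "c", "d", "e"))
  out2 <- eliminate_evaluators(trials, out, max_keep = 4, min_tests = 5)
  expect_length(out2, 4L)
  # insufficient tests: no judgment
  expect_setequal(eliminate_evaluators(trials, evs, max_keep = 4, min_tests = 20), evs)
  # already at max_keep: untouched
  expect_setequal(eliminate_evaluators(trials, evs[1:4], max_keep = 4, min_tests = 5),
                  evs[1:4])
})

test_that("small-sample scaling adds the observed uplift with fallbacks", {
  mk <- function(alg, sig, size, q) {
    list(algorithm = alg, signature = sig, size = size, quality = q,
         status = "completed")
  }
  trials <- list(mk("A", "s1", 100, 0.60), mk("A", "s1", 400, 0.70),
                 mk("A", "s2", 100, 0.62), mk("A", "s2", 400, 0.72))
  expect_equal(scale_accuracy(0.65, "A", trials, 100, 400), 0.75)
  # no pairs for B: falls back to the global uplift
  expect_equal(scale_accuracy(0.65, "B", trials, 100, 400), 0.75)
  # no pairs at all: estimate = q_small
  expect_equal(scale_accuracy(0.65, "B", list(), 100, 400), 0.65)
  expect_equal(scale_accuracy(0.97, "A", trials, 100, 400), 1.0)  # clipped
})

test_that("screened group keeps the top small-sample qualities with seeded ties", {
  q <- c(0.9, 0.5, 0.8, 0.7, 0.6)
  expect_equal(screen_random_group(q, n_keep = 3), c(1L, 3L, 4L))
  tied <- rep(0.5, 5)
  expect_identical(screen_random_group(tied, 3, seed = 1),
                   screen_random_group(tied, 3, seed = 1))
})

test_that("ensemble hillclimb never falls below the best single model", {
  set.seed(9)
  y <- factor(rep(c("0", "1"), each = 50))
  mk_pred <- function(auc_ish) {
    s <- as.numeric(y == "1") * auc_ish + rnorm(100, 0, 0.3)
    p <- (s - min(s)) / (max(s) - min(s))
    cbind("0" = 1 - p, "1" = p)
  }
  preds <- list(mk_pred(0.8), mk_pred(0.5), mk_pred(0.65))
  best_single <- max(vapply(preds, function(p) model_quality(y, p), numeric(1)))
  ens <- build_ensemble(preds, y, iterations = 15)
  expect_gte(ens$quality, best_single)
  expect_equal(sum(ens$weights), 1)
  # degenerate library of one
  e1 <- build_ensemble(preds[1], y, iterations = 5)
  expect_equal(e1$weights, 1)
  # duplicated best model leaves quality unchanged
  e2 <- build_ensemble(c(preds[1], preds[1]), y, iterations = 5)
  expect_equal(e2$quality, model_quality(y, preds[[1]]))
})

test_that("a short search returns a usable model and a monotone best-so-far curve", {
  tbl <- generate_benchmark(benchmark_spec(500, 5, "rule", label_noise = 0.1, seed = 3))
  res <- search(tbl, control = small_control(
    seed = 11, algorithms = c("dtree", "nbayes"), initial_size = 80))
  expect_s3_class(res, "search_result")
  expect_true(all(diff(res$curve$q) >= 0))
  expect_true(all(diff(res$curve$t) >= 0))
  expect_gt(res$best$quality, 0.5)
  expect_true(is.finite(res$holdout_quality))
  # survivor sets shrink weakly
  n_surv <- vapply(res$survivor_history, length, integer(1))
  expect_true(all(diff(n_surv) <= 0))
  n_ev <- vapply(res$evaluator_history, length, integer(1))
  expect_true(all(diff(n_ev) <= 0))
  # estimated entries never reach potentials or the curve
  est_ids <- res$ledger$trial_id[res$ledger$estimated]
  expect_false(any(res$curve$trial_id %in% est_ids))
})

test_that("aborting after round 1 still yields the best model so far", {
  tbl <- generate_benchmark(benchmark_spec(400, 4, "rule", label_noise = 0.1, seed = 5))
  res <- search(tbl, control = small_control(
    seed = 2, algorithms = c("dtree", "logreg"), initial_size = 60,
    max_rounds = 1))
  expect_equal(max(res$ledger$round), 1L)
  expect_true(is.finite(res$best$quality))
  expect_true(is.finite(res$holdout_quality))
})

test_that("restricting to a single algorithm returns that algorithm", {
  tbl <- generate_benchmark(benchmark_spec(300, 4, "rule", label_noise = 0.1, seed = 6))
  res <- search(tbl, control = small_control(
    seed = 3, algorithms = "dtree", evaluators = "none", n_random = 1,
    initial_size = 60, max_rounds = 2))
  expect_equal(res$best$algorithm, "dtree")
  expect_true(all(res$ledger$algorithm == "dtree"))
})

test_that("deterministic mode replays the ledger identically across worker counts", {
  tbl <- generate_benchmark(benchmark_spec(400, 4, "rule", label_noise = 0.1, seed = 7))
  run <- function(w) {
    res <- search(tbl, control = small_control(
      seed = 13, workers = w, algorithms = c("dtree", "nbayes"),
      initial_size = 60, max_rounds = 2))
    res$ledger[, setdiff(names(res$ledger), "wall_time")]
  }
  l1 <- run(1)
  l2 <- run(2)
  l4 <- run(4)
  expect_identical(l1, l2)
  expect_identical(l1, l4)
})

test_that("mandatory features survive feature selection into every model", {
  tbl <- generate_benchmark(benchmark_spec(300, 5, "rule", label_noise = 0.1, seed = 8))
  res <- search(tbl, control = small_control(
    seed = 4, algorithms = "dtree", evaluators = c("none", "infogain"),
    mandatory = "x5", initial_size = 60, max_rounds = 2))
  expect_true(is.finite(res$holdout_quality))
  sel <- clinsearch:::select_features(list(evaluator = "infogain", search = "topk",
                                           k_frac = 0.2),
                                      clinsearch:::design_matrix(tbl), tbl$y,
                                      mandatory = "x5", seed = 1)
  expect_true("x5" %in% sel)
})

test_that("refinement only ever improves quality and grows the flagged parameter", {
  tbl <- generate_benchmark(benchmark_spec(400, 5, "rule", label_noise = 0.15, seed = 9))
  res <- search(tbl, control = small_control(
    seed = 5, algorithms = c("rforest"), evaluators = "none", n_random = 2,
    initial_size = 100, max_rounds = 2, refine_budget = 2))
  refined <- res$ledger[res$ledger$provenance == "refined", ]
  if (nrow(refined) > 0) {
    expect_true(all(refined$status %in% c("completed", "failed", "skipped")))
  }
  expect_gte(res$best$quality, max(res$ledger$quality[res$ledger$round == 1],
                                   na.rm = TRUE))
})
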