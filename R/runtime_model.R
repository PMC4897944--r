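# Runtime prediction: a candidate's test time is predicted as
# baseline x size-ratio x hyper-parameter-ratio, and tests predicted to
# exceed f x T are skipped up front instead of being started and aborted.
# The baseline is the algorithm's default configuration timed at the
# first-round sample size.

#' Training-time ratio between two sample sizes
#'
#' `(n_new / n_base)^p` with the algorithm's complexity exponent `p`; when
#' `p` is unknown it is fitted as the slope of log-time vs log-size over
#' the algorithm's completed trials (at least 3 distinct sizes required,
#' else `p = 1`).
#'
#' @param p complexity exponent, or `NA`.
#' @param n_new,n_base sample sizes.
#' @param trials optional completed trials (fields `size`, `time`) used to
#'   fit `p` when unknown.
#' @return nonnegative ratio.
#' @export
size_ratio <- function(p, n_new, n_base, trials = NULL) {
  if (is.na(p)) p <- fit_size_exponent(trials)
  (n_new / n_base)^p
}

fit_size_exponent <- function(trials) {
  if (is.null(trials)) return(1)
  sizes <- vapply(trials, `[[`, numeric(1), "size")
  times <- vapply(trials, `[[`, numeric(1), "time")
  ok <- times > 0
  if (length(unique(sizes[ok])) < 3L) return(1)
  fit <- stats::lm(log(times[ok]) ~ log(sizes[ok]))
  unname(stats::coef(fit)[2L])
}

#' Hyper-parameter time ratio of a configuration vs the default
#'
#' Two approaches are compared per algorithm on its completed trials and
#' the more accurate one (lower leave-one-out absolute log-error) is used:
#' (A) a linear regression of log time on the encoded configuration;
#' (B) a product of per-hyper-parameter ratio functions, with ratio 1 for
#' parameters known to matter little. Before 5 completed trials exist the
#' ratio is 1, so there is no skipping pressure early on.
#'
#' @param space a [search_space()].
#' @param algorithm algorithm id.
#' @param config a `configuration`.
#' @param trials that algorithm's completed trials (fields `config`,
#'   `size`, `time`).
#' @param approach "auto" (compare A and B), "A" or "B".
#' @return positive ratio; attribute `approach` records the choice.
#' @export
hp_ratio <- function(space, algorithm, config, trials = list(),
                     approach = "auto") {
  alg <- space$algorithms[[algorithm]]
  if (approach == "auto") {
    approach <- if (length(trials) < 5L) "B" else choose_ratio_approach(space, alg, trials)
  }
  r <- if (length(trials) < 5L) {
    1
  } else if (approach == "B") {
    hp_ratio_product(alg, config)
  } else {
    hp_ratio_regression(space, alg, config, trials)
  }
  structure(max(r, 1e-6), approach = approach)
}

# Approach B: product of per-hyper-parameter ratio functions from the
# algorithm's declared cost model; undeclared parameters contribute 1.
hp_ratio_product <- function(alg, config) {
  r <- 1
  for (nm in names(alg$hp_cost)) {
    f <- alg$hp_cost[[nm]]
    r <- r * f(config$hp[[nm]]) / f(alg$hps[[nm]]$default)
  }
  r
}

hp_ratio_regression <- function(space, alg, config, trials, evaluators = space$evaluators) {
  fit <- ratio_regression_fit(space, alg, trials, evaluators)
  if (is.null(fit)) return(hp_ratio_product(alg, config))
  x_cfg <- encode_configuration(space, config, evaluators)
  x_def <- encode_configuration(space, default_configuration(space, alg$id), evaluators)
  exp(ratio_regression_predict(fit, x_cfg) - ratio_regression_predict(fit, x_def))
}

ratio_regression_fit <- function(space, alg, trials, evaluators) {
  times <- vapply(trials, `[[`, numeric(1), "time")
  sizes <- vapply(trials, `[[`, numeric(1), "size")
  ok <- times > 0
  if (sum(ok) < 3L) return(NULL)
  X <- do.call(rbind, lapply(trials[ok], function(tr) {
    encode_configuration(space, tr$config, evaluators)
  }))
  # control for size so the regression isolates the hyper-parameter effect
  y <- log(times[ok]) - log(sizes[ok])
  keep <- apply(X, 2L, function(col) sd(col) > 0)
  if (!any(keep)) return(NULL)
  df <- data.frame(X[, keep, drop = FALSE])
  fit <- stats::lm(y ~ ., data = df)
  list(fit = fit, keep = keep)
}

ratio_regression_predict <- function(frfit, x) {
  nd <- data.frame(t(x[frfit$keep]))
  # one-hot blocks make the design rank-deficient by construction; the
  # prediction is still well-defined on observed level combinations
  as.numeric(suppressWarnings(predict(frfit$fit, nd)))
}

# Pick A or B by leave-one-out absolute log-error on observed trial times.
choose_ratio_approach <- function(space, alg, trials) {
  times <- vapply(trials, `[[`, numeric(1), "time")
  sizes <- vapply(trials, `[[`, numeric(1), "size")
  ok <- which(times > 0)
  if (length(ok) < 5L) return("B")
  err <- c(A = 0, B = 0)
  for (i in ok) {
    rest <- trials[setdiff(ok, i)]
    base_t <- mean(vapply(rest, `[[`, numeric(1), "time") /
                   vapply(rest, `[[`, numeric(1), "size"))
    for (ap in c("A", "B")) {
      r <- if (ap == "B") hp_ratio_product(alg, trials[[i]]$config)
           else hp_ratio_regression(space, alg, trials[[i]]$config, rest)
      pred <- base_t * sizes[i] * r
      err[[ap]] <- err[[ap]] + abs(log(pred) - log(times[i]))
    }
  }
  if (err[["B"]] <= err[["A"]]) "B" else "A"
}

#' Skip rule for overly slow tests
#'
#' A candidate is skipped iff its predicted test time exceeds `f * T`
#' (strictly); `f > 1` tolerates prediction imprecision.
#'
#' @param predicted_time predicted test time.
#' @param T_limit per-combination time limit of the current round.
#' @param f tolerance factor, must be > 1.
#' @return logical.
#' @export
should_skip <- function(predicted_time, T_limit, f) {
  if (f <= 1) stop("tolerance factor f must be > 1")
  stopifnot(T_limit > 0)
  predicted_time > f * T_limit
}

#' Predicted test time of a configuration
#'
#' Multiplicative decomposition: baseline time of the algorithm's default
#' configuration at the first-round size, times the size ratio, times the
#' hyper-parameter ratio.
#'
#' @param space a [search_space()].
#' @param algorithm algorithm id.
#' @param config a `configuration`.
#' @param baseline baseline time (default config, round-1 sample); `NA`
#'   yields `NA` (no skipping before a baseline exists).
#' @param n_new,n_base current and baseline sample sizes.
#' @param trials completed trials for ratio fitting.
#' @return predicted time, or `NA`.
#' @export
predict_test_time <- function(space, algorithm, config, baseline, n_new,
                              n_base, trials = list()) {
  if (is.na(baseline)) return(NA_real_)
  alg <- space$algorithms[[algorithm]]
  baseline * size_ratio(alg$p, n_new, n_base, trials) *
    as.numeric(hp_ratio(space, algorithm, config, trials))
}

# Deterministic analytic cost of a trial (cost units, not seconds): used as
# the runtime model's "time" in deterministic mode so skip decisions replay
# identically; wall-clock seconds are logged separately.
deterministic_cost <- function(space, algorithm, config, n) {
  alg <- space$algorithms[[algorithm]]
  n^(alg$p) / 1000 * alg$cost_unit * hp_ratio_product(alg, config)
}
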