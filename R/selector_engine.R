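# The progressive-sampling search loop. Round 1 tests every algorithm's
# default plus a fixed number of random configurations on a small training
# sample; later rounds double the sample, propose candidates per surviving
# algorithm from the surrogate, skip candidates predicted to be too slow,
# and eliminate unpromising algorithms and feature evaluators. The final
# (full-pool) round re-tests only the few best combinations; afterwards the
# expensive-monotone hyper-parameters of the top algorithms are pushed
# further, and an ensemble is hill-climbed from the model library.

#' Search control parameters
#'
#' All method constants surface here with their standard defaults: 20
#' random configurations per algorithm in round 1, candidate groups of
#' 10 + 10 drawn from local search and a 10,000-strong random pool, 30
#' screened small-sample candidates from round 3 on, at most 4 surviving
#' feature evaluators each judged only after 20 tests, skip factor `f = 2`
#' over a per-round limit `T0` that doubles each round, elimination margin
#' `delta1 = 0.10` halving per round, curve window `g = 20`, and the
#' task/data-parallel switch round `m = 3` (accepted for interface
#' fidelity; execution is a single-machine work queue).
#'
#' @param seed integer master seed.
#' @param workers logical work-queue count (result is worker-invariant).
#' @param deterministic when TRUE (default) trial "times" fed to the
#'   runtime model are analytic cost units so runs replay bit-identically;
#'   when FALSE measured wall seconds are used.
#' @param n_random,n_local,n_random_prop,random_pool,screen_n,screen_from_round
#'   candidate-generation constants.
#' @param max_keep,min_tests feature-evaluator elimination constants.
#' @param delta1 round-1 algorithm-elimination margin.
#' @param f,T0,T_growth runtime-skip constants.
#' @param g projection curve window.
#' @param m task-parallel switch round (interface fidelity only).
#' @param initial_size,test_fraction,holdout_fraction schedule parameters
#'   (see [make_schedule()]).
#' @param max_rounds optional cap on rounds (early stop returns the best
#'   model so far).
#' @param final_round_trials combinations re-tested on the full pool.
#' @param algorithms,evaluators optional restriction lists.
#' @param mandatory features that must enter every model (feature
#'   selection applies only to the rest).
#' @param prefilter remove features with no marginal signal before the
#'   search.
#' @param ensemble_iterations hillclimb steps for ensemble selection.
#' @param library_size model-library size for ensemble selection.
#' @param refine_budget maximum refinement steps per algorithm.
#' @param refine_top algorithms considered for refinement.
#' @param refine_eps minimum quality gain counted as improvement.
#' @return a `search_control` list.
#' @export
search_control <- function(seed = 1L, workers = 1L, deterministic = TRUE,
                           n_random = 20L, n_local = 10L, n_random_prop = 10L,
                           random_pool = 10000L, screen_n = 30L,
                           screen_from_round = 3L, max_keep = 4L,
                           min_tests = 20L, delta1 = 0.10, f = 2, T0 = 10,
                           T_growth = 2, g = 20L, m = 3L,
                           initial_size = NULL, test_fraction = 0.2,
                           holdout_fraction = 0.2, max_rounds = Inf,
                           final_round_trials = 4L,
                           algorithms = NULL, evaluators = NULL,
                           mandatory = character(), prefilter = TRUE,
                           ensemble_iterations = 20L, library_size = 10L,
                           refine_budget = 8L, refine_top = 2L,
                           refine_eps = 0.001) {
  stopifnot(f > 1, T0 > 0, T_growth >= 1, delta1 > 0)
  as.list(environment())
}

#' Pre-filter features by marginal relevance
#'
#' Information gain (categorical target) or variance reduction (continuous)
#' on a seeded sample of the data; mandatory features are always kept, the
#' rest survive iff their score exceeds `threshold` or ranks in the top
#' `top_k`.
#'
#' @param X numeric feature matrix.
#' @param y target (factor or numeric).
#' @param mandatory feature names always kept.
#' @param threshold minimum relevance score.
#' @param top_k cap on kept non-mandatory features.
#' @param sample_size scoring sample size.
#' @param seed integer.
#' @return character vector of surviving feature names.
#' @export
prefilter_features <- function(X, y, mandatory = character(), threshold = 0,
                               top_k = Inf, sample_size = 5000L, seed = 1L) {
  n <- nrow(X)
  idx <- if (n > sample_size) {
    with_seed(derive_seed(seed, "prefilter"), sort(sample(n, sample_size)))
  } else seq_len(n)
  free <- setdiff(colnames(X), mandatory)
  scores <- vapply(free, function(f) {
    relevance_score(X[idx, f], if (is.factor(y)) y[idx] else y[idx])
  }, numeric(1))
  keep <- free[scores > threshold]
  if (is.finite(top_k) && length(keep) > top_k) {
    keep <- keep[order(-scores[match(keep, free)])][seq_len(top_k)]
  }
  out <- c(mandatory, keep)
  colnames(X)[colnames(X) %in% out]  # preserve column order
}

#' Algorithm elimination by potential
#'
#' An algorithm's potential is the highest completed quality achieved so
#' far. After round `round`, survivors are the algorithms within
#' `delta1 * 2^(1 - round)` of the best potential; at least 2 survive until
#' the final two rounds, and only the arg-max enters the full-data round.
#'
#' @param potentials named numeric vector (algorithm -> potential; `-Inf`
#'   for algorithms with no completed trial).
#' @param round the round just finished (1-based).
#' @param n_rounds total rounds in the schedule.
#' @param delta1 round-1 margin.
#' @return surviving algorithm ids (entrants of round `round + 1`).
#' @export
eliminate_algorithms <- function(potentials, round, n_rounds, delta1 = 0.10) {
  stopifnot(length(potentials) >= 1L)
  if (length(potentials) == 1L) return(names(potentials))
  next_round <- round + 1L
  if (next_round >= n_rounds) {
    return(names(potentials)[which.max(potentials)])
  }
  delta <- delta1 * 2^(1 - round)
  best <- max(potentials)
  survivors <- names(potentials)[potentials >= best - delta]
  if (length(survivors) < 2L && next_round < n_rounds - 1L) {
    survivors <- names(sort(potentials, decreasing = TRUE))[1:2]
  }
  survivors
}

#' Feature-evaluator elimination
#'
#' Evaluators are judged only once each has at least `min_tests`
#' completed-or-skipped trials; then the lowest-potential evaluator is
#' dropped (one per round) until at most `max_keep` remain. A dropped
#' evaluator is never proposed again and its dimensions leave all
#' surrogate encodings.
#'
#' @param trials ledger trial list.
#' @param evaluators currently surviving evaluator ids.
#' @param max_keep maximum evaluators retained.
#' @param min_tests minimum trials per evaluator before judgment.
#' @return surviving evaluator ids.
#' @export
eliminate_evaluators <- function(trials, evaluators, max_keep = 4L,
                                 min_tests = 20L) {
  if (length(evaluators) <= max_keep) return(evaluators)
  evs <- vapply(trials, function(tr) tr$config$fs$evaluator, character(1))
  status <- vapply(trials, `[[`, character(1), "status")
  counted <- status %in% c("completed", "skipped")
  n_tests <- vapply(evaluators, function(e) sum(counted & evs == e), numeric(1))
  if (any(n_tests < min_tests)) return(evaluators)
  potential <- vapply(evaluators, function(e) {
    q <- vapply(trials[status == "completed" & evs == e], `[[`, numeric(1), "quality")
    if (length(q) == 0) -Inf else max(q)
  }, numeric(1))
  drop <- evaluators[order(potential, rev(seq_along(evaluators)))][1L]
  setdiff(evaluators, drop)
}

#' Pick the screened group 2 from small-sample trial qualities
#'
#' Of the 30 largest-EI random candidates tested on the round-1 sample, the
#' 10 with the highest small-sample quality form group 2; ties at the cut
#' break by a seeded random order.
#'
#' @param qualities small-sample qualities of the screened candidates.
#' @param n_keep group-2 size.
#' @param seed integer for tie-breaking.
#' @return integer indices of the keepers, best first.
#' @export
screen_random_group <- function(qualities, n_keep = 10L, seed = 1L) {
  jitter_rank <- with_seed(derive_seed(seed, "screen-tie"),
                           sample(seq_along(qualities)))
  order(-qualities, jitter_rank)[seq_len(min(n_keep, length(qualities)))]
}

#' Scale a small-sample quality to the current sample size
#'
#' The estimate adds the mean quality uplift observed among configurations
#' of the same algorithm completed at both sizes; falls back to the global
#' mean uplift, then to no uplift. Clipped to \[0, 1\].
#'
#' @param q_small quality measured at `size_small`.
#' @param algorithm algorithm id.
#' @param trials ledger trial list.
#' @param size_small,size_cur the two sample sizes.
#' @return scaled quality estimate.
#' @export
scale_accuracy <- function(q_small, algorithm, trials, size_small, size_cur) {
  uplift <- uplift_between(trials, size_small, size_cur, algorithm)
  if (is.na(uplift)) uplift <- uplift_between(trials, size_small, size_cur, NULL)
  if (is.na(uplift)) uplift <- 0
  min(max(q_small + uplift, 0), 1)
}

uplift_between <- function(trials, size_small, size_cur, algorithm) {
  completed <- Filter(function(tr) {
    tr$status == "completed" &&
      (is.null(algorithm) || tr$algorithm == algorithm)
  }, trials)
  if (length(completed) == 0) return(NA_real_)
  sig <- vapply(completed, `[[`, character(1), "signature")
  size <- vapply(completed, `[[`, numeric(1), "size")
  q <- vapply(completed, `[[`, numeric(1), "quality")
  ups <- c()
  for (s in unique(sig)) {
    qs <- q[sig == s & size == size_small]
    qc <- q[sig == s & size == size_cur]
    if (length(qs) > 0 && length(qc) > 0) {
      ups <- c(ups, mean(qc) - mean(qs))
    }
  }
  if (length(ups) == 0) NA_real_ else mean(ups)
}

#' Ensemble selection by forward stepwise hillclimbing
#'
#' Caruana-style selection with replacement from a library of fitted
#' models' selection-sample predictions: start from the single best model,
#' repeatedly add (with replacement) the member whose inclusion maximizes
#' the ensemble's selection-sample quality, never accepting a worsening
#' step. Member weights are selection counts over total selections, so the
#' ensemble's selection-sample quality is at least the best single
#' model's.
#'
#' @param preds list of member predictions on the selection sample (score
#'   matrices for classification, numeric vectors for regression).
#' @param truth selection-sample target.
#' @param iterations hillclimb steps after initialization.
#' @return list: `weights` (per member, sums to 1), `quality`
#'   (selection-sample quality of the weighted ensemble), `picks`
#'   (selection sequence).
#' @export
build_ensemble <- function(preds, truth, iterations = 20L) {
  stopifnot(length(preds) >= 1L)
  qualities <- vapply(preds, function(p) model_quality(truth, p), numeric(1))
  counts <- integer(length(preds))
  init <- which.max(qualities)
  counts[init] <- 1L
  ens_pred <- function(cnt) {
    w <- cnt / sum(cnt)
    Reduce(`+`, Map(function(p, wi) p * wi, preds, w))
  }
  cur_q <- model_quality(truth, ens_pred(counts))
  picks <- init
  for (it in seq_len(iterations)) {
    cand_q <- vapply(seq_along(preds), function(j) {
      cnt <- counts; cnt[j] <- cnt[j] + 1L
      model_quality(truth, ens_pred(cnt))
    }, numeric(1))
    j <- which.max(cand_q)
    if (cand_q[j] < cur_q) break  # hillclimb never accepts a worsening step
    counts[j] <- counts[j] + 1L
    cur_q <- cand_q[j]
    picks <- c(picks, j)
  }
  list(weights = counts / sum(counts), quality = cur_q, picks = picks)
}

# --- the search itself -----------------------------------------------------

new_trial_id <- function(state) {
  state$trial_counter <- state$trial_counter + 1L
  state$trial_counter
}

record_trial <- function(state, round, config, size, quality, time, wall_time,
                         status, provenance, estimated = FALSE, preds = NULL,
                         fit = NULL) {
  id <- new_trial_id(state)
  state$trials[[id]] <- list(
    trial_id = id, round = round, algorithm = config$algorithm,
    config = config, signature = config_signature(config), size = size,
    quality = quality, time = time, wall_time = wall_time, status = status,
    provenance = provenance, estimated = estimated)
  if (!is.null(preds)) state$preds[[as.character(id)]] <- preds
  if (!is.null(fit)) state$fits[[as.character(id)]] <- fit
  if (identical(status, "completed") && !estimated && !is.na(quality)) {
    t_now <- as.numeric(Sys.time()) - state$t0
    prev <- if (nrow(state$curve) > 0) max(state$curve$q) else -Inf
    state$curve <- rbind(state$curve,
                         data.frame(t = t_now, trial_id = id,
                                    q = max(quality, prev)))
    if (quality > prev) {
      state$best_trial_id <- id
      record_confusion(state, t_now, preds$test)
    }
  }
  id
}

record_confusion <- function(state, t_now, pred_test) {
  if (!is.factor(state$y_test) || is.null(pred_test)) return(invisible())
  lev <- levels(state$y_test)
  pred_cls <- lev[max.col(pred_test, ties.method = "first")]
  for (c1 in lev) {
    in_c1 <- state$y_test == c1
    if (!any(in_c1)) next
    for (c2 in lev) {
      state$confusion <- rbind(state$confusion,
        data.frame(t = t_now, c1 = c1, c2 = c2,
                   p = mean(pred_cls[in_c1] == c2)))
    }
  }
}

completed_trials <- function(state, algorithm = NULL, include_estimated = FALSE) {
  Filter(function(tr) {
    (tr$status == "completed" || (include_estimated && tr$status == "estimated")) &&
      (is.null(algorithm) || tr$algorithm == algorithm) && !is.na(tr$quality)
  }, state$trials)
}

algorithm_potentials <- function(state, algorithms) {
  vapply(algorithms, function(a) {
    q <- vapply(completed_trials(state, a), `[[`, numeric(1), "quality")
    if (length(q) == 0) -Inf else max(q)
  }, numeric(1))
}

trial_time_for_model <- function(state, tr) {
  if (state$control$deterministic) tr$time else tr$wall_time
}

#' Initialize the search state
#'
#' Prepares the design matrix, applies the pre-filter, builds the
#' progressive-sampling schedule and seeds the trial ledger. [run_round()]
#' advances the returned state one round; [search()] wraps the whole loop.
#'
#' @param tbl an [instance_table()] with a typed target.
#' @param space a [search_space()]; default built for the target type.
#' @param control a [search_control()].
#' @return a `search_state` environment.
#' @export
init_search_state <- function(tbl, space = NULL, control = search_control()) {
  task <- target_type(tbl)
  stopifnot(!is.null(task))
  if (is.null(space)) space <- search_space(default_algorithms(task))
  algorithms <- names(space$algorithms)
  if (!is.null(control$algorithms)) {
    algorithms <- intersect(algorithms, control$algorithms)
  }
  algorithms <- algorithms[vapply(space$algorithms[algorithms],
                                  function(a) task %in% a$tasks, logical(1))]
  stopifnot(length(algorithms) >= 1L)
  evaluators <- control$evaluators %||% space$evaluators

  y <- tbl[[target_col(tbl)]]
  X <- design_matrix(tbl)
  mandatory <- intersect(control$mandatory, colnames(X))
  if (isTRUE(control$prefilter)) {
    kept <- prefilter_features(X, y, mandatory = mandatory,
                               seed = control$seed)
    X <- X[, kept, drop = FALSE]
  }
  schedule <- make_schedule(tbl, initial_size = control$initial_size,
                            test_fraction = control$test_fraction,
                            holdout_fraction = control$holdout_fraction,
                            seed = control$seed)
  n_rounds <- min(length(schedule$sizes), control$max_rounds)
  ids <- instance_ids(tbl)
  row_of <- function(set) match(set, ids)

  state <- new.env(parent = emptyenv())
  state$space <- space
  state$control <- control
  state$schedule <- schedule
  state$n_rounds <- n_rounds
  state$round <- 0L
  state$X <- X
  state$y <- y
  state$mandatory <- mandatory
  state$X_test <- X[row_of(schedule$test_ids), , drop = FALSE]
  state$y_test <- y[row_of(schedule$test_ids)]
  state$X_hold <- X[row_of(schedule$holdout_ids), , drop = FALSE]
  state$y_hold <- y[row_of(schedule$holdout_ids)]
  state$row_of <- row_of
  state$survivors <- algorithms
  state$evaluators <- evaluators
  state$survivor_history <- list(algorithms)
  state$evaluator_history <- list(evaluators)
  state$T_limit <- control$T0
  state$trials <- list()
  state$preds <- list()
  state$fits <- list()
  state$trial_counter <- 0L
  state$curve <- data.frame(t = numeric(), trial_id = integer(), q = numeric())
  state$confusion <- data.frame(t = numeric(), c1 = character(),
                                c2 = character(), p = numeric())
  state$best_trial_id <- NA_integer_
  state$baselines <- setNames(rep(NA_real_, length(algorithms)), algorithms)
  state$t0 <- as.numeric(Sys.time())
  class(state) <- c("search_state", "environment")
  state
}

round_candidates <- function(state, r) {
  control <- state$control
  space <- state$space
  size <- state$schedule$sizes[r]
  cands <- list()
  add <- function(cfg, algorithm) {
    cands[[length(cands) + 1L]] <<- cfg
  }
  if (r == 1L) {
    for (a in state$survivors) {
      add(default_configuration(space, a))
      for (cfg in sample_random(space, a, control$n_random,
                                derive_seed(control$seed, "r1", a),
                                state$evaluators)) add(cfg)
    }
    # evaluator top-up: every evaluator gets its minimum number of tests
    ev_count <- table(factor(vapply(cands, function(c) c$fs$evaluator, character(1)),
                             levels = state$evaluators))
    for (e in state$evaluators) {
      deficit <- control$min_tests - ev_count[[e]]
      k <- 0L
      while (deficit > 0) {
        a <- state$survivors[(k %% length(state$survivors)) + 1L]
        cfg <- sample_random(space, a, 1L,
                             derive_seed(control$seed, "topup", e, k),
                             state$evaluators)[[1L]]
        cfg$fs$evaluator <- e
        cfg$provenance <- "topup"
        add(cfg)
        deficit <- deficit - 1L
        k <- k + 1L
      }
    }
  } else if (r == state$n_rounds && r > 1L) {
    # full-data round: re-test only the best few combinations found so far
    done <- completed_trials(state)
    done <- Filter(function(tr) tr$algorithm %in% state$survivors, done)
    q <- vapply(done, `[[`, numeric(1), "quality")
    sig <- vapply(done, `[[`, character(1), "signature")
    ord <- order(-q, vapply(done, `[[`, integer(1), "trial_id"))
    seen <- character()
    for (i in ord) {
      if (sig[i] %in% seen) next
      seen <- c(seen, sig[i])
      cfg <- done[[i]]$config
      cfg$provenance <- "refit-full"
      add(cfg)
      if (length(seen) >= control$final_round_trials) break
    }
  } else {
    for (a in state$survivors) {
      trials_a <- completed_trials(state, a)
      model <- fit_surrogate(space, completed_trials(state, a, include_estimated = TRUE),
                             a, state$evaluators, control$seed)
      best_q <- best_for_ei(state, a, size)
      group2 <- NULL
      if (r >= control$screen_from_round && isTRUE(model$defined)) {
        group2 <- run_screening(state, r, a, model, best_q)
        model <- fit_surrogate(space,
                               completed_trials(state, a, include_estimated = TRUE),
                               a, state$evaluators, control$seed)
      }
      props <- propose_candidates(space, model, trials_a, size, best_q,
                                  derive_seed(control$seed, "prop", a, r),
                                  evaluators = state$evaluators,
                                  n_local = control$n_local,
                                  n_random = control$n_random_prop,
                                  random_pool = control$random_pool,
                                  group2 = group2)
      for (cfg in props) add(cfg)
    }
  }
  cands
}

# incumbent for EI: best completed quality at the current size, falling
# back to the algorithm's overall best
best_for_ei <- function(state, algorithm, size) {
  done <- completed_trials(state, algorithm)
  if (length(done) == 0) return(0)
  q <- vapply(done, `[[`, numeric(1), "quality")
  s <- vapply(done, `[[`, numeric(1), "size")
  if (any(s == size)) max(q[s == size]) else max(q)
}

# Technique 3: screen the 30 largest-EI random candidates on the round-1
# sample; the best 10 become group 2, the rest enter the surrogate's
# training set as scaled estimates (status "estimated").
run_screening <- function(state, r, algorithm, model, best_q) {
  control <- state$control
  space <- state$space
  size_cur <- state$schedule$sizes[r]
  size1 <- state$schedule$sizes[1L]
  pool <- sample_random(space, algorithm, control$random_pool,
                        derive_seed(control$seed, "screenpool", algorithm, r),
                        state$evaluators)
  ei <- ei_for_configs(model, space, pool, size_cur, best_q)
  screened <- pool[order(-ei, seq_along(ei))[seq_len(min(control$screen_n, length(pool)))]]
  ids <- execute_candidates(state, r, screened, size1,
                            state$schedule$train_ids[[1L]],
                            provenance = "screen")
  q_small <- vapply(ids, function(id) {
    tr <- state$trials[[id]]
    if (tr$status == "completed") tr$quality else -Inf
  }, numeric(1))
  keep <- screen_random_group(q_small, n_keep = control$n_random_prop,
                              seed = derive_seed(control$seed, "screen", algorithm, r))
  # scaled estimates for the rest: surrogate food only
  for (i in setdiff(seq_along(screened), keep)) {
    if (!is.finite(q_small[i])) next
    est <- scale_accuracy(q_small[i], algorithm, state$trials, size1, size_cur)
    record_trial(state, r, screened[[i]], size_cur, est, NA_real_, NA_real_,
                 status = "estimated", provenance = "scaled", estimated = TRUE)
  }
  screened[keep][q_small[keep] > -Inf]
}

# Execute candidates at one size through the work-queue contract: the
# candidate list is partitioned round-robin over `workers` queues, queues
# are drained in order, and results merge back in canonical candidate
# order. Per-trial seeds depend only on (master seed, signature, size), so
# the ledger is a pure function of (seed, candidates) for any worker count.
execute_candidates <- function(state, r, cands, size, train_ids,
                               provenance = NULL) {
  control <- state$control
  space <- state$space
  rows <- state$row_of(train_ids)
  Xtr <- state$X[rows, , drop = FALSE]
  ytr <- state$y[rows]
  n_base <- state$schedule$sizes[1L]
  w <- max(1L, control$workers)
  queue_of <- (seq_along(cands) - 1L) %% w + 1L
  results <- vector("list", length(cands))
  for (queue in seq_len(w)) {
    for (i in which(queue_of == queue)) {
      cfg <- cands[[i]]
      a <- cfg$algorithm
      cost <- deterministic_cost(space, a, cfg, size)
      trials_a <- Filter(function(tr) tr$status == "completed" && tr$algorithm == a,
                         state$trials)
      for (k in seq_along(trials_a)) {
        trials_a[[k]]$time <- trial_time_for_model(state, trials_a[[k]])
      }
      pred_t <- predict_test_time(space, a, cfg, state$baselines[[a]],
                                  size, n_base, trials_a)
      if (!is.na(pred_t) && should_skip(pred_t, state$T_limit, control$f)) {
        results[[i]] <- list(status = "skipped", quality = NA_real_,
                             cost = cost, wall = NA_real_)
        next
      }
      seed_i <- derive_seed(control$seed, "trial", config_signature(cfg), size)
      t_start <- proc.time()[["elapsed"]]
      out <- tryCatch(
        execute_trial(cfg, Xtr, ytr,
                      list(list(X = state$X_test, y = state$y_test),
                           list(X = state$X_hold, y = state$y_hold)),
                      state$mandatory, seed_i),
        error = function(e) e)
      wall <- proc.time()[["elapsed"]] - t_start
      if (inherits(out, "error")) {
        results[[i]] <- list(status = "failed", quality = NA_real_,
                             cost = cost, wall = wall)
      } else {
        keep_fit <- size >= max(state$schedule$sizes[state$n_rounds])
        results[[i]] <- list(status = "completed", quality = out$quality,
                             cost = cost, wall = wall,
                             preds = list(test = out$preds[[1L]],
                                          holdout = out$preds[[2L]]),
                             fit = if (keep_fit) out$fit)
      }
    }
  }
  ids <- integer(length(cands))
  for (i in seq_along(cands)) {
    res <- results[[i]]
    ids[i] <- record_trial(state, r, cands[[i]], size, res$quality, res$cost,
                           res$wall, res$status,
                           provenance %||% cands[[i]]$provenance,
                           preds = res$preds, fit = res$fit)
    # the default configuration's time at round-1 size is the baseline
    if (r == 1L && identical(cands[[i]]$provenance, "default") &&
        res$status == "completed") {
      state$baselines[[cands[[i]]$algorithm]] <-
        if (control$deterministic) res$cost else res$wall
    }
  }
  ids
}

#' Advance the search one round
#'
#' Generates the round's candidates (defaults + randoms in round 1,
#' surrogate proposals afterwards, best-so-far re-tests in the full-data
#' round), applies the runtime skip rule, executes the survivors through
#' the work queue, then updates the evaluator and algorithm survivor sets
#' and doubles the per-combination time limit.
#'
#' @param state a `search_state` from [init_search_state()].
#' @return the state, invisibly (mutated in place).
#' @export
run_round <- function(state) {
  r <- state$round + 1L
  stopifnot(r <= state$n_rounds)
  state$round <- r
  control <- state$control
  cands <- round_candidates(state, r)
  execute_candidates(state, r, cands, state$schedule$sizes[r],
                     state$schedule$train_ids[[r]])
  if (r < state$n_rounds) {
    state$evaluators <- eliminate_evaluators(state$trials, state$evaluators,
                                             control$max_keep, control$min_tests)
    pot <- algorithm_potentials(state, state$survivors)
    state$survivors <- eliminate_algorithms(pot, r, state$n_rounds,
                                            control$delta1)
  }
  state$survivor_history[[r + 1L]] <- state$survivors
  state$evaluator_history[[r + 1L]] <- state$evaluators
  state$T_limit <- state$T_limit * control$T_growth
  invisible(state)
}

#' Refine expensive-monotone hyper-parameters of the top algorithms
#'
#' For the top algorithms (by potential) carrying an expensive-monotone
#' flag, the flagged hyper-parameter of the algorithm's best configuration
#' is moved geometrically (x2) in its flagged direction past the search
#' cap, retraining on the full training pool, until the quality gain falls
#' below `refine_eps` twice in a row or the budget is spent. The best model
#' is only ever replaced by a strictly better one.
#'
#' @param state a `search_state` after the rounds have run.
#' @return the state, invisibly.
#' @export
refine_expensive_hyperparameters <- function(state) {
  control <- state$control
  space <- state$space
  full_ids <- state$schedule$train_ids[[state$n_rounds]]
  full_size <- state$schedule$sizes[state$n_rounds]
  done <- completed_trials(state)
  if (length(done) == 0) return(invisible(state))
  algs <- unique(vapply(done, `[[`, character(1), "algorithm"))
  flagged <- algs[vapply(algs, function(a) {
    any(!vapply(lapply(space$algorithms[[a]]$hps, `[[`, "expensive"),
                is.null, logical(1)))
  }, logical(1))]
  if (length(flagged) == 0) return(invisible(state))
  pot <- algorithm_potentials(state, flagged)
  top <- names(sort(pot, decreasing = TRUE))[seq_len(min(control$refine_top,
                                                         length(flagged)))]
  for (a in top) {
    done_a <- completed_trials(state, a)
    q_a <- vapply(done_a, `[[`, numeric(1), "quality")
    best_cfg <- done_a[[which.max(q_a)]]$config
    best_q <- max(q_a)
    for (nm in names(space$algorithms[[a]]$hps)) {
      def <- space$algorithms[[a]]$hps[[nm]]
      if (is.null(def$expensive)) next
      up <- identical(def$expensive$direction, "up")
      value <- best_cfg$hp[[nm]]
      non_improving <- 0L
      for (step in seq_len(control$refine_budget)) {
        value <- if (up) min(value * 2, def$upper) else max(value / 2, def$lower)
        cfg <- best_cfg
        cfg$hp[[nm]] <- if (def$kind == "integer") round(value) else value
        cfg$provenance <- "refined"
        if (identical(cfg$hp[[nm]], best_cfg$hp[[nm]])) break
        ids <- execute_candidates(state, state$round, list(cfg), full_size,
                                  full_ids, provenance = "refined")
        tr <- state$trials[[ids[1L]]]
        if (tr$status != "completed") break
        gain <- tr$quality - best_q
        if (tr$quality > best_q) {
          best_q <- tr$quality
          best_cfg <- cfg
        }
        if (gain < control$refine_eps) {
          non_improving <- non_improving + 1L
          if (non_improving >= 2L) break
        } else non_improving <- 0L
        if ((up && cfg$hp[[nm]] >= def$upper) ||
            (!up && cfg$hp[[nm]] <= def$lower)) break
        value <- cfg$hp[[nm]]
      }
    }
  }
  invisible(state)
}

finalize_search <- function(state) {
  control <- state$control
  done <- completed_trials(state)
  if (length(done) == 0) {
    stop("every trial failed; ledger attached",
         call. = FALSE)
  }
  q <- vapply(done, `[[`, numeric(1), "quality")
  best_tr <- done[[order(-q, vapply(done, `[[`, integer(1), "trial_id"))[1L]]]
  full_size <- state$schedule$sizes[state$n_rounds]
  full_ids <- state$schedule$train_ids[[state$n_rounds]]
  # final model: the winner trained on the full pool (reuse if it already was)
  fit_key <- as.character(best_tr$trial_id)
  if (best_tr$size >= full_size && !is.null(state$fits[[fit_key]])) {
    final_fit <- state$fits[[fit_key]]
    final_preds <- state$preds[[fit_key]]
    final_quality <- best_tr$quality
  } else {
    ids <- execute_candidates(state, state$round, list(best_tr$config),
                              full_size, full_ids, provenance = "final-refit")
    tr <- state$trials[[ids[1L]]]
    final_fit <- state$fits[[as.character(tr$trial_id)]]
    final_preds <- state$preds[[as.character(tr$trial_id)]]
    final_quality <- tr$quality
  }
  holdout_quality <- model_quality(state$y_hold, final_preds$holdout)

  # ensemble from the model library (top completed trials with predictions)
  done <- completed_trials(state)
  q <- vapply(done, `[[`, numeric(1), "quality")
  has_preds <- vapply(done, function(tr) {
    !is.null(state$preds[[as.character(tr$trial_id)]])
  }, logical(1))
  lib_idx <- order(-q, vapply(done, `[[`, integer(1), "trial_id"))
  lib_idx <- lib_idx[has_preds[lib_idx]][seq_len(min(control$library_size,
                                                     sum(has_preds)))]
  lib <- done[lib_idx]
  ens <- NULL
  if (length(lib) >= 1L) {
    sel_preds <- lapply(lib, function(tr) state$preds[[as.character(tr$trial_id)]]$test)
    hold_preds <- lapply(lib, function(tr) state$preds[[as.character(tr$trial_id)]]$holdout)
    e <- build_ensemble(sel_preds, state$y_test, control$ensemble_iterations)
    ens_hold <- Reduce(`+`, Map(function(p, w) p * w, hold_preds, e$weights))
    ens <- list(weights = e$weights,
                members = vapply(lib, `[[`, integer(1), "trial_id"),
                quality = e$quality,
                holdout_quality = model_quality(state$y_hold, ens_hold))
  }

  structure(list(
    best = list(config = best_tr$config, quality = max(q),
                trial_id = best_tr$trial_id, algorithm = best_tr$algorithm),
    final_model = final_fit,
    final_quality = final_quality,
    holdout_quality = holdout_quality,
    ensemble = ens,
    ledger = ledger_df(state$trials),
    trials = state$trials,
    curve = state$curve,
    confusion_history = state$confusion,
    schedule = state$schedule,
    survivor_history = state$survivor_history,
    evaluator_history = state$evaluator_history,
    control = control), class = "search_result")
}

#' Flatten a trial ledger to a data.frame
#' @param trials list of trial records (or a `search_result`).
#' @return data.frame, one row per trial.
#' @export
ledger_df <- function(trials) {
  if (inherits(trials, "search_result")) trials <- trials$trials
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, round = tr$round,
               algorithm = tr$algorithm, signature = tr$signature,
               size = tr$size, quality = tr$quality %||% NA_real_,
               time = tr$time, wall_time = tr$wall_time, status = tr$status,
               provenance = tr$provenance %||% NA_character_,
               estimated = tr$estimated, stringsAsFactors = FALSE)
  }))
}

#' Progressive search for the best algorithm/feature-selection/
#' hyper-parameter combination
#'
#' Runs the full progressive-sampling loop on an [instance_table()],
#' followed by expensive-hyper-parameter refinement and ensemble
#' selection. The returned result carries the winning configuration, its
#' final model and untouched-holdout quality, the ensemble, the complete
#' trial ledger, and the best-so-far accuracy curve consumed by the
#' projection module.
#'
#' @param tbl an [instance_table()] with a typed target.
#' @param space a [search_space()] (default: built for the target type).
#' @param control a [search_control()].
#' @return a `search_result`.
#' @export
search <- function(tbl, space = NULL, control = search_control()) {
  state <- init_search_state(tbl, space, control)
  while (state$round < state$n_rounds) run_round(state)
  refine_expensive_hyperparameters(state)
  finalize_search(state)
}

#' @export
print.search_result <- function(x, ...) {
  cat("progressive search result\n")
  cat("  best:", x$best$algorithm, "(trial", x$best$trial_id, ")",
      "test quality", round(x$best$quality, 4), "\n")
  cat("  final model holdout quality:", round(x$holdout_quality, 4), "\n")
  if (!is.null(x$ensemble)) {
    cat("  ensemble: ", length(x$ensemble$members), " members, selection ",
        round(x$ensemble$quality, 4), ", holdout ",
        round(x$ensemble$holdout_quality, 4), "\n", sep = "")
  }
  cat("  trials:", nrow(x$ledger), "rounds:", max(x$ledger$round), "\n")
  invisible(x)
}
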