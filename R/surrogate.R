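# Per-algorithm surrogate: a bagged regression-tree model (random forest)
# over encoded configurations plus a training-sample-size feature, giving a
# predictive mean and across-tree variance for the expected-improvement
# acquisition. One surrogate per algorithm keeps other algorithms'
# hyper-parameters out of the regression.

SIZE_FEATURE <- ".log2_size"

surrogate_matrix <- function(space, configs, sizes, evaluators) {
  rows <- lapply(configs, encode_configuration, space = space,
                 evaluators = evaluators)
  X <- do.call(rbind, rows)
  cbind(X, setNames(data.frame(log2(sizes)), SIZE_FEATURE))
}

#' Fit the per-algorithm surrogate from its completed trials
#'
#' Undefined (returns a fallback marker) until at least `d + 2` trials
#' exist, `d` being the encoding dimension; proposals then fall back to
#' pure random sampling. Trials of dropped evaluators stay usable: their
#' evaluator dimensions encode as zeros.
#'
#' @param space a [search_space()].
#' @param trials list of trial records (fields `config`, `size`, `quality`)
#'   for one algorithm, completed or estimated.
#' @param algorithm algorithm id.
#' @param evaluators surviving evaluator ids.
#' @param seed integer.
#' @param ntree bags.
#' @return a `surrogate_model` (or one with `defined = FALSE`).
#' @export
fit_surrogate <- function(space, trials, algorithm, evaluators, seed,
                          ntree = 100L) {
  d <- length(encoding_dims(space, algorithm, evaluators)) + 1L
  base <- list(algorithm = algorithm, evaluators = evaluators, dim = d,
               n_trials = length(trials))
  if (length(trials) < d + 2L) {
    return(structure(c(base, list(defined = FALSE)), class = "surrogate_model"))
  }
  configs <- lapply(trials, `[[`, "config")
  sizes <- vapply(trials, `[[`, numeric(1), "size")
  y <- vapply(trials, `[[`, numeric(1), "quality")
  X <- surrogate_matrix(space, configs, sizes, evaluators)
  set.seed(derive_seed(seed, "surrogate", algorithm))
  # few distinct quality values are expected early on; the bagged trees
  # are still a valid variance estimator there
  rf <- suppressWarnings(randomForest::randomForest(X, y, ntree = ntree))
  structure(c(base, list(defined = TRUE, rf = rf)), class = "surrogate_model")
}

#' Predictive mean and variance of the surrogate at configurations
#'
#' Mean and variance are taken across the bagged trees.
#'
#' @param model a defined `surrogate_model`.
#' @param space a [search_space()].
#' @param configs list of `configuration`s.
#' @param size training-sample size the prediction refers to.
#' @return data.frame with columns `mu`, `var`.
#' @export
predict_mean_var <- function(model, space, configs, size) {
  if (!isTRUE(model$defined)) stop("surrogate model is undefined (too few trials)")
  X <- surrogate_matrix(space, configs, rep(size, length(configs)),
                        model$evaluators)
  all_p <- predict(model$rf, X, predict.all = TRUE)$individual
  data.frame(mu = rowMeans(all_p),
             var = apply(all_p, 1L, function(r) mean((r - mean(r))^2)))
}

#' Expected improvement over the incumbent
#'
#' `EI = (mu - best) * Phi(z) + sigma * phi(z)` with
#' `z = (mu - best) / sigma`; at `sigma = 0` it degenerates to
#' `max(mu - best, 0)`. Vectorized.
#'
#' @param mu predictive mean(s).
#' @param sigma predictive standard deviation(s), >= 0.
#' @param best incumbent quality.
#' @return EI values, always >= 0.
#' @export
expected_improvement <- function(mu, sigma, best) {
  stopifnot(all(sigma >= 0))
  d <- mu - best
  out <- pmax(d, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- d[pos] / sigma[pos]
    out[pos] <- d[pos] * pnorm(z) + sigma[pos] * dnorm(z)
  }
  out
}

ei_for_configs <- function(model, space, configs, size, best) {
  pv <- predict_mean_var(model, space, configs, size)
  expected_improvement(pv$mu, sqrt(pv$var), best)
}

#' Propose the round's candidate configurations for one algorithm
#'
#' Two groups, interleaved: group 1 is the best-EI neighbor of each of the
#' (up to) 10 previously tested configurations with the largest EI; group 2
#' is the 10 largest-EI configurations among a 10,000-strong seeded random
#' pool (or a pre-screened group when small-sample screening is active).
#' Configurations already tested are dropped. With an undefined surrogate
#' the proposal is 20 pure-random configurations.
#'
#' @param space a [search_space()].
#' @param model `surrogate_model` for the algorithm.
#' @param trials that algorithm's completed trials (for "previously
#'   tested" and duplicate suppression).
#' @param size current round's training-sample size.
#' @param best incumbent quality for EI.
#' @param seed integer.
#' @param evaluators surviving evaluator ids.
#' @param n_local,n_random group sizes (paper defaults 10 and 10).
#' @param random_pool random pool size (default 10,000).
#' @param group2 optional externally screened group 2 (list of configs).
#' @return list of `configuration`s in test order, provenance tags
#'   "local" / "random-pool".
#' @export
propose_candidates <- function(space, model, trials, size, best, seed,
                               evaluators = space$evaluators,
                               n_local = 10L, n_random = 10L,
                               random_pool = 10000L, group2 = NULL) {
  algorithm <- model$algorithm
  tested_sigs <- vapply(trials, function(tr) config_signature(tr$config), character(1))
  if (!isTRUE(model$defined)) {
    cands <- sample_random(space, algorithm, n_local + n_random,
                           derive_seed(seed, "fallback"), evaluators)
    sigs <- vapply(cands, config_signature, character(1))
    return(cands[!sigs %in% tested_sigs])
  }
  # group 1: local search around the top previously tested configs by EI
  configs_prev <- lapply(trials, `[[`, "config")
  ei_prev <- ei_for_configs(model, space, configs_prev, size, best)
  top_idx <- order(-ei_prev, seq_along(ei_prev))[seq_len(min(n_local, length(ei_prev)))]
  g1 <- list()
  for (i in top_idx) {
    nb <- neighbors(space, configs_prev[[i]], evaluators)
    if (length(nb) == 0) next
    ei_nb <- ei_for_configs(model, space, nb, size, best)
    g1[[length(g1) + 1L]] <- nb[[order(-ei_nb, seq_along(ei_nb))[1L]]]
  }
  # group 2: best-EI members of a big random pool (unless pre-screened)
  if (is.null(group2)) {
    pool <- sample_random(space, algorithm, random_pool,
                          derive_seed(seed, "pool"), evaluators)
    ei_pool <- ei_for_configs(model, space, pool, size, best)
    g2 <- pool[order(-ei_pool, seq_along(ei_pool))[seq_len(min(n_random, length(pool)))]]
  } else {
    g2 <- group2
  }
  g2 <- lapply(g2, function(cfg) { cfg$provenance <- "random-pool"; cfg })
  out <- list()
  for (i in seq_len(max(length(g1), length(g2)))) {
    if (i <= length(g1)) out[[length(out) + 1L]] <- g1[[i]]
    if (i <= length(g2)) out[[length(out) + 1L]] <- g2[[i]]
  }
  sigs <- vapply(out, config_signature, character(1))
  out[!duplicated(sigs) & !sigs %in% tested_sigs]
}
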