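# Declarative joint search space: learning algorithm x feature-selection
# technique (evaluator x search method) x hyper-parameter values. The
# feature-selection choice is itself treated as a hyper-parameter. A
# separate numeric encoding is built per algorithm so each surrogate sees
# only its own algorithm's dimensions.

#' Define one hyper-parameter
#'
#' @param name parameter name.
#' @param kind "continuous", "integer" or "categorical".
#' @param lower,upper numeric range (numeric kinds).
#' @param values value list (categorical kind).
#' @param default default value (inside the range / value list).
#' @param log sample and encode on a log scale.
#' @param expensive NULL, or `list(direction = "up"|"down", cap = c(lo, hi))`
#'   marking a hyper-parameter whose extreme values trade much slower
#'   training for accuracy; the main search samples only inside `cap`, and
#'   the end-of-search refinement walks past it in `direction`.
#' @return an `hp_def` list.
#' @export
hp_def <- function(name, kind, lower = NULL, upper = NULL, values = NULL,
                   default, log = FALSE, expensive = NULL) {
  kind <- match.arg(kind, c("continuous", "integer", "categorical"))
  if (kind == "categorical") {
    stopifnot(!is.null(values), default %in% values, is.null(expensive))
  } else {
    stopifnot(is.numeric(lower), is.numeric(upper), lower < upper,
              default >= lower, default <= upper)
    if (log) stopifnot(lower > 0)
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 values = values, default = default, log = log,
                 expensive = expensive),
            class = "hp_def")
}

#' Define one learning algorithm for the search space
#'
#' @param id algorithm id.
#' @param hps list of [hp_def()]s.
#' @param tasks supported target types, subset of
#'   `c("categorical", "continuous")`.
#' @param p training-time complexity exponent (time proportional to `n^p`),
#'   or `NA` when unknown (then fitted from observed trial times).
#' @param cost_unit relative single-sample training cost used by the
#'   deterministic runtime model.
#' @param hp_cost named list of functions `value -> multiplicative cost
#'   factor` for hyper-parameters that scale training time.
#' @return an `algorithm_spec` list.
#' @export
algorithm_spec <- function(id, hps, tasks = "categorical", p = 1, cost_unit = 1,
                           hp_cost = list()) {
  names(hps) <- vapply(hps, `[[`, character(1), "name")
  structure(list(id = id, hps = hps, tasks = tasks, p = p,
                 cost_unit = cost_unit, hp_cost = hp_cost),
            class = "algorithm_spec")
}

#' The shipped algorithm roster
#'
#' Seven families (decision tree, random forest, gradient boosting, k-NN,
#' regularized logistic/linear regression, naive Bayes, linear SVM) — enough
#' to exercise elimination; the roster is configurable, not a fixed list.
#' The number of trees of the forest and boosting learners carries the
#' expensive-monotone flag (more trees: better and proportionally slower).
#'
#' @param task "categorical" or "continuous".
#' @return named list of [algorithm_spec()]s supporting `task`.
#' @export
default_algorithms <- function(task = "categorical") {
  roster <- list(
    algorithm_spec("dtree", list(
      hp_def("cp", "continuous", 1e-4, 0.1, default = 0.01, log = TRUE),
      hp_def("maxdepth", "integer", 1, 30, default = 30),
      hp_def("minsplit", "integer", 5, 50, default = 20)
    ), tasks = c("categorical", "continuous"), p = 1, cost_unit = 1),
    algorithm_spec("rforest", list(
      hp_def("ntree", "integer", 50, 500, default = 100,
             expensive = list(direction = "up", cap = c(50, 200))),
      hp_def("mtry_frac", "continuous", 0.1, 1, default = 1 / 3),
      hp_def("nodesize", "integer", 1, 20, default = 1)
    ), tasks = c("categorical", "continuous"), p = 1, cost_unit = 6,
       hp_cost = list(ntree = function(v) v / 100)),
    algorithm_spec("gboost", list(
      hp_def("nrounds", "integer", 20, 300, default = 100,
             expensive = list(direction = "up", cap = c(20, 150))),
      hp_def("eta", "continuous", 0.01, 0.5, default = 0.3, log = TRUE),
      hp_def("max_depth", "integer", 1, 10, default = 6)
    ), tasks = c("categorical", "continuous"), p = 1, cost_unit = 4,
       hp_cost = list(nrounds = function(v) v / 100, max_depth = function(v) v / 6)),
    algorithm_spec("knn", list(
      hp_def("k", "integer", 1, 50, default = 7)
    ), tasks = "categorical", p = 2, cost_unit = 0.5),
    algorithm_spec("logreg", list(
      hp_def("lambda", "continuous", 1e-5, 10, default = 0.01, log = TRUE),
      hp_def("alpha", "continuous", 0, 1, default = 1)
    ), tasks = c("categorical", "continuous"), p = 1, cost_unit = 1),
    algorithm_spec("nbayes", list(
      hp_def("laplace", "continuous", 0, 5, default = 0)
    ), tasks = "categorical", p = 1, cost_unit = 0.5),
    algorithm_spec("lsvm", list(
      hp_def("cost", "continuous", 0.01, 100, default = 1, log = TRUE)
    ), tasks = "categorical", p = 2, cost_unit = 2)
  )
  names(roster) <- vapply(roster, `[[`, character(1), "id")
  roster[vapply(roster, function(a) task %in% a$tasks, logical(1))]
}

FS_EVALUATORS <- c("none", "infogain", "correlation", "variance",
                   "model_importance", "sym_uncert")
FS_SEARCHES <- c("topk", "forward")

#' The joint search space
#'
#' @param algorithms named list of [algorithm_spec()]s
#'   (default: [default_algorithms()]).
#' @param evaluators feature-evaluator ids; "none" (pass-through) is always
#'   legal and is the default technique.
#' @param searches feature-search-method ids.
#' @return a `search_space` list.
#' @export
search_space <- function(algorithms = default_algorithms(),
                         evaluators = FS_EVALUATORS,
                         searches = FS_SEARCHES) {
  stopifnot(length(algorithms) >= 1L, "none" %in% evaluators)
  fs_hps <- list(hp_def("k_frac", "continuous", 0.05, 1, default = 0.5))
  names(fs_hps) <- "k_frac"
  structure(list(algorithms = algorithms, evaluators = evaluators,
                 searches = searches, fs_hps = fs_hps),
            class = "search_space")
}

#' Default configuration of one algorithm
#'
#' All hyper-parameters at their defaults; feature selection is "none"
#' (pass-through).
#'
#' @param space a [search_space()].
#' @param algorithm algorithm id.
#' @return a `configuration` list with fields `algorithm`, `hp`, `fs`,
#'   `provenance`.
#' @export
default_configuration <- function(space, algorithm) {
  alg <- space$algorithms[[algorithm]]
  if (is.null(alg)) stop("unknown algorithm: ", algorithm)
  hp <- lapply(alg$hps, `[[`, "default")
  fs <- c(list(evaluator = "none", search = "topk"),
          lapply(space$fs_hps, `[[`, "default"))
  structure(list(algorithm = algorithm, hp = hp, fs = fs,
                 provenance = "default"),
            class = "configuration")
}

config_signature <- function(config) {
  hp <- config$hp[order(names(config$hp))]
  paste(config$algorithm,
        paste(names(hp), vapply(hp, function(v) format(v, digits = 10), character(1)),
              sep = "=", collapse = ","),
        paste("fs", config$fs$evaluator, config$fs$search,
              format(config$fs$k_frac, digits = 6), sep = ":"),
        sep = "|")
}

sample_hp_value <- function(def) {
  switch(def$kind,
    categorical = sample(def$values, 1L)[[1L]],
    continuous = {
      rng <- hp_search_range(def)
      if (def$log) exp(runif(1L, log(rng[1L]), log(rng[2L]))) else runif(1L, rng[1L], rng[2L])
    },
    integer = {
      rng <- hp_search_range(def)
      if (def$log) {
        round(exp(runif(1L, log(rng[1L]), log(rng[2L]))))
      } else {
        sample(seq.int(rng[1L], rng[2L]), 1L)
      }
    })
}

# the range the main search samples: expensive-monotone params stay capped
hp_search_range <- function(def, capped = TRUE) {
  if (capped && !is.null(def$expensive)) {
    c(def$expensive$cap[1L], def$expensive$cap[2L])
  } else {
    c(def$lower, def$upper)
  }
}

#' Sample random configurations of one algorithm
#'
#' Continuous parameters uniform (log-uniform when flagged), integers
#' uniform inclusive, categoricals uniform; expensive-monotone parameters
#' only inside their capped range; evaluator/search drawn uniformly from
#' the surviving roster. Deterministic per seed.
#'
#' @param space a [search_space()].
#' @param algorithm algorithm id.
#' @param k number of configurations.
#' @param seed integer.
#' @param evaluators surviving evaluator ids (default: all in the space).
#' @return list of `configuration`s.
#' @export
sample_random <- function(space, algorithm, k, seed, evaluators = space$evaluators) {
  alg <- space$algorithms[[algorithm]]
  if (is.null(alg)) stop("unknown algorithm: ", algorithm)
  if (k <= 0) return(list())
  with_seed(derive_seed(seed, "rand", algorithm), {
    lapply(seq_len(k), function(i) {
      hp <- lapply(alg$hps, sample_hp_value)
      fs <- list(evaluator = sample(evaluators, 1L),
                 search = sample(space$searches, 1L),
                 k_frac = sample_hp_value(space$fs_hps$k_frac))
      structure(list(algorithm = algorithm, hp = hp, fs = fs,
                     provenance = "random"),
                class = "configuration")
    })
  })
}

hp_grid <- function(def, steps = 20L, capped = TRUE) {
  rng <- hp_search_range(def, capped)
  g <- if (def$log) exp(seq(log(rng[1L]), log(rng[2L]), length.out = steps + 1L))
       else seq(rng[1L], rng[2L], length.out = steps + 1L)
  if (def$kind == "integer") g <- unique(round(g))
  g
}

nearest_grid_index <- function(def, value, grid) {
  if (def$log) which.min(abs(log(grid) - log(value))) else which.min(abs(grid - value))
}

#' One-step neighbors of a configuration
#'
#' One-parameter perturbations: each numeric parameter moves one step on a
#' 20-step grid over its (capped) range, log-spaced when flagged; each
#' categorical parameter — including the feature evaluator and search
#' method — takes each alternative value. Clipped to range; duplicates (and
#' the input itself) removed.
#'
#' @param space a [search_space()].
#' @param config a `configuration`.
#' @param evaluators surviving evaluator ids.
#' @param steps grid resolution.
#' @return list of neighbor `configuration`s, provenance "local".
#' @export
neighbors <- function(space, config, evaluators = space$evaluators, steps = 20L) {
  alg <- space$algorithms[[config$algorithm]]
  out <- list()
  push <- function(cfg) {
    cfg$provenance <- "local"
    out[[length(out) + 1L]] <<- cfg
  }
  perturb_numeric <- function(def, value, setter) {
    grid <- hp_grid(def, steps)
    i <- nearest_grid_index(def, value, grid)
    for (j in c(i - 1L, i + 1L)) {
      if (j >= 1L && j <= length(grid) && grid[j] != value) setter(grid[j])
    }
  }
  for (nm in names(alg$hps)) {
    def <- alg$hps[[nm]]
    if (def$kind == "categorical") {
      for (v in setdiff(def$values, list(config$hp[[nm]]))) {
        cfg <- config; cfg$hp[[nm]] <- v; push(cfg)
      }
    } else {
      perturb_numeric(def, config$hp[[nm]], function(v) {
        cfg <- config; cfg$hp[[nm]] <- v; push(cfg)
      })
    }
  }
  for (v in setdiff(evaluators, config$fs$evaluator)) {
    cfg <- config; cfg$fs$evaluator <- v; push(cfg)
  }
  for (v in setdiff(space$searches, config$fs$search)) {
    cfg <- config; cfg$fs$search <- v; push(cfg)
  }
  perturb_numeric(space$fs_hps$k_frac, config$fs$k_frac, function(v) {
    cfg <- config; cfg$fs$k_frac <- v; push(cfg)
  })
  sigs <- vapply(out, config_signature, character(1))
  out[!duplicated(sigs) & sigs != config_signature(config)]
}

encoding_dims <- function(space, algorithm, evaluators = space$evaluators) {
  alg <- space$algorithms[[algorithm]]
  dims <- list()
  for (nm in names(alg$hps)) {
    def <- alg$hps[[nm]]
    if (def$kind == "categorical") {
      for (v in def$values) dims[[paste0("hp.", nm, "=", v)]] <- list(hp = nm, value = v)
    } else {
      dims[[paste0("hp.", nm)]] <- list(hp = nm)
    }
  }
  for (v in evaluators) dims[[paste0("fs.evaluator=", v)]] <- list(fs = "evaluator", value = v)
  for (v in space$searches) dims[[paste0("fs.search=", v)]] <- list(fs = "search", value = v)
  dims[["fs.k_frac"]] <- list(fs = "k_frac")
  dims
}

scale_numeric <- function(def, value) {
  rng <- c(def$lower, def$upper)
  if (def$log) {
    (log(value) - log(rng[1L])) / (log(rng[2L]) - log(rng[1L]))
  } else {
    (value - rng[1L]) / (rng[2L] - rng[1L])
  }
}

unscale_numeric <- function(def, u) {
  rng <- c(def$lower, def$upper)
  v <- if (def$log) exp(log(rng[1L]) + u * (log(rng[2L]) - log(rng[1L])))
       else rng[1L] + u * (rng[2L] - rng[1L])
  if (def$kind == "integer") round(v) else v
}

#' Numeric encoding of a configuration (per algorithm)
#'
#' Numeric parameters min-max scaled to \[0, 1\] (log first when flagged);
#' categoricals — including the evaluator (restricted to the surviving
#' roster; a dropped evaluator encodes as all-zeros) and search method —
#' one-hot. The encoding covers only this algorithm's dimensions.
#'
#' @param space a [search_space()].
#' @param config a `configuration`.
#' @param evaluators surviving evaluator ids.
#' @return named numeric vector.
#' @export
encode_configuration <- function(space, config, evaluators = space$evaluators) {
  alg <- space$algorithms[[config$algorithm]]
  dims <- encoding_dims(space, config$algorithm, evaluators)
  out <- numeric(length(dims))
  names(out) <- names(dims)
  for (dn in names(dims)) {
    d <- dims[[dn]]
    out[dn] <- if (!is.null(d$hp)) {
      def <- alg$hps[[d$hp]]
      if (def$kind == "categorical") as.numeric(identical(config$hp[[d$hp]], d$value))
      else scale_numeric(def, config$hp[[d$hp]])
    } else if (d$fs == "k_frac") {
      scale_numeric(space$fs_hps$k_frac, config$fs$k_frac)
    } else {
      as.numeric(identical(config$fs[[d$fs]], d$value))
    }
  }
  out
}

#' @rdname encode_configuration
#' @param x encoded vector from [encode_configuration()].
#' @param algorithm algorithm id of the encoding.
#' @export
decode_configuration <- function(space, x, algorithm, evaluators = space$evaluators) {
  alg <- space$algorithms[[algorithm]]
  cfg <- default_configuration(space, algorithm)
  for (nm in names(alg$hps)) {
    def <- alg$hps[[nm]]
    if (def$kind == "categorical") {
      hits <- vapply(def$values, function(v) x[[paste0("hp.", nm, "=", v)]], numeric(1))
      cfg$hp[[nm]] <- def$values[[which.max(hits)]]
    } else {
      cfg$hp[[nm]] <- unscale_numeric(def, x[[paste0("hp.", nm)]])
    }
  }
  ev_hits <- vapply(evaluators, function(v) x[[paste0("fs.evaluator=", v)]], numeric(1))
  if (any(ev_hits > 0)) cfg$fs$evaluator <- evaluators[which.max(ev_hits)]
  se_hits <- vapply(space$searches, function(v) x[[paste0("fs.search=", v)]], numeric(1))
  cfg$fs$search <- space$searches[which.max(se_hits)]
  cfg$fs$k_frac <- unscale_numeric(space$fs_hps$k_frac, x[["fs.k_frac"]])
  cfg$provenance <- "decoded"
  cfg
}

validate_configuration <- function(space, config) {
  alg <- space$algorithms[[config$algorithm]]
  if (is.null(alg)) return(FALSE)
  for (nm in names(alg$hps)) {
    def <- alg$hps[[nm]]
    v <- config$hp[[nm]]
    if (is.null(v)) return(FALSE)
    if (def$kind == "categorical") {
      if (!any(vapply(def$values, identical, logical(1), v))) return(FALSE)
    } else {
      if (v < def$lower || v > def$upper) return(FALSE)
      if (def$kind == "integer" && v != round(v)) return(FALSE)
    }
  }
  config$fs$evaluator %in% FS_EVALUATORS &&
    config$fs$search %in% FS_SEARCHES &&
    config$fs$k_frac >= space$fs_hps$k_frac$lower &&
    config$fs$k_frac <= space$fs_hps$k_frac$upper
}
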