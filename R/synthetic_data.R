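# Synthetic inputs with known ground truth: an EAV cohort whose target is
# driven by one planted (attribute, period, operator) aggregate, tabular
# benchmarks whose generative family fixes the Bayes-optimal learner
# family, and noisy accuracy-vs-time traces drawn from a known inverse
# power law. Everything is bit-reproducible from its seed.

#' Specify a synthetic EAV cohort
#'
#' @param n_patients number of patients.
#' @param attributes named list; each element is a list with `type`
#'   ("numeric", "event" or "medication"), `rate_per_month` (Poisson event
#'   rate), and `dist` (value distribution: `list(kind = "normal", mean,
#'   sd)`, `list(kind = "lognormal", meanlog, sdlog)` or
#'   `list(kind = "categorical", levels)`).
#' @param horizon_days observation horizon per patient.
#' @param planted an [aggregation_spec()]: the one aggregate the target
#'   depends on.
#' @param link "threshold" (binary target: aggregate above its cohort
#'   median) or "linear" (continuous target proportional to the aggregate).
#' @param noise for "threshold", the label-flip probability; for "linear",
#'   the noise sd as a fraction of the signal sd.
#' @param n_index_dates index dates per patient (1 = end of horizon;
#'   more exercise the multiple-target-instances-per-patient case, spaced a
#'   year apart ending at the horizon).
#' @param seed integer fixing the whole cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, attributes, horizon_days = 730,
                        planted, link = "threshold", noise = 0,
                        n_index_dates = 1L, seed = 1L) {
  stopifnot(inherits(planted, "aggregation_spec"))
  stopifnot(planted$attribute %in% names(attributes))
  ptype <- attributes[[planted$attribute]]$type
  if (!operator_applicable(planted$operator, ptype)) {
    stop("planted operator '", planted$operator,
         "' is not applicable to attribute type '", ptype, "'")
  }
  stopifnot(link %in% c("threshold", "linear"), noise >= 0)
  for (a in attributes) stopifnot(a$rate_per_month > 0)
  structure(list(n_patients = n_patients, attributes = attributes,
                 horizon_days = horizon_days, planted = planted, link = link,
                 noise = noise, n_index_dates = n_index_dates, seed = seed),
            class = "cohort_spec")
}

draw_values <- function(dist, n) {
  switch(dist$kind %||% "normal",
    normal = format(rnorm(n, dist$mean %||% 0, dist$sd %||% 1), digits = 8, trim = TRUE),
    lognormal = format(rlnorm(n, dist$meanlog %||% 0, dist$sdlog %||% 0.5),
                       digits = 8, trim = TRUE),
    categorical = sample(unlist(dist$levels), n, replace = TRUE),
    stop("unknown value distribution: ", dist$kind))
}

#' Generate a synthetic EAV cohort with a planted temporal signal
#'
#' Event times are a homogeneous Poisson process per attribute per patient
#' over the horizon; values follow the attribute's distribution. The target
#' of each (patient, index date) instance is the planted aggregate passed
#' through the link plus the stated noise, so the planted
#' (attribute, period, operator) pair is recoverable by construction.
#'
#' @param spec a [cohort_spec()].
#' @return list: `eav` (an `eav_table`), `instances` (data.frame:
#'   `patient_id`, `index_date`, static features `age`, `sex`, column
#'   `outcome` = the target), `truth` (planted spec, the threshold used,
#'   the noiseless aggregate).
#' @export
generate_eav_cohort <- function(spec) {
  origin <- as.POSIXct("2020-01-01", tz = "UTC")
  if (spec$n_patients == 0) {
    return(list(eav = eav_table(),
                instances = data.frame(patient_id = character(),
                                       index_date = as.POSIXct(character(), tz = "UTC"),
                                       age = numeric(), sex = character(),
                                       outcome = numeric()),
                truth = list(planted = spec$planted)))
  }
  pids <- sprintf("P%05d", seq_len(spec$n_patients))
  horizon_s <- spec$horizon_days * DAY_SECONDS
  rows <- with_seed(derive_seed(spec$seed, "events"), {
    out <- vector("list", length(pids) * length(spec$attributes))
    k <- 0L
    for (pid in pids) {
      for (attribute in names(spec$attributes)) {
        a <- spec$attributes[[attribute]]
        lambda <- a$rate_per_month * spec$horizon_days / 30
        n_ev <- rpois(1L, lambda)
        if (n_ev == 0) next
        times <- sort(runif(n_ev, 0, horizon_s))
        k <- k + 1L
        out[[k]] <- data.frame(patient_id = pid,
                               timestamp = origin + times,
                               attribute = attribute,
                               value = draw_values(a$dist %||% list(kind = "normal"), n_ev),
                               stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
  eav <- eav_table(rows$patient_id, rows$timestamp, rows$attribute, rows$value)

  # index dates: last one at the horizon, earlier ones a year apart
  idx_offsets <- (spec$horizon_days - 365 * (spec$n_index_dates - seq_len(spec$n_index_dates))) *
    DAY_SECONDS
  stopifnot(all(idx_offsets > 0))
  instances <- data.frame(
    patient_id = rep(pids, each = spec$n_index_dates),
    index_date = origin + rep(idx_offsets, times = length(pids)),
    stringsAsFactors = FALSE)
  instances$instance_id <- paste0(instances$patient_id, "#",
                                  rep(seq_len(spec$n_index_dates), length(pids)))

  agg <- pivot_aggregate(eav, list(spec$planted), instances)
  z <- agg[[spec_feature_name(spec$planted)]]
  z[is.na(z)] <- median(z, na.rm = TRUE)

  truth <- list(planted = spec$planted, aggregate = z)
  with_seed(derive_seed(spec$seed, "target"), {
    if (spec$link == "threshold") {
      thr <- median(z)
      y <- as.integer(z > thr)
      if (spec$noise > 0) {
        flip <- runif(length(y)) < spec$noise
        y[flip] <- 1L - y[flip]
      }
      instances$outcome <- factor(y, levels = c(0L, 1L))
      truth$threshold <- thr
    } else {
      s <- sd(z); if (is.na(s) || s == 0) s <- 1
      instances$outcome <- z + rnorm(length(z), 0, spec$noise * s)
    }
  })
  with_seed(derive_seed(spec$seed, "static"), {
    n <- nrow(instances)
    instances$age <- round(runif(n, 18, 90))
    instances$sex <- sample(c("F", "M"), n, replace = TRUE)
  })
  list(eav = eav, instances = instances, truth = truth)
}

#' Specify a tabular benchmark with a known best learner family
#'
#' @param n_instances,n_features table shape.
#' @param family generative family: "rule" (axis-aligned decision rule of
#'   depth `rule_depth`; tree-friendly), "linear" (logistic in a random
#'   linear score; linear-model-friendly) or "interaction" (sign of a
#'   feature product; neither margin nor single split suffices).
#' @param label_noise label-flip probability.
#' @param rule_depth 1 = single-feature threshold; 2 = two-level rule.
#' @param seed integer.
#' @return a `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_instances, n_features = 10L, family = "rule",
                           label_noise = 0, rule_depth = 2L, seed = 1L) {
  stopifnot(family %in% c("rule", "linear", "interaction"),
            n_features >= 1L, label_noise >= 0, label_noise < 0.5)
  structure(list(n_instances = n_instances, n_features = n_features,
                 family = family, label_noise = label_noise,
                 rule_depth = rule_depth, seed = seed),
            class = "benchmark_spec")
}

#' Generate a tabular classification benchmark
#'
#' @param spec a [benchmark_spec()].
#' @return an [instance_table()] with numeric features `x1..xk` and factor
#'   target `y`; attribute `truth` records the generating rule.
#' @export
generate_benchmark <- function(spec) {
  with_seed(derive_seed(spec$seed, "benchmark"), {
    n <- spec$n_instances; p <- spec$n_features
    X <- matrix(rnorm(n * p), nrow = n)
    colnames(X) <- paste0("x", seq_len(p))
    truth <- list(family = spec$family)
    raw <- switch(spec$family,
      rule = {
        if (spec$rule_depth == 1L || p == 1L) {
          truth$rule <- "x1 > 0"
          X[, 1L] > 0
        } else {
          # asymmetric sub-rules give the root split a marginal effect, so
          # the rule is recoverable by greedy axis-aligned partitioning
          truth$rule <- "(x1 > 0 & x2 > -0.5) | (x1 <= 0 & x3 > 0.5)"
          j3 <- min(3L, p)
          (X[, 1L] > 0 & X[, 2L] > -0.5) | (X[, 1L] <= 0 & X[, j3] > 0.5)
        }
      },
      linear = {
        w <- rnorm(p); w <- w / sqrt(sum(w^2))
        truth$weights <- w
        score <- drop(X %*% w) * 3
        runif(n) < stats::plogis(score)
      },
      interaction = {
        truth$rule <- "x1 * x2 > 0"
        X[, 1L] * X[, min(2L, p)] > 0
      })
    y <- as.integer(raw)
    if (spec$label_noise > 0) {
      flip <- runif(n) < spec$label_noise
      y[flip] <- 1L - y[flip]
    }
    df <- as.data.frame(X)
    df$y <- factor(y, levels = c(0L, 1L))
    tbl <- instance_table(df, target = "y")
    attr(tbl, "truth") <- truth
    tbl
  })
}

#' Generate a noisy accuracy-vs-time trace from an inverse power law
#'
#' `y_i = a - b * t_i^-c + eps_i`, `eps ~ N(0, noise_sd^2)`, clipped to
#' \[0, 1\]. Used to exercise the learning-curve fitting in reverse.
#'
#' @param a,b,c law parameters, `0 < b < a < 1`, `c > 0`.
#' @param times positive, strictly increasing time points.
#' @param noise_sd Gaussian noise sd (0 = exact curve).
#' @param seed integer.
#' @param direction "increasing" (`a - b t^-c`) or "decreasing"
#'   (`a + b t^-c`, error-rate style).
#' @return data.frame with columns `t`, `y`.
#' @export
generate_accuracy_trace <- function(a, b, c, times, noise_sd = 0, seed = 1L,
                                    direction = "increasing") {
  stopifnot(c > 0, all(diff(times) > 0), all(times > 0))
  if (direction == "increasing") stopifnot(b > 0, b < a, a < 1)
  mu <- if (direction == "increasing") a - b * times^(-c) else a + b * times^(-c)
  y <- with_seed(derive_seed(seed, "trace"), mu + rnorm(length(times), 0, noise_sd))
  data.frame(t = times, y = pmin(pmax(y, 0), 1))
}
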