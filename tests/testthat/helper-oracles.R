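# Independent brute-force oracles and fixture builders. The oracles are
# written as naive explicit loops over events, on purpose: they share no
# code with the package's operator implementations.

DAY <- 86400

# naive per-event loop oracle for every single-attribute operator
brute_operator <- function(op, times, values, window, params = list()) {
  t_in <- numeric(0); v_in <- character(0)
  for (i in seq_along(times)) {
    if (times[i] > window[1] && times[i] <= window[2]) {
      t_in <- c(t_in, times[i]); v_in <- c(v_in, values[i])
    }
  }
  ord <- order(t_in)
  t_in <- t_in[ord]; v_in <- v_in[ord]
  num <- suppressWarnings(as.numeric(v_in))
  keep <- !(is.na(num) & !is.na(v_in))
  tn <- t_in[keep]; xn <- num[keep]
  strict_mono <- function(x, up) {
    if (length(x) < 2) return(0)
    for (i in 2:length(x)) {
      if (up && x[i] <= x[i - 1]) return(0)
      if (!up && x[i] >= x[i - 1]) return(0)
    }
    1
  }
  freq_mono <- function(up, bin_days) {
    width <- bin_days * DAY
    nb <- floor((window[2] - window[1]) / width + 1e-9)
    if (nb < 2) return(0)
    counts <- numeric(nb)
    for (k in 1:nb) {
      hi <- window[2] - (nb - k) * width
      lo <- hi - width
      for (tt in t_in) if (tt > lo && tt <= hi) counts[k] <- counts[k] + 1
    }
    strict_mono(counts, up)
  }
  switch(op,
    min = if (length(xn)) min(xn) else NA_real_,
    max = if (length(xn)) max(xn) else NA_real_,
    mean = if (length(xn)) sum(xn) / length(xn) else NA_real_,
    most_recent = if (length(xn)) xn[length(xn)] else NA_real_,
    presence = if (length(t_in) > 0) 1 else 0,
    count = length(t_in),
    duration_days = if (length(t_in) >= 2) (t_in[length(t_in)] - t_in[1]) / DAY else 0,
    mono_increasing = strict_mono(xn, TRUE),
    mono_decreasing = strict_mono(xn, FALSE),
    med_intensified = strict_mono(xn, TRUE),
    med_deintensified = strict_mono(xn, FALSE),
    change = if (length(xn)) xn[length(xn)] - xn[1] else NA_real_,
    relative_change = {
      if (length(xn) == 0) NA_real_
      else if (xn[1] == 0) NA_real_
      else (xn[length(xn)] - xn[1]) / abs(xn[1])
    },
    frac_high = if (length(xn)) sum(xn > params$high) / length(xn) else NA_real_,
    frac_low = if (length(xn)) sum(xn < params$low) / length(xn) else NA_real_,
    frac_normal = if (length(xn)) {
      sum(xn >= params$low & xn <= params$high) / length(xn)
    } else NA_real_,
    frac_equal = if (length(xn)) sum(xn == params$value) / length(xn) else NA_real_,
    freq_increasing = freq_mono(TRUE, c(week = 7, month = 30, quarter = 91)[[params$bin]]),
    freq_decreasing = freq_mono(FALSE, c(week = 7, month = 30, quarter = 91)[[params$bin]]),
    stop("no oracle for ", op))
}

# direct-formula entropy oracle for information gain on a 2-way table
ig_from_counts <- function(counts) {
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- sum(counts)
  hy <- h(colSums(counts) / n)
  hc <- 0
  for (r in seq_len(nrow(counts))) {
    hc <- hc + sum(counts[r, ]) / n * h(counts[r, ] / sum(counts[r, ]))
  }
  hy - hc
}

# random event fixture: times in a 120-day span, values numeric with
# occasional non-numeric junk
random_event_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(0:12, 1)
  times <- sort(runif(n, 0, 120 * DAY))
  values <- as.character(round(rnorm(n, 10, 5), 3))
  if (n > 0 && runif(1) < 0.15) values[sample(n, 1)] <- "not-a-number"
  window_start <- runif(1, 0, 40 * DAY)
  window_end <- window_start + runif(1, 20, 80) * DAY
  list(times = times, values = values, window = c(window_start, window_end))
}

# minimal two-attribute knowledge base used across aggregation tests
toy_kb <- function() {
  validate_knowledge_base(list(
    attribute_types = list(ed_visit = "event", weight = "numeric"),
    attribute_groups = list(ed_visit = "utilization", weight = "vitals"),
    groups = list(
      utilization = list(
        list(category = "count", shortest = 30, longest = 360,
             progression = "exponential", factor = 2)),
      vitals = list(
        list(category = "value_summary", shortest = 30, longest = 120,
             progression = "arithmetic", step_days = 30)))
  ))
}

small_cohort_spec <- function(n = 300, noise = 0, seed = 11,
                              n_index_dates = 1L) {
  cohort_spec(
    n_patients = n,
    attributes = list(
      ed_visit = list(type = "event", rate_per_month = 0.5),
      weight = list(type = "numeric", rate_per_month = 1,
                    dist = list(kind = "normal", mean = 80, sd = 12))),
    horizon_days = 730,
    planted = aggregation_spec("ed_visit", 90, "count"),
    link = "threshold", noise = noise, n_index_dates = n_index_dates,
    seed = seed)
}

# quadratic toy response used for surrogate convergence checks
quad_quality <- function(cfg) {
  v <- log10(cfg$hp$lambda)  # in [-5, 1]
  0.9 - 0.05 * (v + 2)^2
}

# timed-trial fixture whose times follow the multiplicative product law
# time = base * size * (ntree / 100), with small lognormal noise
make_timed_trials <- function(space, algorithm, k, seed) {
  cfgs <- sample_random(space, algorithm, k, seed)
  set.seed(seed + 1000)
  lapply(cfgs, function(cfg) {
    size <- sample(c(100, 200, 400), 1)
    t <- 1e-3 * size * (cfg$hp$ntree / 100) * exp(rnorm(1, 0, 0.02))
    list(config = cfg, size = size, time = t, quality = runif(1, 0.5, 0.9),
         status = "completed", algorithm = algorithm,
         signature = clinsearch:::config_signature(cfg))
  })
}
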