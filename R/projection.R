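# Real-time projection of best-so-far model accuracy and expected outcome.
# The best-so-far accuracy curve is modeled by an inverse power law
# f(t) = a - b * t^-c (0 < b < a < 1, c > 0); only the last n = min(g, h)
# recorded points are fitted, the i-th of them weighted i/n so recent
# points dominate. Class-pair confusion fractions get the same treatment
# (diagonal pairs increasing, off-diagonal decreasing, a + b * t^-c), and
# the expected outcome at a future time is sum over class pairs of
# q_c1 * p_c1c2(t) * o_c1c2.

#' Create / update a best-so-far accuracy curve
#'
#' `record_point` appends the running maximum of quality at a strictly
#' later time; `h` counts points recorded so far.
#'
#' @param g window parameter: at most the last `min(g, h)` points are
#'   fitted (default 20).
#' @return an `accuracy_curve` list with fields `t`, `y`, `g`, `h`.
#' @export
accuracy_curve <- function(g = 20L) {
  structure(list(t = numeric(), y = numeric(), g = as.integer(g), h = 0L),
            class = "accuracy_curve")
}

#' @rdname accuracy_curve
#' @param curve an `accuracy_curve`.
#' @param t time of the new point (seconds since search start); must
#'   exceed the last recorded time.
#' @param quality the new model's quality; the stored value is the
#'   best-so-far maximum.
#' @export
record_point <- function(curve, t, quality) {
  if (curve$h > 0 && t <= curve$t[curve$h]) {
    stop("time must be strictly increasing")
  }
  y <- if (curve$h > 0) max(quality, curve$y[curve$h]) else quality
  curve$t <- c(curve$t, t)
  curve$y <- c(curve$y, y)
  curve$h <- curve$h + 1L
  curve
}

ipl_value <- function(t, a, b, c, direction = "increasing") {
  if (direction == "increasing") a - b * t^(-c) else a + b * t^(-c)
}

#' Fit a weighted inverse power law to the recent curve window
#'
#' Minimizes `sum_i (i/n) * (f(t_i) - y_i)^2` over the last
#' `n = min(g, h)` points. The increasing form `a - b t^-c` is constrained
#' to `0 < b < a < 1, c > 0` via a smooth reparameterization
#' (`a = logistic(alpha)`, `b = a * logistic(beta)`, `c = exp(gamma)`); the
#' decreasing form `a + b t^-c` requires only `a in (0,1)`, `b > 0`.
#' Optimization is L-BFGS-B from 16 seeded starts; deterministic given
#' `seed`. Times are shifted by +1 before fitting so `t^-c` is bounded on
#' the observed window (undone nowhere: projections use the same shift).
#'
#' @param curve an `accuracy_curve`, or any list with `t`, `y` (and
#'   optionally `g`, `h`).
#' @param direction "increasing" (accuracy-like) or "decreasing"
#'   (error-like).
#' @param seed integer for the multi-start draws.
#' @param n_starts number of optimizer starts.
#' @param shift added to `t` before fitting (default 1).
#' @return a `power_law_fit` list: `a`, `b`, `c`, `direction`, `sse`
#'   (weighted), `window` (the fitted points), `shift`; or `NULL` when
#'   fewer than 3 distinct times are available (projection unavailable).
#' @export
fit_inverse_power <- function(curve, direction = "increasing", seed = 1L,
                              n_starts = 16L, shift = 1) {
  h <- curve$h %||% length(curve$t)
  g <- curve$g %||% 20L
  n <- min(g, h)
  if (n < 3L) return(NULL)
  idx <- seq.int(h - n + 1L, h)
  t <- curve$t[idx] + shift
  y <- curve$y[idx]
  if (length(unique(t)) < 3L) return(NULL)
  w <- seq_len(n) / n

  increasing <- direction == "increasing"
  unpack <- function(par) {
    a <- stats::plogis(par[1L])
    b <- if (increasing) a * stats::plogis(par[2L]) else exp(par[2L])
    c <- exp(par[3L])
    c(a = a, b = b, c = c)
  }
  obj <- function(par) {
    p <- unpack(par)
    if (!is.finite(p["c"]) || p["c"] > 50) return(1e10)
    f <- ipl_value(t, p["a"], p["b"], p["c"], direction)
    sum(w * (f - y)^2)
  }
  starts <- with_seed(derive_seed(seed, "ipl-starts"), {
    lapply(seq_len(n_starts), function(i) {
      c(stats::qlogis(runif(1, 0.3, 0.99)),
        if (increasing) stats::qlogis(runif(1, 0.05, 0.95)) else log(runif(1, 0.01, 2)),
        log(runif(1, 0.05, 5)))
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = rep(-15, 3), upper = c(15, 15, log(50)),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  p <- unpack(best$par)
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 direction = direction, sse = best$value,
                 window = data.frame(t = t - shift, y = y, w = w),
                 shift = shift),
            class = "power_law_fit")
}

#' Project model accuracy at a future time
#'
#' Plug-in evaluation of the fitted law; an increasing fit is monotone
#' nondecreasing in `t` and never exceeds its own asymptote `a`.
#'
#' @param fit a `power_law_fit` (or `NULL`: returns `NA`, projection
#'   unavailable).
#' @param t_future future time(s) on the curve's time scale.
#' @return projected quality value(s).
#' @export
project_accuracy <- function(fit, t_future) {
  if (is.null(fit)) return(NA_real_)
  ipl_value(t_future + fit$shift, fit$a, fit$b, fit$c, fit$direction)
}

#' Fit class-pair confusion-fraction curves
#'
#' For each ordered class pair (c1, c2), the fraction of test instances of
#' class c1 that the best model at time t predicts as c2 is fitted against
#' time: diagonal pairs (accuracy-like, tending to increase) with the
#' increasing form, off-diagonal pairs (error-like) with the decreasing
#' form `a + b t^-c`.
#'
#' @param history data.frame with columns `t`, `c1`, `c2`, `p` (as
#'   produced in a `search_result`'s `confusion_history`).
#' @param g window parameter.
#' @param seed integer.
#' @return named list of `power_law_fit`s keyed `"c1->c2"`, with the class
#'   levels in attribute `classes`.
#' @export
fit_class_pair_curves <- function(history, g = 20L, seed = 1L) {
  classes <- unique(c(history$c1, history$c2))
  fits <- list()
  for (c1 in classes) {
    for (c2 in classes) {
      sub <- history[history$c1 == c1 & history$c2 == c2, , drop = FALSE]
      sub <- sub[order(sub$t), , drop = FALSE]
      key <- paste0(c1, "->", c2)
      if (nrow(sub) == 0) { fits[key] <- list(NULL); next }
      direction <- if (c1 == c2) "increasing" else "decreasing"
      crv <- list(t = sub$t, y = sub$p, g = g, h = nrow(sub))
      fits[[key]] <- fit_inverse_power(crv, direction, seed = seed)
    }
  }
  attr(fits, "classes") <- classes
  fits
}

#' Projected confusion matrix at a future time
#'
#' Evaluates every fitted class-pair curve at `t_future`, clips to
#' \[0, 1\], and renormalizes each row of the projected matrix to sum
#' to 1 (the pair fits are independent, so the simplex constraint is
#' restored explicitly).
#'
#' @param fits result of [fit_class_pair_curves()].
#' @param t_future future time.
#' @return matrix `p` with `p[c1, c2]` the projected fraction of class-c1
#'   instances predicted as c2; rows sum to 1.
#' @export
project_confusion <- function(fits, t_future) {
  classes <- attr(fits, "classes")
  p <- matrix(0, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (c1 in classes) {
    for (c2 in classes) {
      f <- fits[[paste0(c1, "->", c2)]]
      p[c1, c2] <- if (is.null(f)) {
        if (c1 == c2) 1 else 0
      } else {
        min(max(project_accuracy(f, t_future), 0), 1)
      }
    }
    s <- sum(p[c1, ])
    if (s > 0) p[c1, ] <- p[c1, ] / s else p[c1, c1] <- 1
  }
  p
}

#' Outcome specification for projection
#'
#' @param classes class labels.
#' @param q class proportions (`sum(q) = 1`).
#' @param o outcome matrix: `o[c1, c2]` is the user-specified outcome
#'   (e.g. cost) when an average instance of class c1 is predicted as c2.
#' @return an `outcome_spec` list.
#' @export
outcome_spec <- function(classes, q, o) {
  q <- as.numeric(q)
  o <- as.matrix(o)
  stopifnot(length(q) == length(classes),
            abs(sum(q) - 1) < 1e-9,
            all(dim(o) == length(classes)))
  dimnames(o) <- list(classes, classes)
  structure(list(classes = classes, q = setNames(q, classes), o = o),
            class = "outcome_spec")
}

#' Projected expected outcome of using the best model at a future time
#'
#' `sum_{c1, c2} q_c1 * p_c1c2 * o_c1c2`, where `q_c1 * p_c1c2` is the
#' expected fraction of instances in class c1 predicted as c2.
#'
#' @param spec an [outcome_spec()].
#' @param p projected confusion matrix (rows: true class; columns:
#'   predicted), e.g. from [project_confusion()].
#' @return scalar expected outcome.
#' @export
project_outcome <- function(spec, p) {
  p <- as.matrix(p)
  stopifnot(all(dim(p) == length(spec$classes)))
  sum(spec$q * rowSums(p * spec$o))
}

#' Discretize a continuous target into an outcome specification
#'
#' Continuous targets are handled through quantile discretization: the
#' target is cut into `bins` equal-frequency bins, whose empirical
#' proportions become the class proportions of the returned spec.
#'
#' @param target numeric target values.
#' @param o outcome matrix over the bins (`bins x bins`).
#' @param bins number of quantile bins.
#' @return list: `spec` (an [outcome_spec()]), `breaks` (bin edges),
#'   `bin_of` (factor of bin memberships).
#' @export
handle_continuous_target <- function(target, o, bins = 2L) {
  stopifnot(bins >= 1L)
  if (bins == 1L) {
    spec <- outcome_spec("bin1", 1, matrix(o[1L], 1, 1))
    return(list(spec = spec, breaks = range(target),
                bin_of = factor(rep("bin1", length(target)))))
  }
  breaks <- unique(quantile(target, probs = seq(0, 1, length.out = bins + 1L)))
  bin_of <- cut(target, breaks = breaks, include.lowest = TRUE)
  classes <- paste0("bin", seq_len(nlevels(bin_of)))
  levels(bin_of) <- classes
  q <- as.numeric(table(bin_of)) / length(target)
  o <- as.matrix(o)[seq_along(classes), seq_along(classes), drop = FALSE]
  list(spec = outcome_spec(classes, q, o), breaks = breaks, bin_of = bin_of)
}
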