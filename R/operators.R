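# Temporal aggregation operator catalog. Operators collapse the events of
# one clinical attribute inside a lookback window ending at the instance's
# index date into a single feature value. Operators in the same category
# yield relatively redundant values; selection keeps one winner per
# (attribute, category).

DAY_SECONDS <- 86400

#' The temporal aggregation operator catalog
#'
#' Ten operator families: value min/max/mean; presence; duration of use;
#' event count; value monotonically increasing/decreasing; most recent
#' value; (relative) change in value; fraction of values
#' high/low/normal/equal-to-a-given-value; weekly/monthly/quarterly event
#' frequency monotonically increasing/decreasing; and medication
#' intensified/de-intensified (dose-trend reading). Two-attribute operators
#' (`event_before_event`) are handled separately. `med_switched` and
#' `med_multi_therapy` are registered but not implemented (no accepted
#' operational definition); constructing them errors.
#'
#' @return data.frame with columns `id`, `category`, `applies_to`
#'   (comma-joined attribute types), `needs_numeric`, `output`, `order`.
#' @export
operator_catalog <- function() {
  ops <- list(
    list("min",            "value_summary", "numeric",            TRUE,  "numeric"),
    list("max",            "value_summary", "numeric",            TRUE,  "numeric"),
    list("mean",           "value_summary", "numeric",            TRUE,  "numeric"),
    list("presence",       "presence",      "numeric,event,medication", FALSE, "binary"),
    list("duration_days",  "duration",      "medication,event",   FALSE, "duration-days"),
    list("count",          "count",         "numeric,event,medication", FALSE, "count"),
    list("mono_increasing","value_trend",   "numeric",            TRUE,  "binary"),
    list("mono_decreasing","value_trend",   "numeric",            TRUE,  "binary"),
    list("most_recent",    "recent_value",  "numeric",            TRUE,  "numeric"),
    list("change",         "value_change",  "numeric",            TRUE,  "numeric"),
    list("relative_change","value_change",  "numeric",            TRUE,  "numeric"),
    list("frac_high",      "value_fraction","numeric",            TRUE,  "numeric"),
    list("frac_low",       "value_fraction","numeric",            TRUE,  "numeric"),
    list("frac_normal",    "value_fraction","numeric",            TRUE,  "numeric"),
    list("frac_equal",     "value_fraction","numeric",            TRUE,  "numeric"),
    list("freq_increasing","freq_trend",    "numeric,event,medication", FALSE, "binary"),
    list("freq_decreasing","freq_trend",    "numeric,event,medication", FALSE, "binary"),
    list("med_intensified","med_intensity", "medication",         TRUE,  "binary"),
    list("med_deintensified","med_intensity","medication",        TRUE,  "binary"),
    list("med_switched",   "med_regimen",   "medication",         FALSE, "binary"),
    list("med_multi_therapy","med_regimen", "medication",         FALSE, "binary")
  )
  data.frame(
    id = vapply(ops, `[[`, character(1), 1L),
    category = vapply(ops, `[[`, character(1), 2L),
    applies_to = vapply(ops, `[[`, character(1), 3L),
    needs_numeric = vapply(ops, `[[`, logical(1), 4L),
    output = vapply(ops, `[[`, character(1), 5L),
    order = seq_along(ops),
    stringsAsFactors = FALSE
  )
}

UNIMPLEMENTED_OPERATORS <- c("med_switched", "med_multi_therapy")

operator_applicable <- function(op_id, attr_type) {
  cat <- operator_catalog()
  row <- cat[cat$id == op_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown operator: ", op_id)
  attr_type %in% strsplit(row$applies_to, ",")[[1L]]
}

#' Apply one aggregation operator to the events of one attribute
#'
#' The window is half-open `(start, end]` with `end` at the index date: an
#' event exactly at the window start never contributes, one exactly at the
#' end always does. Empty-window policy: numeric-output operators return
#' `NA` (imputed downstream); presence/count/duration/trend/flag operators
#' return 0. Monotonicity operators require at least 2 in-window events
#' (strict ordering); frequency-trend operators require at least 2 complete
#' bins, binned backwards from the window end (7/30/91-day bins), dropping
#' any partial leading bin.
#'
#' @param op_id operator id from [operator_catalog()].
#' @param times event times, numeric seconds (or `POSIXct`), sorted ascending.
#' @param values event values as character (numeric operators parse them;
#'   unparseable values are skipped and counted in attribute `n_skipped`).
#' @param window numeric length-2 `(start, end]` in the same time scale.
#' @param params named list of extra parameters: `low`/`high` reference
#'   bounds for `frac_high`/`frac_low`/`frac_normal`; `value` for
#'   `frac_equal`; `bin` ("week", "month", "quarter") for frequency trends.
#' @return a single value per the operator's output type; `NA` for empty
#'   windows of numeric operators.
#' @export
apply_operator <- function(op_id, times, values, window, params = list()) {
  if (op_id %in% UNIMPLEMENTED_OPERATORS) {
    stop("operator '", op_id, "' is registered but has no accepted definition; not implemented")
  }
  times <- as.numeric(times)
  start <- as.numeric(window[[1L]]); end <- as.numeric(window[[2L]])
  keep <- times > start & times <= end
  t_in <- times[keep]
  v_in <- values[keep]
  n_skipped <- 0L

  cat <- operator_catalog()
  needs_num <- cat$needs_numeric[cat$id == op_id]
  if (length(needs_num) == 0) stop("unknown operator: ", op_id)
  if (needs_num) {
    x <- suppressWarnings(as.numeric(v_in))
    bad <- is.na(x) & !is.na(v_in)
    n_skipped <- sum(bad)
    t_in <- t_in[!bad]
    x <- x[!bad]
  }

  res <- switch(op_id,
    min = if (length(x)) min(x) else NA_real_,
    max = if (length(x)) max(x) else NA_real_,
    mean = if (length(x)) mean(x) else NA_real_,
    most_recent = if (length(x)) x[which.max(t_in)] else NA_real_,
    presence = as.numeric(length(t_in) > 0),
    count = length(t_in),
    duration_days = if (length(t_in) >= 2L) (max(t_in) - min(t_in)) / DAY_SECONDS else 0,
    mono_increasing = mono_flag(t_in, x, increasing = TRUE),
    mono_decreasing = mono_flag(t_in, x, increasing = FALSE),
    change = change_value(t_in, x, relative = FALSE),
    relative_change = change_value(t_in, x, relative = TRUE),
    frac_high = frac_value(x, function(v) v > param_req(params, "high", op_id)),
    frac_low = frac_value(x, function(v) v < param_req(params, "low", op_id)),
    frac_normal = frac_value(x, function(v) {
      v >= param_req(params, "low", op_id) & v <= param_req(params, "high", op_id)
    }),
    frac_equal = frac_value(x, function(v) v == param_req(params, "value", op_id)),
    freq_increasing = freq_trend(t_in, start, end, params$bin %||% "month", TRUE),
    freq_decreasing = freq_trend(t_in, start, end, params$bin %||% "month", FALSE),
    med_intensified = mono_flag(t_in, x, increasing = TRUE),
    med_deintensified = mono_flag(t_in, x, increasing = FALSE),
    stop("unknown operator: ", op_id)
  )
  attr(res, "n_skipped") <- n_skipped
  res
}

param_req <- function(params, name, op_id) {
  if (is.null(params[[name]])) {
    stop("operator '", op_id, "' requires parameter '", name, "'")
  }
  params[[name]]
}

mono_flag <- function(t_in, x, increasing) {
  if (length(x) < 2L) return(0)
  x <- x[order(t_in)]
  d <- diff(x)
  as.numeric(if (increasing) all(d > 0) else all(d < 0))
}

change_value <- function(t_in, x, relative) {
  if (length(x) == 0) return(NA_real_)
  ord <- order(t_in)
  first <- x[ord[1L]]; last <- x[ord[length(ord)]]
  if (!relative) return(last - first)
  if (first == 0) return(NA_real_)
  (last - first) / abs(first)
}

frac_value <- function(x, pred) {
  if (length(x) == 0) return(NA_real_)
  mean(pred(x))
}

BIN_DAYS <- c(week = 7, month = 30, quarter = 91)

# Bin the window backwards from its end into whole week/month/quarter bins,
# dropping the partial leading (oldest) bin; strict monotone event counts.
freq_trend <- function(t_in, start, end, bin, increasing) {
  if (!bin %in% names(BIN_DAYS)) stop("unknown frequency bin: ", bin)
  width <- BIN_DAYS[[bin]] * DAY_SECONDS
  n_bins <- floor((end - start) / width + 1e-9)
  if (n_bins < 2L) return(0)
  counts <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    # bin k counted from the oldest complete bin forward to the window end
    hi <- end - (n_bins - k) * width
    lo <- hi - width
    counts[k] <- sum(t_in > lo & t_in <= hi)
  }
  d <- diff(counts)
  as.numeric(if (increasing) all(d > 0) else all(d < 0))
}

#' Two-attribute operator: did A occur shortly before a qualifying B?
#'
#' Returns 1 iff some event of attribute A and some qualifying event of
#' attribute B both fall in the window with
#' `0 < time(B) - time(A) <= gap_days` — e.g. a medication prescribed within
#' a gap before an abnormal lab result.
#'
#' @param times_a,times_b event times of A and of qualifying B (seconds or
#'   `POSIXct`); the caller applies the qualification predicate to B first.
#' @param gap_days maximum allowed gap in days.
#' @param window half-open `(start, end]`.
#' @return 0 or 1.
#' @export
event_before_event <- function(times_a, times_b, gap_days, window) {
  ta <- as.numeric(times_a); tb <- as.numeric(times_b)
  start <- as.numeric(window[[1L]]); end <- as.numeric(window[[2L]])
  ta <- ta[ta > start & ta <= end]
  tb <- tb[tb > start & tb <= end]
  if (length(ta) == 0 || length(tb) == 0) return(0)
  gap <- gap_days * DAY_SECONDS
  for (a in ta) {
    if (any(tb - a > 0 & tb - a <= gap)) return(1)
  }
  0
}
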