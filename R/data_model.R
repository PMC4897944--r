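# Domain containers: tall EAV event tables and wide per-instance tables,
# plus deterministic splitting and the doubling sample schedule that drives
# the progressive search.

#' Construct an EAV event table
#'
#' One row per clinical event observation. The entity is the combination of
#' patient identifier and timestamp; the attribute names the clinical
#' parameter and the value holds its (string or numeric) reading.
#'
#' @param patient_id character vector of patient identifiers.
#' @param timestamp ISO-8601 datetimes (`POSIXct` or parseable strings,
#'   timezone-naive by convention, compared as UTC).
#' @param attribute non-empty attribute identifier strings.
#' @param value character or numeric values; numeric strings are kept as-is
#'   and parsed by numeric operators on demand.
#' @return a `data.frame` of class `eav_table` with columns
#'   `patient_id`, `timestamp`, `attribute`, `value`.
#' @export
eav_table <- function(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      attribute = character(), value = character()) {
  if (is.character(timestamp)) {
    timestamp <- parse_iso8601(timestamp)
  }
  stopifnot(all(nzchar(attribute)))
  df <- data.frame(patient_id = as.character(patient_id),
                   timestamp = timestamp,
                   attribute = as.character(attribute),
                   value = as.character(value),
                   stringsAsFactors = FALSE)
  class(df) <- c("eav_table", "data.frame")
  df
}

parse_iso8601 <- function(x) {
  # strptime-based so unparseable strings yield NA (reported and dropped by
  # the reader) instead of an error
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    idx <- which(is.na(out))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

#' Read an EAV CSV file
#'
#' Expects a header with columns mapping to `patient_id`, `timestamp`,
#' `attribute`, `value` (names overridable through `dialect`). Rows whose
#' timestamp does not parse are dropped and counted rather than failing the
#' whole read.
#'
#' @param path CSV path (UTF-8, RFC-4180).
#' @param dialect optional named list remapping header names, e.g.
#'   `list(patient_id = "pid")`.
#' @return the `eav_table`; attribute `dropped` carries the number of rows
#'   removed for unparseable timestamps.
#' @export
read_eav_csv <- function(path, dialect = list()) {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- c(patient_id = "patient_id", timestamp = "timestamp",
            attribute = "attribute", value = "value")
  for (nm in names(dialect)) cols[[nm]] <- dialect[[nm]]
  missing_cols <- setdiff(unname(cols), names(raw))
  if (nrow(raw) == 0 && length(missing_cols) == length(cols)) {
    out <- eav_table()
    attr(out, "dropped") <- 0L
    return(out)
  }
  if (length(missing_cols) > 0) {
    stop("EAV file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- suppressWarnings(parse_iso8601(raw[[cols[["timestamp"]]]]))
  ok <- !is.na(ts) & nzchar(raw[[cols[["attribute"]]]])
  dropped <- sum(!ok)
  if (dropped > 0) {
    warning(dropped, " EAV row(s) dropped (unparseable timestamp or empty attribute)")
  }
  out <- eav_table(patient_id = raw[[cols[["patient_id"]]]][ok],
                   timestamp = ts[ok],
                   attribute = raw[[cols[["attribute"]]]][ok],
                   value = raw[[cols[["value"]]]][ok])
  attr(out, "dropped") <- dropped
  out
}

#' Write an EAV table to CSV
#' @param eav an `eav_table`.
#' @param path output path.
#' @export
write_eav_csv <- function(eav, path) {
  out <- as.data.frame(eav)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a wide per-instance table
#'
#' Rows are prediction instances (typically one per patient and index date);
#' columns are features plus an optional typed target. Missing values are
#' `NA` and imputed downstream inside each training fold.
#'
#' @param data data.frame of features (numeric or factor columns).
#' @param instance_id unique instance identifiers (default: row numbers).
#' @param target optional name of the target column in `data`.
#' @param target_type "categorical" or "continuous"; inferred from the
#'   column's class when omitted.
#' @param index_date optional per-instance anchor datetimes.
#' @return a `data.frame` of class `instance_table` with attributes
#'   `target`, `target_type`, `index_date`.
#' @export
instance_table <- function(data, instance_id = NULL, target = NULL,
                           target_type = NULL, index_date = NULL) {
  stopifnot(!anyDuplicated(names(data)))
  if (is.null(instance_id)) instance_id <- as.character(seq_len(nrow(data)))
  stopifnot(!anyDuplicated(instance_id))
  df <- data
  df$.instance_id <- as.character(instance_id)
  if (!is.null(target)) {
    stopifnot(target %in% names(data))
    if (is.null(target_type)) {
      target_type <- if (is.numeric(data[[target]])) "continuous" else "categorical"
    }
    if (target_type == "categorical" && !is.factor(df[[target]])) {
      df[[target]] <- factor(df[[target]])
    }
  }
  attr(df, "target") <- target
  attr(df, "target_type") <- target_type
  attr(df, "index_date") <- index_date
  class(df) <- c("instance_table", "data.frame")
  df
}

instance_ids <- function(tbl) tbl$.instance_id
target_col <- function(tbl) attr(tbl, "target")
target_type <- function(tbl) attr(tbl, "target_type")

feature_names <- function(tbl) {
  setdiff(names(tbl), c(".instance_id", target_col(tbl)))
}

subset_instances <- function(tbl, ids) {
  out <- tbl[match(ids, tbl$.instance_id), , drop = FALSE]
  idx <- attr(tbl, "index_date")
  attr(out, "target") <- attr(tbl, "target")
  attr(out, "target_type") <- attr(tbl, "target_type")
  attr(out, "index_date") <- if (!is.null(idx)) idx[match(ids, tbl$.instance_id)]
  class(out) <- class(tbl)
  rownames(out) <- NULL
  out
}

#' Write / read a wide instance table as CSV with a type sidecar
#'
#' The CSV holds the data (empty field = missing); a small JSON sidecar
#' (`<path>.types.json`) records the declared column types and the target so
#' that reading round-trips values and types exactly.
#'
#' @param tbl an `instance_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_instance_csv <- function(tbl, path) {
  df <- as.data.frame(tbl)
  meta <- list(
    target = target_col(tbl),
    target_type = target_type(tbl),
    types = lapply(df, function(col) {
      if (is.factor(col)) list(kind = "factor", levels = levels(col))
      else if (is.numeric(col)) list(kind = "numeric")
      else list(kind = "character")
    })
  )
  jsonlite::write_json(meta, paste0(path, ".types.json"), auto_unbox = TRUE, null = "null")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_instance_csv
#' @export
read_instance_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".types.json"))
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = "character")
  for (nm in names(meta$types)) {
    kind <- meta$types[[nm]]$kind
    if (kind == "numeric") df[[nm]] <- as.numeric(df[[nm]])
    if (kind == "factor") {
      df[[nm]] <- factor(df[[nm]], levels = unlist(meta$types[[nm]]$levels))
    }
  }
  ids <- df$.instance_id
  df$.instance_id <- NULL
  instance_table(df, instance_id = ids,
                 target = meta$target %||% NULL,
                 target_type = meta$target_type %||% NULL)
}

#' Stratified random split into disjoint parts
#'
#' With a categorical target the per-class proportions of every part are
#' within one instance of exact stratification; otherwise the split is
#' simple random. Deterministic given `seed`.
#'
#' @param tbl an `instance_table`.
#' @param fractions numeric vector summing to 1.
#' @param seed integer.
#' @return list of `instance_table`s partitioning `tbl`.
#' @export
stratified_split <- function(tbl, fractions, seed) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n_parts <- length(fractions)
  ids <- instance_ids(tbl)
  tgt <- target_col(tbl)
  assign_part <- function(k) {
    # largest-remainder apportionment of k items over the fractions
    exact <- fractions * k
    base <- floor(exact)
    rem <- k - sum(base)
    if (rem > 0) {
      order_rem <- order(exact - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
    }
    rep(seq_len(n_parts), times = base)
  }
  part_of <- integer(length(ids))
  with_seed(derive_seed(seed, "split"), {
    if (!is.null(tgt) && identical(target_type(tbl), "categorical")) {
      cls <- tbl[[tgt]]
      for (lv in levels(cls)) {
        idx <- which(cls == lv)
        if (length(idx) < n_parts) {
          warning("class ", lv, " has fewer instances than parts; round-robin assignment")
          part_of[sample(idx)] <- rep_len(seq_len(n_parts), length(idx))
        } else {
          part_of[sample(idx)] <- assign_part(length(idx))
        }
      }
    } else {
      part_of[sample(seq_along(ids))] <- assign_part(length(ids))
    }
  })
  lapply(seq_len(n_parts), function(p) subset_instances(tbl, ids[part_of == p]))
}

#' Progressive-sampling schedule
#'
#' Carves a fixed test sample from the pool, then builds nested training
#' samples starting at `initial_size` and doubling each round until the full
#' training pool is reached (the final round always uses the full pool; a
#' shortfall round is capped there).
#'
#' @param tbl an `instance_table` (stratified carving when its target is
#'   categorical).
#' @param initial_size first-round training-sample size; default
#'   `min(ceiling(pool/8), 500)` with a floor of 2 per class.
#' @param test_fraction fraction held out as the fixed test sample, in
#'   (0, 0.5]; a further `holdout_fraction` of that split is reserved as an
#'   untouched final holdout (the search never sees it).
#' @param holdout_fraction fraction of the test split kept for final
#'   reporting only.
#' @param seed integer controlling all sampling.
#' @return a `sample_schedule` list: `sizes`, `train_ids` (nested list),
#'   `test_ids`, `holdout_ids`, `seed`.
#' @export
make_schedule <- function(tbl, initial_size = NULL, test_fraction = 0.2,
                          holdout_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction <= 0.5)
  parts <- stratified_split(tbl, c(1 - test_fraction, test_fraction), seed)
  train_pool <- instance_ids(parts[[1L]])
  eval_split <- stratified_split(parts[[2L]],
                                 c(1 - holdout_fraction, holdout_fraction),
                                 derive_seed(seed, "holdout"))
  test_ids <- instance_ids(eval_split[[1L]])
  holdout_ids <- instance_ids(eval_split[[2L]])
  pool_n <- length(train_pool)
  n_class <- if (identical(target_type(tbl), "categorical")) {
    nlevels(tbl[[target_col(tbl)]])
  } else 1L
  if (is.null(initial_size)) {
    initial_size <- max(min(ceiling(pool_n / 8), 500L), 2L * n_class)
  }
  if (initial_size >= pool_n) {
    warning("initial size >= training pool; single-round schedule")
    sizes <- pool_n
  } else {
    sizes <- initial_size
    while (tail(sizes, 1L) < pool_n) {
      sizes <- c(sizes, min(2L * tail(sizes, 1L), pool_n))
    }
  }
  # nested training samples: a seeded stratified order of the pool, prefixes
  pool_tbl <- subset_instances(tbl, train_pool)
  ordered_ids <- stratified_order(pool_tbl, derive_seed(seed, "order"))
  train_ids <- lapply(sizes, function(s) ordered_ids[seq_len(s)])
  structure(list(sizes = sizes, train_ids = train_ids, test_ids = test_ids,
                 holdout_ids = holdout_ids, seed = seed),
            class = "sample_schedule")
}

# A permutation of instance ids whose every prefix is close to stratified:
# classes are interleaved proportionally via cumulative quotas.
stratified_order <- function(tbl, seed) {
  ids <- instance_ids(tbl)
  tgt <- target_col(tbl)
  if (is.null(tgt) || !identical(target_type(tbl), "categorical")) {
    return(with_seed(seed, sample(ids)))
  }
  cls <- tbl[[tgt]]
  with_seed(seed, {
    by_class <- lapply(levels(cls), function(lv) sample(ids[cls == lv]))
  })
  n_by <- vapply(by_class, length, integer(1))
  n <- length(ids)
  taken <- integer(length(by_class))
  out <- character(n)
  for (i in seq_len(n)) {
    # take from the class furthest behind its proportional quota
    deficit <- (n_by / n) * i - taken
    deficit[taken >= n_by] <- -Inf
    k <- which.max(deficit)
    taken[k] <- taken[k] + 1L
    out[i] <- by_class[[k]][taken[k]]
  }
  out
}
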