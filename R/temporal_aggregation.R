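# Automated selection of temporal aggregation periods and operators.
# For every clinical attribute covered by the knowledge base, all
# period x operator pairs of each related operator category are enumerated,
# each candidate feature is scored on a seeded sample of instances, and
# exactly one winning pair per (attribute, category) is computed on all
# instances and joined into the wide table.

#' Enumerate candidate aggregation periods
#'
#' Starting from the shortest period, lengths grow exponentially (by
#' `factor`) or arithmetically (by `step_days`) until the longest period is
#' reached; when the progression overshoots, the longest period itself is
#' appended so the schedule's upper bound is always a candidate.
#'
#' @param shortest,longest period bounds in days, `0 < shortest <= longest`.
#' @param progression "exponential" or "arithmetic".
#' @param factor growth factor (> 1) for exponential progression.
#' @param step_days increment (> 0) for arithmetic progression.
#' @return strictly increasing numeric vector of period lengths in days.
#' @export
enumerate_periods <- function(shortest, longest, progression = "exponential",
                              factor = 2, step_days = 30) {
  stopifnot(shortest > 0, shortest <= longest)
  periods <- shortest
  if (shortest < longest) {
    repeat {
      nxt <- if (progression == "exponential") {
        stopifnot(factor > 1)
        tail(periods, 1L) * factor
      } else if (progression == "arithmetic") {
        stopifnot(step_days > 0)
        tail(periods, 1L) + step_days
      } else stop("unknown progression: ", progression)
      if (nxt > longest) break
      periods <- c(periods, nxt)
    }
    if (tail(periods, 1L) < longest) periods <- c(periods, longest)
  }
  periods
}

#' Read a temporal-aggregation knowledge base (YAML or JSON)
#'
#' The knowledge base maps attributes to attribute groups and each group to
#' a list of related operator categories with their period schedules. It is
#' deliberately partial: only attributes it covers are aggregated. Schema:
#' `attribute_types` (attribute -> numeric|event|medication),
#' `attribute_groups` (attribute -> group), `groups` (group -> list of
#' `{category, shortest, longest, progression, factor|step_days, params}`),
#' optional `reference_ranges` (attribute -> `{low, high}`).
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return the knowledge base as a named list, class `knowledge_base`.
#' @export
read_knowledge_base <- function(path) {
  kb <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  validate_knowledge_base(kb)
}

#' @rdname read_knowledge_base
#' @param kb a knowledge-base list built in code.
#' @export
validate_knowledge_base <- function(kb) {
  stopifnot(is.list(kb$attribute_groups), is.list(kb$groups))
  catalog <- operator_catalog()
  for (grp in names(kb$groups)) {
    for (entry in kb$groups[[grp]]) {
      if (!entry$category %in% catalog$category) {
        stop("knowledge base references unknown operator category: ", entry$category)
      }
      stopifnot(entry$shortest > 0, entry$shortest <= entry$longest)
    }
  }
  structure(kb, class = c("knowledge_base", "list"))
}

kb_attr_type <- function(kb, attribute) {
  kb$attribute_types[[attribute]] %||% "event"
}

kb_entries_for <- function(kb, attribute) {
  grp <- kb$attribute_groups[[attribute]]
  if (is.null(grp)) return(list())
  kb$groups[[grp]] %||% list()
}

kb_operator_params <- function(kb, attribute, entry) {
  params <- entry$params %||% list()
  rng <- kb$reference_ranges[[attribute]]
  if (!is.null(rng)) {
    params$low <- params$low %||% rng$low
    params$high <- params$high %||% rng$high
  }
  params
}

#' One temporal aggregate feature definition
#'
#' @param attribute attribute id (character).
#' @param period_days lookback window length; the window is
#'   `(index_date - period, index_date]`.
#' @param operator operator id from [operator_catalog()].
#' @param params extra operator parameters.
#' @return an `aggregation_spec` list.
#' @export
aggregation_spec <- function(attribute, period_days, operator, params = list()) {
  if (operator %in% UNIMPLEMENTED_OPERATORS) {
    stop("operator '", operator, "' is not implemented")
  }
  structure(list(attribute = attribute, period_days = period_days,
                 operator = operator, params = params),
            class = "aggregation_spec")
}

spec_feature_name <- function(spec) {
  paste0(spec$attribute, ".", spec$operator, ".", spec$period_days, "d")
}

# Group the relevant EAV rows by patient once; returns an environment-free
# nested list patient -> attribute -> list(times, values), times sorted.
index_events <- function(eav, attributes) {
  sub <- eav[eav$attribute %in% attributes, , drop = FALSE]
  if (nrow(sub) == 0) return(list())
  ord <- order(sub$patient_id, sub$attribute, as.numeric(sub$timestamp))
  sub <- sub[ord, , drop = FALSE]
  out <- list()
  key_split <- split(seq_len(nrow(sub)), sub$patient_id)
  for (pid in names(key_split)) {
    rows <- key_split[[pid]]
    by_attr <- split(rows, sub$attribute[rows])
    out[[pid]] <- lapply(by_attr, function(r) {
      list(times = as.numeric(sub$timestamp[r]), values = sub$value[r])
    })
  }
  out
}

#' Pivot an EAV table into a wide table of temporal aggregate features
#'
#' One output row per (patient, index date) instance; one column per spec.
#' EAV rows for attributes not named in any spec are filtered out before
#' grouping. Patients missing from the EAV table get the empty-window value
#' of each operator. The computation partitions patients over `workers`
#' logical work queues and merges in canonical order, so the result is
#' identical for any worker count.
#'
#' @param eav an `eav_table`.
#' @param specs list of [aggregation_spec()]s.
#' @param instances data.frame with columns `patient_id`, `index_date`
#'   (`POSIXct`), optionally `instance_id`.
#' @param workers positive integer (work-queue partitioning contract).
#' @return data.frame: `instance_id`, `patient_id`, `index_date`, one
#'   numeric column per spec (named `attr.operator.<period>d`).
#' @export
pivot_aggregate <- function(eav, specs, instances, workers = 1L) {
  stopifnot(workers >= 1L)
  if (is.null(instances$instance_id)) {
    instances$instance_id <- paste0(instances$patient_id, "@",
                                    format(instances$index_date, "%Y-%m-%d"))
  }
  base <- data.frame(instance_id = instances$instance_id,
                     patient_id = instances$patient_id,
                     index_date = instances$index_date,
                     stringsAsFactors = FALSE)
  if (length(specs) == 0) return(base)
  attrs <- unique(vapply(specs, `[[`, character(1), "attribute"))
  events <- index_events(eav, attrs)
  n <- nrow(instances)
  # partition rows over work queues, compute per queue, merge canonically
  queue_of <- (seq_len(n) - 1L) %% workers + 1L
  cols <- matrix(NA_real_, nrow = n, ncol = length(specs))
  for (w in seq_len(workers)) {
    for (i in which(queue_of == w)) {
      pid <- instances$patient_id[i]
      idx_t <- as.numeric(instances$index_date[i])
      pat_events <- events[[pid]]
      for (j in seq_along(specs)) {
        sp <- specs[[j]]
        ev <- pat_events[[sp$attribute]]
        window <- c(idx_t - sp$period_days * DAY_SECONDS, idx_t)
        cols[i, j] <- as.numeric(apply_operator(
          sp$operator,
          ev$times %||% numeric(), ev$values %||% character(),
          window, sp$params))
      }
    }
  }
  colnames(cols) <- vapply(specs, spec_feature_name, character(1))
  cbind(base, as.data.frame(cols))
}

#' Information gain of a feature about a categorical target
#'
#' `IG = H(target) - H(target | feature)` in bits. Numeric features are
#' discretized into `bins` equal-frequency bins; missing values form their
#' own bin.
#'
#' @param feature numeric or categorical vector.
#' @param target factor.
#' @param bins number of equal-frequency bins for numeric features.
#' @return information gain in bits (>= 0 up to floating error).
#' @export
information_gain <- function(feature, target, bins = 10L) {
  stopifnot(is.factor(target), length(feature) == length(target))
  f <- discretize_feature(feature, bins)
  h_y <- entropy_bits(table(target))
  tab <- table(f, target)
  n <- sum(tab)
  h_cond <- 0
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    h_cond <- h_cond + sum(row) / n * entropy_bits(row)
  }
  max(h_y - h_cond, 0)
}

discretize_feature <- function(feature, bins = 10L) {
  if (is.numeric(feature)) {
    finite <- feature[!is.na(feature)]
    if (length(unique(finite)) <= bins) {
      f <- factor(feature, exclude = NULL)
    } else {
      brk <- unique(quantile(finite, probs = seq(0, 1, length.out = bins + 1)))
      f <- cut(feature, breaks = brk, include.lowest = TRUE)
      f <- addNA(f, ifany = TRUE)
    }
  } else {
    f <- addNA(factor(feature), ifany = TRUE)
  }
  f
}

#' Variance reduction of a feature about a continuous target
#'
#' Regression analogue of information gain:
#' `Var(target) - E[Var(target | feature bin)]`, with the feature
#' discretized exactly as for [information_gain()].
#'
#' @inheritParams information_gain
#' @return variance reduction (>= 0 up to floating error).
#' @export
variance_reduction <- function(feature, target, bins = 10L) {
  stopifnot(is.numeric(target))
  f <- discretize_feature(feature, bins)
  v <- function(x) if (length(x) < 2L) 0 else mean((x - mean(x))^2)
  total <- v(target)
  groups <- split(target, f)
  within <- sum(vapply(groups, function(g) length(g) * v(g), numeric(1))) / length(target)
  max(total - within, 0)
}

relevance_score <- function(feature, target) {
  if (is.factor(target)) information_gain(feature, target)
  else variance_reduction(feature, target)
}

#' Select one period-operator pair per (attribute, category)
#'
#' For each attribute present in both the EAV table and the knowledge base,
#' and each related operator category, enumerates every period x operator
#' candidate, computes each candidate feature on a seeded random sample of
#' instances (stratified when the target is categorical), scores it by
#' information gain (categorical target) or variance reduction (continuous),
#' and returns exactly the arg-max pair per category. Ties break to the
#' shorter period, then catalog order. When every candidate of a category
#' scores 0, the tie-break winner is still returned, flagged uninformative.
#'
#' @param eav an `eav_table`.
#' @param instances data.frame with `patient_id`, `index_date`, and the
#'   target column.
#' @param target name of the target column in `instances`.
#' @param kb a `knowledge_base`.
#' @param sample_size instances scored per candidate (default
#'   `min(5000, n)`).
#' @param seed integer for the scoring sample.
#' @return list with `specs` (winning [aggregation_spec()]s, one per
#'   attribute x category, each with attributes `score`, `category`,
#'   `uninformative`) and `provenance` (data.frame of every candidate and
#'   its score).
#' @export
select_spec_per_category <- function(eav, instances, target, kb,
                                     sample_size = NULL, seed = 1L) {
  kb <- validate_knowledge_base(unclass(kb))
  y_all <- instances[[target]]
  if (!is.numeric(y_all)) y_all <- factor(y_all)
  n <- nrow(instances)
  if (is.null(sample_size)) sample_size <- min(5000L, n)
  sample_size <- min(sample_size, n)
  sample_idx <- with_seed(derive_seed(seed, "agg-sample"), {
    if (is.factor(y_all) && sample_size < n) {
      # proportional allocation per class
      idx <- unlist(lapply(levels(y_all), function(lv) {
        cls_idx <- which(y_all == lv)
        take <- max(1L, round(sample_size * length(cls_idx) / n))
        sample(cls_idx, min(take, length(cls_idx)))
      }))
      sort(idx)
    } else if (sample_size < n) {
      sort(sample(seq_len(n), sample_size))
    } else seq_len(n)
  })
  inst_s <- instances[sample_idx, , drop = FALSE]
  y <- y_all[sample_idx]

  catalog <- operator_catalog()
  attrs <- intersect(unique(eav$attribute), names(kb$attribute_groups))
  winners <- list()
  prov <- list()
  for (attribute in attrs) {
    attr_type <- kb_attr_type(kb, attribute)
    for (entry in kb_entries_for(kb, attribute)) {
      ops <- catalog[catalog$category == entry$category, , drop = FALSE]
      ops <- ops[vapply(ops$id, operator_applicable, logical(1),
                        attr_type = attr_type), , drop = FALSE]
      ops <- ops[!ops$id %in% UNIMPLEMENTED_OPERATORS, , drop = FALSE]
      if (nrow(ops) == 0) next
      periods <- enumerate_periods(entry$shortest, entry$longest,
                                   entry$progression %||% "exponential",
                                   factor = entry$factor %||% 2,
                                   step_days = entry$step_days %||% 30)
      params <- kb_operator_params(kb, attribute, entry)
      cands <- list(); scores <- numeric()
      for (period in periods) {
        for (k in seq_len(nrow(ops))) {
          sp <- aggregation_spec(attribute, period, ops$id[k], params)
          feat <- pivot_aggregate(eav, list(sp), inst_s)[[spec_feature_name(sp)]]
          sc <- relevance_score(feat, y)
          cands[[length(cands) + 1L]] <- sp
          scores <- c(scores, sc)
          prov[[length(prov) + 1L]] <- data.frame(
            attribute = attribute, category = entry$category,
            operator = ops$id[k], period_days = period, score = sc,
            stringsAsFactors = FALSE)
        }
      }
      # argmax; ties -> shorter period, then catalog order
      op_order <- catalog$order[match(vapply(cands, `[[`, character(1), "operator"),
                                      catalog$id)]
      per <- vapply(cands, `[[`, numeric(1), "period_days")
      best <- order(-scores, per, op_order)[1L]
      w <- cands[[best]]
      attr(w, "score") <- scores[best]
      attr(w, "category") <- entry$category
      attr(w, "uninformative") <- all(scores <= 0)
      winners[[length(winners) + 1L]] <- w
    }
  }
  list(specs = winners, provenance = do.call(rbind, prov))
}

#' Build the modeling table: selected aggregates joined to static features
#'
#' Runs [select_spec_per_category()], computes the winning specs on all
#' instances, and joins them with the non-repeated (static) columns of
#' `instances` into one [instance_table()].
#'
#' @inheritParams select_spec_per_category
#' @param static_cols names of static columns of `instances` to carry over.
#' @param workers work-queue partitions for the final pivot.
#' @return list: `table` (an `instance_table` ready for [search()]),
#'   `specs`, `provenance`.
#' @export
aggregate_features <- function(eav, instances, target, kb, static_cols = character(),
                               sample_size = NULL, seed = 1L, workers = 1L) {
  sel <- select_spec_per_category(eav, instances, target, kb,
                                  sample_size = sample_size, seed = seed)
  wide <- pivot_aggregate(eav, sel$specs, instances, workers = workers)
  df <- wide[, setdiff(names(wide), c("instance_id", "patient_id", "index_date")),
             drop = FALSE]
  for (sc in static_cols) df[[sc]] <- instances[[sc]]
  df[[target]] <- instances[[target]]
  tbl <- instance_table(df, instance_id = wide$instance_id, target = target)
  attr(tbl, "index_date") <- instances$index_date
  list(table = tbl, specs = sel$specs, provenance = sel$provenance)
}
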