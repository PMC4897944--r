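test_that("period enumeration follows exponential and arithmetic progressions", {
  expect_equal(enumerate_periods(30, 365), c(30, 60, 120, 240, 365))
  expect_equal(enumerate_periods(30, 90, "arithmetic", step_days = 30), c(30, 60, 90))
  expect_equal(enumerate_periods(180, 180), 180)
  expect_equal(enumerate_periods(30, 240), c(30, 60, 120, 240))  # exact hit, no append
})

test_that("information gain matches the entropy-formula oracle", {
  y <- factor(rep(c("a", "b"), each = 50))
  f_same <- factor(rep(c(0, 1), each = 50))
  expect_equal(information_gain(f_same, y), 1.0)
  expect_equal(information_gain(factor(rep(0, 100)), y), 0.0)
  # 2x2 counts [[45,5],[5,45]]
  f <- factor(c(rep(0, 45), rep(1, 5), rep(0, 5), rep(1, 45)))
  counts <- matrix(c(45, 5, 5, 45), 2, byrow = TRUE)
  expect_equal(information_gain(f, y), ig_from_counts(counts), tolerance = 1e-12)
  expect_equal(information_gain(f, y), 0.531, tolerance = 1e-3)
})

test_that("variance reduction is the regression analogue and is nonnegative", {
  y <- c(rnorm(50, 0), rnorm(50, 5))
  f <- factor(rep(c("lo", "hi"), each = 50))
  expect_gt(variance_reduction(f, y), 0)
  expect_equal(variance_reduction(factor(rep("x", 100)), y), 0)
})

test_that("EAV pivot computes per-patient in-window means for two lab tests", {
  origin <- as.POSIXct("2021-01-01", tz = "UTC")
  eav <- eav_table(
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P2"),
    timestamp = origin + c(5, 10, 15, 5, 10, 200) * 86400,
    attribute = c("test 1", "test 1", "test 2", "test 1", "test 2", "test 2"),
    value = c("2", "4", "10", "6", "20", "99"))
  inst <- data.frame(patient_id = c("P1", "P2"),
                     index_date = origin + 30 * 86400)
  specs <- list(aggregation_spec("test 1", 30, "mean"),
                aggregation_spec("test 2", 30, "mean"))
  wide <- pivot_aggregate(eav, specs, inst)
  expect_equal(nrow(wide), 2L)
  expect_equal(wide[["test 1.mean.30d"]], c(3, 6))
  expect_equal(wide[["test 2.mean.30d"]], c(10, 20))  # P2's day-200 value is out of window
  # no specs -> ids only
  empty <- pivot_aggregate(eav, list(), inst)
  expect_equal(names(empty), c("instance_id", "patient_id", "index_date"))
  # patient absent from the EAV table takes the empty-window policy value
  inst3 <- rbind(inst, data.frame(patient_id = "P9", index_date = inst$index_date[1]))
  wide3 <- pivot_aggregate(eav, specs, inst3)
  expect_true(is.na(wide3[["test 1.mean.30d"]][3]))
})

test_that("multiple index dates per patient anchor separate windows", {
  origin <- as.POSIXct("2021-01-01", tz = "UTC")
  eav <- eav_table(patient_id = rep("P1", 4),
                   timestamp = origin + c(10, 50, 100, 140) * 86400,
                   attribute = "ed", value = "1")
  inst <- data.frame(patient_id = c("P1", "P1"),
                     index_date = origin + c(60, 150) * 86400,
                     instance_id = c("P1#1", "P1#2"))
  wide <- pivot_aggregate(eav, list(aggregation_spec("ed", 60, "count")), inst)
  # brute force: window (0,60] holds days 10,50; window (90,150] holds 100,140
  expect_equal(wide[["ed.count.60d"]], c(2, 2))
  wide30 <- pivot_aggregate(eav, list(aggregation_spec("ed", 30, "count")), inst)
  expect_equal(wide30[["ed.count.30d"]], c(1, 1))
})

test_that("pivot is identical across work-queue widths", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 60, seed = 21))
  specs <- list(aggregation_spec("ed_visit", 90, "count"),
                aggregation_spec("weight", 60, "mean"))
  w1 <- pivot_aggregate(coh$eav, specs, coh$instances, workers = 1L)
  w2 <- pivot_aggregate(coh$eav, specs, coh$instances, workers = 2L)
  w4 <- pivot_aggregate(coh$eav, specs, coh$instances, workers = 4L)
  expect_identical(w1, w2)
  expect_identical(w1, w4)
})

test_that("selection returns exactly one winning pair per (attribute, category)", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 250, noise = 0, seed = 13))
  sel <- select_spec_per_category(coh$eav, coh$instances, "outcome", toy_kb(),
                                  seed = 5)
  keys <- vapply(sel$specs, function(s) paste(s$attribute, attr(s, "category")),
                 character(1))
  expect_equal(sort(keys), c("ed_visit count", "weight value_summary"))
  # provenance lists every candidate: count over periods {30,60,120,240,360},
  # and min/max/mean over periods {30,60,90,120}
  expect_equal(nrow(sel$provenance), 5 + 12)
})

test_that("noiseless planted signal wins its category with maximal score", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 400, noise = 0, seed = 17))
  sel <- select_spec_per_category(coh$eav, coh$instances, "outcome", toy_kb(),
                                  seed = 5)
  win <- sel$specs[[which(vapply(sel$specs, `[[`, character(1), "attribute") == "ed_visit")]]
  expect_equal(win$operator, "count")
  expect_gte(win$period_days, 90)
  # exhaustive oracle: the winner's score equals the max over all candidates
  prov <- sel$provenance
  cand <- prov[prov$attribute == "ed_visit", ]
  expect_equal(attr(win, "score"), max(cand$score), tolerance = 1e-12)
  expect_false(attr(win, "uninformative"))
})

test_that("degenerate selection cases: single pair, uninformative flag", {
  coh <- generate_eav_cohort(small_cohort_spec(n = 80, noise = 0, seed = 19))
  kb1 <- validate_knowledge_base(list(
    attribute_types = list(ed_visit = "event"),
    attribute_groups = list(ed_visit = "g"),
    groups = list(g = list(list(category = "presence", shortest = 90,
                                longest = 90)))))
  sel <- select_spec_per_category(coh$eav, coh$instances, "outcome", kb1)
  expect_length(sel$specs, 1L)
  expect_equal(sel$specs[[1]]$operator, "presence")
  expect_equal(sel$specs[[1]]$period_days, 90)
  # scramble the target: every candidate scores ~0 but a winner still returns
  inst <- coh$instances
  inst$outcome <- factor(rep(c(0, 1), length.out = nrow(inst)))
  sel0 <- select_spec_per_category(coh$eav, inst, "outcome", toy_kb())
  expect_length(sel0$specs, 2L)
})

test_that("knowledge base round-trips through YAML and rejects unknown categories", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(toy_kb()), path)
  kb <- read_knowledge_base(path)
  expect_s3_class(kb, "knowledge_base")
  bad <- unclass(toy_kb())
  bad$groups$utilization[[1]]$category <- "no_such_category"
  expect_error(validate_knowledge_base(bad), "unknown operator category")
})
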