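# Readers, windowed featurization, filtering, scaling and grouped splits.

test_that("read_events parses fixtures and enforces the schema", {
  f <- write_tiny_files()
  ev <- read_events(f$events)
  expect_equal(nrow(ev), 3L)
  expect_s3_class(ev$event_date, "Date")
  expect_equal(ev$concept_id, c("C1", "C2", "C1"))

  empty <- file.path(f$dir, "empty.csv")
  writeLines("person_id,concept_id,event_date,domain", empty)
  expect_equal(nrow(read_events(empty)), 0L)

  bad <- file.path(f$dir, "bad.csv")
  writeLines(c("person_id,concept_id,event_date,domain",
               "p1,C1,2020-13-40,condition"), bad)
  expect_error(read_events(bad), "row")

  miss <- file.path(f$dir, "miss.csv")
  writeLines(c("person_id,concept_id,domain", "p1,C1,condition"), miss)
  expect_error(read_events(miss), "event_date")
})

test_that("read_cohort validates outcomes and duplicates", {
  f <- write_tiny_files()
  co <- read_cohort(f$cohort)
  expect_equal(attr(co, "prevalence"), 2 / 3)

  bad <- file.path(f$dir, "bad_cohort.csv")
  writeLines(c("person_id,index_date,outcome,age_years,sex",
               "p1,2021-06-30,2,70,female"), bad)
  expect_error(read_cohort(bad), "binary")

  dup <- file.path(f$dir, "dup_cohort.csv")
  writeLines(c("person_id,index_date,outcome,age_years,sex",
               "p1,2021-06-30,1,70,female",
               "p1,2021-06-30,0,70,female"), dup)
  expect_error(read_cohort(dup), "duplicate")
  expect_equal(nrow(read_cohort(dup, allow_duplicates = TRUE)), 2L)
})

test_that("binarize_windows places events in nested windows", {
  f <- write_tiny_files()
  ev <- read_events(f$events)
  co <- read_cohort(f$cohort)
  fm <- binarize_windows(ev, co)
  m <- fm$matrix
  # p1: C1 occurred 40 days before index
  expect_equal(m["p1@2021-06-30", "C1_365"], 1)
  expect_equal(m["p1@2021-06-30", "C1_180"], 1)
  expect_equal(m["p1@2021-06-30", "C1_30"], 0)
  # p1: C2 on the index date counts in every window (inclusive endpoint)
  expect_equal(unname(m["p1@2021-06-30", c("C2_365", "C2_180", "C2_30")]),
               c(1, 1, 1))
  # p2: event 396 days before index is outside every window
  expect_equal(sum(m["p2@2021-06-01", fm$feature_map$window != "static"]), 0)
  # statics populated even without events
  expect_equal(m["p3@2021-06-01", "age_static"], 80)
  # index-date exclusion flag drops the C2 event
  fm2 <- binarize_windows(ev, co, include_index_date = FALSE)
  expect_equal(sum(fm2$matrix["p1@2021-06-30", grep("^C2", colnames(fm2$matrix))]), 0)
  expect_error(binarize_windows(ev, co, windows = c(365, 365)), "distinct")
})

test_that("window nesting holds on simulated data", {
  sim <- small_sim(150)
  fm <- binarize_windows(sim$events, sim$cohort)
  fmap <- fm$feature_map
  for (cid in unique(fmap$concept_id[fmap$window != "static"])) {
    w365 <- fm$matrix[, paste0(cid, "_365")]
    w180 <- fm$matrix[, paste0(cid, "_180")]
    w30 <- fm$matrix[, paste0(cid, "_30")]
    expect_true(all(w30 <= w180))
    expect_true(all(w180 <= w365))
  }
})

test_that("density is exact and filtering is a monotone threshold", {
  sim <- small_sim(200)
  fm <- binarize_windows(sim$events, sim$cohort)
  m <- fm$matrix
  expect_equal(matrix_density(fm), sum(m != 0) / prod(dim(m)))

  # a feature present in exactly the cutoff fraction is kept
  n <- nrow(m)
  prev <- Matrix::colSums(m != 0) / n
  cut <- sort(unique(prev[prev > 0]))[2]
  kept <- suppressMessages(filter_rare_features(fm, cut))
  expect_true(all(Matrix::colSums(kept$matrix != 0) / n >= cut))
  expect_true(any(abs(Matrix::colSums(kept$matrix != 0) / n - cut) < 1e-12))

  # identity at zero, monotone column counts along rising cutoffs
  expect_equal(ncol(filter_rare_features(fm, 0)$matrix), ncol(m))
  cuts <- c(0, 0.001, 0.01, 0.05, 0.2, 0.5)
  ncols <- vapply(cuts, function(cc)
    ncol(suppressMessages(filter_rare_features(fm, cc))$matrix), numeric(1))
  expect_true(all(diff(ncols) <= 0))
  expect_error(filter_rare_features(fm, 1.5), "min_prevalence")
})

test_that("max-abs scaling uses training rows only", {
  sim <- small_sim(50)
  fm <- binarize_windows(sim$events, sim$cohort)
  ages <- fm$matrix[, "age_static"]
  train <- which(ages < max(ages))  # leave the max age out of training
  fms <- scale_numeric(fm, train)
  expect_equal(max(fms$matrix[train, "age_static"]), 1)
  expect_gt(max(fms$matrix[, "age_static"]), 1)  # held-out can exceed 1
  expect_true(all(fms$matrix[, "sex_male_static"] %in% c(0, 1)))
  # scaler reuse reproduces the transformation
  fm2 <- apply_scaler(binarize_windows(sim$events, sim$cohort),
                      attr(fms, "scaler"))
  expect_equal(fm2$matrix[, "age_static"], fms$matrix[, "age_static"])
})

test_that("build_sequences groups visits by date, dedups, truncates, and matches the 365-window matrix", {
  f <- write_tiny_files()
  ev <- read_events(f$events)
  co <- read_cohort(f$cohort)
  sq <- build_sequences(ev, co)
  s1 <- sq$sequences[["p1@2021-06-30"]]
  expect_equal(s1$days_before_index, c(40L, 0L))
  expect_equal(length(sq$sequences[["p2@2021-06-01"]]$days_before_index), 0L)

  # duplicate same-day same-concept events collapse
  dup_ev <- rbind(ev, ev[1, ])
  sq2 <- build_sequences(dup_ev, co)
  expect_equal(sq2$sequences[["p1@2021-06-30"]]$concept_indices[[1]],
               s1$concept_indices[[1]])

  expect_error(build_sequences(ev, co, obs_window_days = -1), "non-negative")

  # truncation drops the oldest visits
  sim <- small_sim(60)
  sq_cap <- build_sequences(sim$events, sim$cohort, max_visits = 2)
  nv <- vapply(sq_cap$sequences, function(s) length(s$days_before_index), integer(1))
  expect_true(all(nv <= 2))
  sq_full <- build_sequences(sim$events, sim$cohort)
  long <- names(which(vapply(sq_full$sequences,
                             function(s) length(s$days_before_index), integer(1)) > 2))[1]
  expect_equal(sq_cap$sequences[[long]]$days_before_index,
               utils::tail(sq_full$sequences[[long]]$days_before_index, 2))

  # flattened sequences equal the 365-day window matrix at concept level
  fm365 <- binarize_windows(sim$events, sim$cohort, windows = 365)
  for (oid in names(sq_full$sequences)) {
    idx <- sort(unique(unlist(sq_full$sequences[[oid]]$concept_indices)))
    concepts_seq <- sort(sq_full$concept_map$concept_id[idx])
    row <- fm365$matrix[oid, ]
    on <- names(row)[row != 0]
    concepts_mat <- sort(sub("_365$", "", on[grepl("_365$", on)]))
    expect_equal(concepts_seq, concepts_mat)
  }
})

test_that("split_data never splits a person and hits fold fractions", {
  sim <- small_sim(600)
  # persons never span folds, across many seeds
  co <- sim$cohort
  for (s in 1:25) {
    sp <- split_data(co, seed = s)
    folds <- tapply(sp$assignment, co$person_id[match(names(sp$assignment),
                                                      co$observation_id)],
                    function(f) length(unique(f)))
    expect_true(all(folds == 1))
  }
  sp1 <- split_data(co, seed = 11)
  sp2 <- split_data(co, seed = 11)
  expect_identical(sp1$assignment, sp2$assignment)

  tab <- table(sp1$assignment) / length(sp1$assignment)
  expect_lt(abs(tab[["test"]] - 0.25), 0.03)
  expect_lt(abs(tab[["validation"]] - 0.75 * 0.33), 0.03)

  # 4 persons at test_frac 0.25: exactly one person lands in test
  tiny <- data.table::data.table(person_id = c("a", "b", "c", "d"),
                                 index_date = as.Date("2021-01-01"),
                                 outcome = c(0L, 1L, 0L, 1L),
                                 age_years = 50, sex = "female",
                                 observation_id = c("a1", "b1", "c1", "d1"))
  for (s in 1:20)
    expect_equal(sum(split_data(tiny, seed = s)$assignment == "test"), 1L)

  expect_error(split_data(co, test_frac = 0), "fractions")
})

test_that("feature matrices and sequences round-trip through disk formats", {
  sim <- small_sim(40)
  fm <- binarize_windows(sim$events, sim$cohort)
  dir <- withr::local_tempdir()
  write_feature_matrix(fm, dir)
  fm2 <- read_feature_matrix(dir)
  expect_equal(as.matrix(fm2$matrix), as.matrix(fm$matrix),
               ignore_attr = TRUE)
  expect_equal(fm2$feature_map$concept_id, fm$feature_map$concept_id)

  sq <- build_sequences(sim$events, sim$cohort)
  path <- file.path(dir, "seq.jsonl")
  write_sequences(sq, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(sim$cohort))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("observation_id", "days_before_index", "concepts") %in%
                    names(rec)))
})
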