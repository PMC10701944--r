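## Featurization: windowed binary matrices for static models, visit sequences
## for temporal models. Both share the cohort's observation_id as row key.

#' Build a windowed binary feature matrix
#'
#' For each observation (cohort row) and each lookback window `w`, the column
#' `(concept, w)` is 1 iff the concept occurs in `[index_date - w, index_date]`
#' for that observation. Scaled-age and male-sex columns are appended as
#' static features (age unscaled here; see [scale_numeric()]).
#'
#' @param events event table from [read_events()].
#' @param cohort cohort table from [read_cohort()].
#' @param windows lookback window lengths in days, longest first by
#'   convention; must be positive and distinct.
#' @param include_index_date whether events dated exactly on the index date
#'   count as features (`TRUE`) or are dropped to guard against label
#'   leakage (`FALSE`).
#' @return a `feature_matrix` object: sparse matrix (`Matrix::dgCMatrix`) of
#'   observations x features, a feature map (`index`, `concept_id`,
#'   `window`), row ids, and the indices of numeric (non-binary) columns.
#' @export
binarize_windows <- function(events, cohort, windows = c(365L, 180L, 30L),
                             include_index_date = TRUE) {
  windows <- as.integer(windows)
  if (any(windows <= 0L) || anyDuplicated(windows))
    stop_arg("windows must be positive and distinct")
  windows <- sort(windows, decreasing = TRUE)
  ev <- data.table::as.data.table(events)
  co <- data.table::as.data.table(cohort)
  joined <- merge(ev, co[, c("person_id", "index_date", "observation_id")],
                  by = "person_id", allow.cartesian = TRUE)
  joined[, delta := as.integer(index_date - event_date)]
  lo <- if (include_index_date) 0L else 1L
  joined <- joined[delta >= lo & delta <= max(windows)]
  concepts <- sort(unique(joined$concept_id))
  n_w <- length(windows)
  fmap <- data.table::data.table(
    concept_id = rep(concepts, each = n_w),
    window = rep(as.character(windows), times = length(concepts))
  )
  fmap <- rbind(fmap,
                data.table::data.table(concept_id = c("age", "sex_male"),
                                       window = "static"))
  fmap[, index := seq_len(.N) - 1L]
  row_ids <- co$observation_id
  n <- length(row_ids)
  p <- nrow(fmap)
  ridx <- match(joined$observation_id, row_ids)
  cbase <- (match(joined$concept_id, concepts) - 1L) * n_w
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(windows)) {
    sel <- joined$delta <= windows[k]
    ii <- c(ii, ridx[sel])
    jj <- c(jj, cbase[sel] + k)
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, p),
                            use.last.ij = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m@x[] <- 1  # dedup: presence, not counts
  m[, p - 1L] <- co$age_years
  m[, p] <- as.numeric(co$sex == "male")
  dimnames(m) <- list(row_ids, paste0(fmap$concept_id, "_", fmap$window))
  new_feature_matrix(m, fmap, numeric_cols = p - 1L)
}

new_feature_matrix <- function(m, fmap, numeric_cols) {
  structure(list(matrix = m, feature_map = fmap,
                 row_ids = rownames(m), numeric_cols = numeric_cols),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d observations x %d features, density %.4f\n",
              nrow(x$matrix), ncol(x$matrix), matrix_density(x)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$matrix)

#' Nonzero density of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param concept_only restrict to concept (binary) columns, excluding the
#'   static age/sex columns.
#' @return nonzeros / (rows x cols).
#' @export
matrix_density <- function(fm, concept_only = FALSE) {
  m <- fm$matrix
  if (concept_only) {
    keep <- fm$feature_map$window != "static"
    m <- m[, keep, drop = FALSE]
  }
  length(m@x[m@x != 0]) / prod(dim(m))
}

#' Drop features rarer than a prevalence cutoff
#'
#' A column is kept iff its nonzero fraction is at least `min_prevalence`
#' (strictly rarer columns are removed). The feature map is reindexed.
#'
#' @param fm a `feature_matrix`.
#' @param min_prevalence minimum fraction of observations, in `[0, 1]`.
#' @return the filtered `feature_matrix`; attribute `removed` lists dropped
#'   column names.
#' @export
filter_rare_features <- function(fm, min_prevalence = 0.001) {
  if (!is.numeric(min_prevalence) || min_prevalence < 0 || min_prevalence > 1)
    stop_arg("min_prevalence must lie in [0, 1]")
  if (nrow(fm$matrix) == 0L) stop_arg("feature matrix has no rows")
  nz <- Matrix::colSums(fm$matrix != 0)
  keep <- (nz / nrow(fm$matrix)) >= min_prevalence
  removed <- colnames(fm$matrix)[!keep]
  if (length(removed))
    message(sprintf("filter_rare_features: removed %d/%d features below prevalence %g",
                    length(removed), length(keep), min_prevalence))
  fmap <- fm$feature_map[keep]
  fmap[, index := seq_len(.N) - 1L]
  ncols <- match(fm$numeric_cols, which(keep))
  out <- new_feature_matrix(fm$matrix[, keep, drop = FALSE], fmap,
                            numeric_cols = ncols[!is.na(ncols)])
  attr(out, "removed") <- removed
  out
}

#' Max-absolute scaling of numeric columns
#'
#' Divides each numeric column by its maximum absolute value computed on the
#' training rows only, so training values lie in `[0, 1]`; held-out rows may
#' exceed 1. Binary columns are untouched. The fitted scaler is attached for
#' reuse via [apply_scaler()].
#'
#' @param fm a `feature_matrix`.
#' @param train_rows row indices (or row ids) used to fit the scaler;
#'   defaults to all rows.
#' @return the scaled `feature_matrix` with attribute `scaler` (named vector
#'   of divisors).
#' @export
scale_numeric <- function(fm, train_rows = NULL) {
  rows <- resolve_rows(fm, train_rows)
  scaler <- numeric(0)
  for (j in fm$numeric_cols) {
    mx <- max(abs(fm$matrix[rows, j]))
    if (mx == 0) {
      warning("all-zero numeric column left unchanged: ", colnames(fm$matrix)[j])
      next
    }
    scaler[colnames(fm$matrix)[j]] <- mx
  }
  attr(fm, "scaler") <- scaler
  apply_scaler(fm, scaler)
}

#' Apply a previously fitted max-abs scaler
#' @param fm a `feature_matrix`.
#' @param scaler named divisor vector from [scale_numeric()].
#' @return the scaled `feature_matrix`.
#' @export
apply_scaler <- function(fm, scaler) {
  for (nm in names(scaler)) {
    j <- match(nm, colnames(fm$matrix))
    if (!is.na(j)) fm$matrix[, j] <- fm$matrix[, j] / scaler[[nm]]
  }
  attr(fm, "scaler") <- scaler
  fm
}

resolve_rows <- function(fm, rows) {
  if (is.null(rows)) return(seq_len(nrow(fm$matrix)))
  if (is.character(rows)) match(rows, fm$row_ids) else rows
}

#' Build per-observation visit sequences
#'
#' Groups each observation's qualifying events (within the lookback window)
#' into visits by calendar date, deduplicating concepts within a visit.
#' Visits are ordered oldest to newest; if there are more than `max_visits`,
#' the oldest are truncated.
#'
#' @param events event table from [read_events()].
#' @param cohort cohort table from [read_cohort()].
#' @param obs_window_days lookback length in days (default 365).
#' @param max_visits cap on visits per observation (default 50).
#' @param include_index_date as in [binarize_windows()].
#' @return a `visit_sequences` object: per-observation list of visits
#'   (`days_before_index`, 1-based `concept_indices`), a concept map, a
#'   static matrix (`age_years`, `sex_male`), outcome labels, and row ids.
#' @export
build_sequences <- function(events, cohort, obs_window_days = 365L,
                            max_visits = 50L, include_index_date = TRUE) {
  if (obs_window_days < 0) stop_arg("obs_window_days must be non-negative")
  ev <- data.table::as.data.table(events)
  co <- data.table::as.data.table(cohort)
  joined <- merge(ev, co[, c("person_id", "index_date", "observation_id")],
                  by = "person_id", allow.cartesian = TRUE)
  joined[, delta := as.integer(index_date - event_date)]
  lo <- if (include_index_date) 0L else 1L
  joined <- joined[delta >= lo & delta <= obs_window_days]
  concepts <- sort(unique(joined$concept_id))
  cmap <- data.table::data.table(index = seq_along(concepts) - 1L,
                                 concept_id = concepts)
  joined[, cidx := match(concept_id, concepts)]
  grouped <- unique(joined[, c("observation_id", "delta", "cidx")])
  data.table::setorder(grouped, observation_id, -delta, cidx)
  by_obs <- split(grouped, by = "observation_id", keep.by = FALSE)
  seqs <- vector("list", nrow(co))
  names(seqs) <- co$observation_id
  for (oid in names(by_obs)) {
    g <- by_obs[[oid]]
    vis <- split(g$cidx, -g$delta)  # ascending time (descending delta)
    days <- -as.integer(names(vis))
    if (length(vis) > max_visits) {  # drop oldest
      keep <- (length(vis) - max_visits + 1L):length(vis)
      vis <- vis[keep]; days <- days[keep]
    }
    seqs[[oid]] <- list(days_before_index = days,
                        concept_indices = unname(vis))
  }
  empty <- list(days_before_index = integer(0), concept_indices = list())
  for (oid in names(seqs)) if (is.null(seqs[[oid]])) seqs[[oid]] <- empty
  static <- cbind(age_years = co$age_years,
                  sex_male = as.numeric(co$sex == "male"))
  rownames(static) <- co$observation_id
  structure(list(sequences = seqs, concept_map = cmap, static = static,
                 outcome = setNames(co$outcome, co$observation_id),
                 obs_window_days = as.integer(obs_window_days),
                 max_visits = as.integer(max_visits)),
            class = "visit_sequences")
}

#' @export
print.visit_sequences <- function(x, ...) {
  nv <- vapply(x$sequences, function(s) length(s$days_before_index), integer(1))
  cat(sprintf("<visit_sequences> %d observations, %d concepts, visits/obs median %d (max %d)\n",
              length(x$sequences), nrow(x$concept_map),
              as.integer(median(nv)), max(nv, 0L)))
  invisible(x)
}

#' Grouped train/validation/test split
#'
#' Randomizes persons (never observations) to folds so that no person spans
#' folds, then assigns each observation its person's fold. Test persons are
#' drawn first (`test_frac` of persons); of the remaining training persons,
#' `val_frac_of_train` go to validation.
#'
#' @param cohort cohort table from [read_cohort()].
#' @param test_frac fraction of persons for the test fold.
#' @param val_frac_of_train fraction of the non-test persons for validation.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return a `split_spec`: named character vector `assignment` mapping
#'   observation_id to `"train"`, `"validation"` or `"test"`, plus the seed.
#' @export
split_data <- function(cohort, test_frac = 0.25, val_frac_of_train = 0.33,
                       seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1 || val_frac_of_train < 0 ||
      val_frac_of_train >= 1)
    stop_arg("split fractions must lie in (0, 1)")
  co <- data.table::as.data.table(cohort)
  persons <- unique(co$person_id)
  set.seed(seed)
  persons <- sample(persons)
  n <- length(persons)
  n_test <- max(1L, round(test_frac * n))
  test_p <- persons[seq_len(n_test)]
  rest <- persons[-seq_len(n_test)]
  n_val <- round(val_frac_of_train * length(rest))
  val_p <- if (n_val > 0) rest[seq_len(n_val)] else character(0)
  fold <- ifelse(co$person_id %in% test_p, "test",
                 ifelse(co$person_id %in% val_p, "validation", "train"))
  structure(list(assignment = setNames(fold, co$observation_id),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  tb <- table(x$assignment)
  cat("<split_spec>", paste(names(tb), as.integer(tb), sep = "=", collapse = " "),
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}

#' Observation ids in a given fold
#' @param split a `split_spec`.
#' @param fold one of `"train"`, `"validation"`, `"test"`; `"train+validation"`
#'   returns both non-test folds.
#' @return character vector of observation ids.
#' @export
fold_ids <- function(split, fold) {
  if (fold == "train+validation")
    return(names(split$assignment)[split$assignment != "test"])
  names(split$assignment)[split$assignment == fold]
}
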