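## Hyperparameter search with a tree-of-Parzen-estimators sampler: trials
## are split into a good fraction (top gamma by validation AUC) and the
## rest; candidates are drawn from a kernel density over the good trials
## and ranked by the good/bad density ratio, dimension-wise independent.
## A plain random-search backend is available as a fallback.

#' Hyperparameter range constructors
#'
#' `hp_uniform` and `hp_loguniform` are continuous ranges (the latter
#' sampled uniformly in log space), `hp_quniform` rounds to a step (integer
#' ranges), `hp_choice` is categorical over explicit values.
#'
#' @param low,high range bounds.
#' @param step rounding step for `hp_quniform`.
#' @param values candidate values for `hp_choice`.
#' @return a range descriptor used in a search space list.
#' @export
hp_uniform <- function(low, high) list(type = "uniform", low = low, high = high)

#' @rdname hp_uniform
#' @export
hp_loguniform <- function(low, high) list(type = "loguniform", low = low, high = high)

#' @rdname hp_uniform
#' @export
hp_quniform <- function(low, high, step = 1) {
  list(type = "quniform", low = low, high = high, step = step)
}

#' @rdname hp_uniform
#' @export
hp_choice <- function(values) list(type = "choice", values = values)

hp_sample <- function(hp) {
  switch(hp$type,
         uniform = runif(1, hp$low, hp$high),
         loguniform = exp(runif(1, log(hp$low), log(hp$high))),
         quniform = round(runif(1, hp$low, hp$high) / hp$step) * hp$step,
         choice = hp$values[[sample.int(length(hp$values), 1L)]])
}

## log-density of a 1-d Gaussian mixture over observed points, with a
## uniform prior component for robustness
parzen_logdens <- function(x, obs, lo, hi) {
  if (!length(obs)) return(log(1 / (hi - lo)))
  bw <- max(1.06 * sd(obs) * length(obs)^(-1 / 5), (hi - lo) / 50, 1e-12)
  dens <- rowMeans(outer(x, obs, function(a, b) stats::dnorm(a, b, bw)))
  log(0.9 * dens + 0.1 / (hi - lo))
}

tpe_propose <- function(space, trials_x, values, gamma, n_candidates) {
  n <- length(values)
  n_good <- max(1L, ceiling(gamma * n))
  good_idx <- order(-values)[seq_len(n_good)]
  cand <- vector("list", n_candidates)
  score <- numeric(n_candidates)
  for (ci in seq_len(n_candidates)) {
    cfg <- list(); s <- 0
    for (nm in names(space)) {
      hp <- space[[nm]]
      obs <- trials_x[[nm]]
      if (hp$type == "choice") {
        vals <- hp$values
        key <- vapply(vals, format, character(1))
        cg <- table(factor(vapply(obs[good_idx], format, character(1)), levels = key))
        cb <- table(factor(vapply(obs[-good_idx], format, character(1)), levels = key))
        pg <- (as.numeric(cg) + 1) / sum(as.numeric(cg) + 1)
        pb <- (as.numeric(cb) + 1) / sum(as.numeric(cb) + 1)
        k <- sample.int(length(vals), 1L, prob = pg)
        cfg[[nm]] <- vals[[k]]
        s <- s + log(pg[k]) - log(pb[k])
      } else {
        tf <- if (hp$type == "loguniform") log else identity
        itf <- if (hp$type == "loguniform") exp else identity
        lo <- tf(hp$low); hi <- tf(hp$high)
        og <- tf(as.numeric(obs[good_idx]))
        ob <- tf(as.numeric(obs[-good_idx]))
        # draw from the good mixture: pick a center, jitter by its bandwidth
        bw <- max(1.06 * sd(og) * length(og)^(-1 / 5), (hi - lo) / 50, 1e-12)
        x <- og[sample.int(length(og), 1L)] + rnorm(1, 0, bw)
        x <- min(max(x, lo), hi)
        s <- s + parzen_logdens(x, og, lo, hi) - parzen_logdens(x, ob, lo, hi)
        x <- itf(x)
        if (hp$type == "quniform") x <- round(x / hp$step) * hp$step
        cfg[[nm]] <- x
      }
    }
    cand[[ci]] <- cfg; score[ci] <- s
  }
  cand[[which.max(score)]]
}

#' Hyperparameter search over a space
#'
#' Maximizes `objective(config)` (validation AUC by convention) over the
#' space with a tree-of-Parzen-estimators sampler (default) or plain random
#' search. Trials whose objective raises an error are logged as failed and
#' the search continues. Deterministic under the seed.
#'
#' @param space named list of ranges from [hp_uniform()] and friends.
#' @param objective function taking a named config list, returning a scalar
#'   to maximize.
#' @param n_iter trial budget.
#' @param seed integer seed.
#' @param backend `"tpe"` or `"random"`.
#' @param gamma good-trial fraction for the TPE split.
#' @param n_candidates candidates scored per TPE iteration.
#' @param n_startup random trials before the TPE model kicks in.
#' @return list with `best` (config), `best_value`, and `trials` (a
#'   `trial_log` data.frame with one row per trial and a `validation_auc`
#'   column).
#' @export
tpe_search <- function(space, objective, n_iter = 20L, seed = 1L,
                       backend = c("tpe", "random"), gamma = 0.25,
                       n_candidates = 24L, n_startup = NULL) {
  backend <- match.arg(backend)
  n_startup <- n_startup %||% max(5L, n_iter %/% 4L)
  set.seed(seed)
  trials_x <- lapply(space, function(...) list())
  values <- numeric(0)
  status <- character(0)
  configs <- list()
  for (it in seq_len(n_iter)) {
    ok <- which(status == "ok")
    cfg <- if (backend == "random" || it <= n_startup || length(ok) < 5L) {
      lapply(space, hp_sample)
    } else {
      tpe_propose(space, lapply(trials_x, function(v) v[ok]), values[ok],
                  gamma, n_candidates)
    }
    val <- tryCatch(objective(cfg), error = function(e) {
      warning("trial ", it, " failed: ", conditionMessage(e))
      NA_real_
    })
    configs[[it]] <- cfg
    for (nm in names(space)) trials_x[[nm]] <- c(trials_x[[nm]], cfg[[nm]])
    values <- c(values, ifelse(is.na(val), -Inf, val))
    status <- c(status, ifelse(is.na(val), "failed", "ok"))
  }
  if (!any(status == "ok")) stop_arg("all trials failed")
  best_i <- which.max(values)
  log_df <- data.frame(trial = seq_len(n_iter))
  for (nm in names(space)) {
    col <- trials_x[[nm]]
    log_df[[nm]] <- if (all(vapply(col, is.numeric, logical(1))))
      unlist(col) else vapply(col, format, character(1))
  }
  log_df$validation_auc <- ifelse(is.finite(values), values, NA_real_)
  log_df$status <- status
  class(log_df) <- c("trial_log", "data.frame")
  list(best = configs[[best_i]], best_value = values[best_i], trials = log_df)
}

#' Write a trial log as JSON-lines
#' @param trials a `trial_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(trials)))
    writeLines(jsonlite::toJSON(as.list(trials[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
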