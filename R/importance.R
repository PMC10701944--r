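## Hyperparameter-importance analysis: a random-forest surrogate of the
## validation AUC over the trial log, explained with exact Shapley values.

#' Hyperparameter importance from a search trial log
#'
#' Fits a random-forest regression of validation AUC on the hyperparameter
#' combinations and computes per-trial additive (Shapley) attributions by
#' exhaustive coalition enumeration against a background sample, so the
#' attributions plus the base value reproduce the surrogate's prediction
#' exactly. The summary ranks hyperparameters by mean absolute attribution.
#'
#' @param trials a data.frame with one hyperparameter per column plus a
#'   `validation_auc` column (a `trial_log` from [tpe_search()] works).
#' @param n_background background rows used for the interventional
#'   expectation (subsampled from the trials).
#' @param n_trees random-forest size.
#' @param seed seed for forest fitting and background subsampling.
#' @return a `hyperparam_importance`: `summary` (ranked mean |attribution|),
#'   `attributions` (trials x hyperparameters), `base_value`, and `beeswarm`
#'   (long table of trial, hyperparameter, value, attribution for plotting).
#' @export
hyperparam_importance <- function(trials, n_background = 64L, n_trees = 500L,
                                  seed = 1L) {
  trials <- as.data.frame(trials)
  if (!"validation_auc" %in% names(trials))
    stop_arg("trials must contain a validation_auc column")
  if (nrow(trials) < 10L)
    stop_arg("need at least 10 trials for importance analysis (got ",
             nrow(trials), ")")
  y <- trials$validation_auc
  x <- trials[setdiff(names(trials), c("validation_auc", "trial", "status"))]
  x[] <- lapply(x, function(col) if (is.character(col)) factor(col) else col)
  m <- ncol(x)
  if (m > 12L) stop_arg("exhaustive Shapley supports at most 12 hyperparameters")
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees)
  bg <- x[sample.int(nrow(x), min(n_background, nrow(x))), , drop = FALSE]
  nb <- nrow(bg); nt <- nrow(x)

  # v[i, S] = mean over background of rf prediction with features in S taken
  # from trial i and the rest from the background row
  n_sub <- 2L^m
  vmat <- matrix(0, nt, n_sub)
  for (s in 0:(n_sub - 1L)) {
    in_s <- as.logical(bitwAnd(s, bitwShiftL(1L, 0:(m - 1L))))
    synth <- bg[rep(seq_len(nb), nt), , drop = FALSE]
    for (j in which(in_s))
      synth[[j]] <- rep(x[[j]], each = nb)
    pred <- predict(rf, synth)
    vmat[, s + 1L] <- colMeans(matrix(pred, nb, nt))
  }
  fact <- factorial(0:m)
  phi <- matrix(0, nt, m, dimnames = list(NULL, colnames(x)))
  for (j in seq_len(m)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (s in 0:(n_sub - 1L)) {
      if (bitwAnd(s, bit_j) != 0L) next
      size <- sum(as.logical(bitwAnd(s, bitwShiftL(1L, 0:(m - 1L)))))
      w <- fact[size + 1L] * fact[m - size] / fact[m + 1L]
      phi[, j] <- phi[, j] + w * (vmat[, s + bit_j + 1L] - vmat[, s + 1L])
    }
  }
  base_value <- vmat[1L, 1L]
  summ <- data.frame(hyperparameter = colnames(x),
                     mean_abs_attribution = colMeans(abs(phi)))
  summ <- summ[order(-summ$mean_abs_attribution), ]
  rownames(summ) <- NULL
  bees <- do.call(rbind, lapply(seq_len(m), function(j) {
    data.frame(trial = seq_len(nt), hyperparameter = colnames(x)[j],
               value = as.numeric(as.numeric(x[[j]])),
               attribution = phi[, j])
  }))
  structure(list(summary = summ, attributions = phi, base_value = base_value,
                 beeswarm = bees, surrogate = rf),
            class = "hyperparam_importance")
}

#' @export
print.hyperparam_importance <- function(x, ...) {
  cat("<hyperparam_importance> ranked by mean |attribution|:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
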