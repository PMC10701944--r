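## Static baselines on the windowed feature matrix: L1 logistic regression
## (glmnet over a geometric regularization path with stratified CV) and
## gradient-boosted trees (xgboost, exhaustive grid search).

stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in c(0, 1)) {
    idx <- sample(which(labels == cls))
    if (length(idx) < n_folds)
      stop_arg("need at least one case and one control per fold")
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' L1-regularized logistic regression with cross-validated strength
#'
#' Selects the regularization strength by cross-validated log loss over a
#' 20-point geometric lambda path with stratified folds, then refits on all
#' training rows at the selected strength.
#'
#' @param fm_train training `feature_matrix` (or a plain sparse matrix).
#' @param labels binary outcomes for the training rows.
#' @param n_folds CV folds (default 3).
#' @param n_lambda path length.
#' @param lambda fixed regularization strength; skips the CV selection.
#' @param seed fold-assignment seed; the fit is deterministic given it.
#' @return a `lasso_model`: glmnet fit, selected `lambda`, `coefficients`
#'   aligned to the feature map, `intercept`, and the CV table.
#' @export
fit_lasso <- function(fm_train, labels, n_folds = 3L, n_lambda = 20L,
                      lambda = NULL, seed = 1L) {
  x <- if (inherits(fm_train, "feature_matrix")) fm_train$matrix else fm_train
  if (length(unique(labels)) < 2L) stop_arg("labels contain a single class")
  lambda_max <- max(abs(Matrix::crossprod(x, labels - mean(labels)))) / length(labels)
  path <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = n_lambda))
  cv_tab <- NULL
  if (is.null(lambda)) {
    foldid <- stratified_folds(labels, n_folds, seed)
    cv <- glmnet::cv.glmnet(x, labels, family = "binomial", alpha = 1,
                            lambda = path, foldid = foldid,
                            type.measure = "deviance", standardize = FALSE)
    lambda <- cv$lambda.min
    cv_tab <- data.frame(lambda = cv$lambda, cvm = cv$cvm)
  } else {
    path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  }
  fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE)
  co <- coef(fit, s = lambda, exact = TRUE, x = x, y = labels)
  structure(list(fit = fit, lambda = lambda,
                 coefficients = setNames(as.numeric(co)[-1], colnames(x)),
                 intercept = as.numeric(co)[1],
                 cv = cv_tab,
                 feature_map = if (inherits(fm_train, "feature_matrix"))
                   fm_train$feature_map else NULL),
            class = "lasso_model")
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("<lasso_model> lambda = %.3g, %d/%d nonzero coefficients\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' @export
coef.lasso_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.lasso_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_matrix")) newdata$matrix else newdata
  eta <- as.numeric(x %*% object$coefficients) + object$intercept
  if (type == "link") eta else sigmoid(eta)
}

#' Gradient-boosted trees with exhaustive grid search
#'
#' Selects the grid point with the best cross-validated log loss and refits
#' on the full training rows at the selected setting (including the CV-best
#' boosting round count).
#'
#' @inheritParams fit_lasso
#' @param search_grid data.frame of hyperparameter combinations; columns may
#'   include `eta`, `max_depth`, `nrounds`, `subsample`,
#'   `colsample_bytree`, `min_child_weight`.
#' @return a `gbt_model` wrapping the fitted booster and the grid log.
#' @export
fit_gbt <- function(fm_train, labels, search_grid = NULL, n_folds = 3L, seed = 1L) {
  x <- if (inherits(fm_train, "feature_matrix")) fm_train$matrix else fm_train
  if (is.null(search_grid))
    search_grid <- expand.grid(eta = c(0.1, 0.3), max_depth = c(3L, 6L),
                               nrounds = 100L)
  if (!is.data.frame(search_grid) || nrow(search_grid) == 0L)
    stop_arg("search_grid must be a non-empty data.frame")
  foldid <- stratified_folds(labels, n_folds, seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = labels)
  folds <- split(seq_along(labels), foldid)
  results <- vector("list", nrow(search_grid))
  for (g in seq_len(nrow(search_grid))) {
    row <- search_grid[g, , drop = FALSE]
    params <- list(objective = "binary:logistic", eval_metric = "logloss",
                   eta = row$eta %||% 0.3,
                   max_depth = row$max_depth %||% 6L,
                   subsample = row$subsample %||% 1,
                   colsample_bytree = row$colsample_bytree %||% 1,
                   min_child_weight = row$min_child_weight %||% 1,
                   nthread = 1L)
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = params, data = dtrain, folds = folds,
                          nrounds = row$nrounds %||% 100L,
                          early_stopping_rounds = 10L, verbose = 0)
    el <- cv$evaluation_log
    best_it <- cv$best_iteration %||% which.min(el$test_logloss_mean)
    results[[g]] <- list(params = params,
                         best_nrounds = best_it,
                         logloss = el$test_logloss_mean[best_it])
  }
  losses <- vapply(results, `[[`, numeric(1), "logloss")
  best <- results[[which.min(losses)]]
  set.seed(seed)
  booster <- xgboost::xgb.train(params = best$params, data = dtrain,
                                nrounds = best$best_nrounds, verbose = 0)
  structure(list(booster = booster, best_params = best$params,
                 best_nrounds = best$best_nrounds,
                 grid = cbind(search_grid, cv_logloss = losses)),
            class = "gbt_model")
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("<gbt_model> eta = %g, max_depth = %d, %d rounds (grid of %d)\n",
              x$best_params$eta, x$best_params$max_depth, x$best_nrounds,
              nrow(x$grid)))
  invisible(x)
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$matrix else newdata
  predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Select the strongest features by absolute LASSO coefficient
#'
#' @param model a `lasso_model`.
#' @param k number of features to keep; ties broken by lower feature index.
#'   If fewer than `k` coefficients are nonzero, all nonzero features are
#'   returned with a warning.
#' @return integer column indices (sorted), with feature names.
#' @export
select_top_features <- function(model, k) {
  co <- model$coefficients
  nz <- which(co != 0)
  if (k > length(nz)) {
    warning("only ", length(nz), " nonzero coefficients; returning all of them")
    k <- length(nz)
  }
  ord <- order(-abs(co), seq_along(co))  # ties -> lower index first
  sel <- sort(ord[seq_len(k)])
  setNames(sel, names(co)[sel])
}

#' Top coefficients by absolute value
#'
#' @param model a `lasso_model`.
#' @param feature_map optional feature map to annotate concept/window.
#' @param top_n rows to report.
#' @return data.frame of (feature, coefficient) sorted by `|coefficient|`
#'   descending.
#' @export
report_coefficients <- function(model, feature_map = NULL, top_n = 10L) {
  co <- model$coefficients
  ord <- order(-abs(co), seq_along(co))
  top <- ord[seq_len(min(top_n, length(co)))]
  out <- data.frame(feature = names(co)[top], coefficient = unname(co[top]))
  fmap <- feature_map %||% model$feature_map
  if (!is.null(fmap)) {
    out$concept_id <- fmap$concept_id[top]
    out$window <- fmap$window[top]
  }
  out
}
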