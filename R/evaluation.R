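## Discrimination, recalibration, calibration curves, decision curves and
## hyperparameter importance. All functions take a score vector in [0, 1]
## and a binary label vector.

check_pred <- function(scores, labels, need_both_classes = TRUE) {
  if (length(scores) != length(labels)) stop_arg("scores and labels differ in length")
  if (!is_binary01(labels)) stop_arg("labels must be binary 0/1")
  if (need_both_classes && (all(labels == 0) || all(labels == 1)))
    stop_arg("both outcome classes must be present")
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half.
#'
#' @param scores risk scores.
#' @param labels binary outcomes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_pred(scores, labels)
  r <- rank(scores, ties.method = "average")
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_metric_ci <- function(estimate, lower, upper, level, method) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 level = level, method = method), class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.4f [%.4f, %.4f] (%g%% CI, %s)\n", x$estimate, x$lower,
              x$upper, 100 * x$level, x$method))
  invisible(x)
}

#' AUC with a DeLong-type confidence interval
#'
#' Variance of the Mann-Whitney AUC from case/control placement values
#' computed with the fast midrank algorithm (O(n log n)); normal-theory
#' interval clipped to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @param level confidence level.
#' @return a `metric_ci`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  check_pred(scores, labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n            # placements of cases
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m    # placements of controls
  auc <- mean(v10)
  v <- var(v10) / m + var(v01) / n
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(v, 0))
  new_metric_ci(auc, max(0, auc - half), min(1, auc + half), level, "DeLong")
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision estimator without interpolation: the sum over
#' descending unique score thresholds of precision times the recall
#' increment.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`; tends to the prevalence under random scores.
#' @export
auprc <- function(scores, labels) {
  check_pred(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # end of each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp); rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' AUPRC with a logit-scale confidence interval
#'
#' Normal interval on the logit of average precision with standard error
#' `1 / sqrt(n_pos * AP * (1 - AP))`, back-transformed; appropriate for the
#' skewed sampling distribution of AUPRC under class imbalance.
#'
#' @inheritParams auc_ci
#' @param n_boot if positive, use a stratified bootstrap (percentile
#'   interval) instead of the logit interval.
#' @param seed seed for the bootstrap alternative.
#' @return a `metric_ci`.
#' @export
auprc_ci <- function(scores, labels, level = 0.95, n_boot = 0L, seed = 1L) {
  check_pred(scores, labels)
  ap <- auprc(scores, labels)
  z <- qnorm(1 - (1 - level) / 2)
  if (n_boot > 0) {
    set.seed(seed)
    idx1 <- which(labels == 1); idx0 <- which(labels == 0)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
      auprc(scores[i], labels[i])
    }, numeric(1))
    qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    return(new_metric_ci(ap, qs[1], qs[2], level, "bootstrap"))
  }
  n_pos <- sum(labels)
  tau <- 1 / sqrt(n_pos * ap * (1 - ap))
  eta <- logit(clamp_prob(ap))
  new_metric_ci(ap, sigmoid(eta - z * tau), sigmoid(eta + z * tau),
                level, "logit")
}

#' Fit Platt recalibration parameters
#'
#' Maximum-likelihood slope `a` and intercept `b` of
#' `sigmoid(a * logit(p) + b)` against the outcomes of the fitting fold
#' (typically the validation set). After recalibration the mean score on the
#' fitting fold equals the event rate (logistic score equation).
#'
#' @inheritParams roc_auc
#' @return a `platt_params` list with `a` and `b`.
#' @export
platt_fit <- function(scores, labels) {
  check_pred(scores, labels)
  lp <- logit(clamp_prob(scores))
  a <- NA_real_; b <- NA_real_
  if (length(unique(lp)) > 1L && var(lp) > 1e-12) {
    fit <- glm(labels ~ lp, family = binomial())
    a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  }
  if (!is.finite(a)) {  # (near-)constant scores: slope unidentifiable
    warning("constant scores: slope unidentifiable, fitting intercept only")
    a <- 1
    b <- logit(clamp_prob(mean(labels))) - mean(lp)
  }
  structure(list(a = a, b = b), class = "platt_params")
}

#' @export
print.platt_params <- function(x, ...) {
  cat(sprintf("<platt_params> slope a = %.4f, intercept b = %.4f\n", x$a, x$b))
  invisible(x)
}

#' Apply Platt recalibration to scores
#' @param scores risk scores in `[0, 1]`.
#' @param params a `platt_params`.
#' @return recalibrated scores.
#' @export
platt_apply <- function(scores, params) {
  sigmoid(params$a * logit(clamp_prob(scores)) + params$b)
}

## Restricted cubic spline basis (linear tails), standard quantile-based
## knot normalization by (t_k - t_1)^2; first column is x itself.
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3)
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  norm2 <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  out
}

harrell_quantiles <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
         "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583, 0.8167, 0.975),
         seq(0.05, 0.95, length.out = k))
}

#' Smooth calibration curve via restricted cubic splines
#'
#' Fits a logistic model of the outcome on a restricted-cubic-spline basis
#' of `logit(score)`, with knots at standard quantiles, and evaluates the
#' observed-risk curve over the score range, with a pointwise normal band on
#' the link scale. A density summary of the predictions is attached.
#'
#' @inheritParams roc_auc
#' @param n_knots number of knots (reduced with a warning if there are too
#'   few distinct scores).
#' @param grid_size number of evaluation points across the score range.
#' @param level band level.
#' @return a `calibration_curve`: `grid` (predicted risk), `observed`
#'   (smoothed observed risk), `lower`/`upper`, `knots` (risk scale),
#'   `density` (predicted-score density) and `central90` (5th/95th score
#'   percentiles).
#' @export
smooth_calibration <- function(scores, labels, n_knots = 5L, grid_size = 101L,
                               level = 0.95) {
  check_pred(scores, labels)
  lp <- logit(clamp_prob(scores))
  n_distinct <- length(unique(lp))
  k <- n_knots
  while (k > 3 && (n_distinct < k ||
                   length(unique(quantile(lp, harrell_quantiles(k)))) < k)) {
    k <- k - 1L
  }
  if (k < n_knots) warning("too few distinct scores; reduced to ", k, " knots")
  knots <- unique(quantile(lp, harrell_quantiles(k), names = FALSE))
  if (length(knots) < 3) {  # nearly constant scores: fall back to intercept
    rate <- mean(labels)
    grid <- seq(min(scores), max(scores), length.out = grid_size)
    return(structure(list(grid = grid, observed = rep(rate, grid_size),
                          lower = rep(NA_real_, grid_size),
                          upper = rep(NA_real_, grid_size),
                          knots = sigmoid(knots),
                          density = density(scores),
                          central90 = quantile(scores, c(0.05, 0.95), names = FALSE)),
                     class = "calibration_curve"))
  }
  basis <- rcs_basis(lp, knots)
  fit <- glm(labels ~ basis, family = binomial())
  grid <- seq(quantile(scores, 0.001), quantile(scores, 0.999),
              length.out = grid_size)
  gb <- cbind(1, rcs_basis(logit(clamp_prob(grid)), knots))
  bet <- coef(fit)
  eta <- as.numeric(gb %*% bet)
  se <- sqrt(rowSums((gb %*% stats::vcov(fit)) * gb))
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(grid = grid, observed = sigmoid(eta),
                 lower = sigmoid(eta - z * se), upper = sigmoid(eta + z * se),
                 knots = sigmoid(knots), density = density(scores),
                 central90 = quantile(scores, c(0.05, 0.95), names = FALSE)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  in90 <- x$grid >= x$central90[1] & x$grid <= x$central90[2]
  dev <- max(abs(x$observed[in90] - x$grid[in90]))
  cat(sprintf("<calibration_curve> %d grid points, %d knots, max |obs - pred| = %.4f over central 90%%\n",
              length(x$grid), length(x$knots), dev))
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$grid, x$observed, type = "l", xlab = "Predicted risk",
                 ylab = "Observed risk", ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  if (!all(is.na(x$lower))) {
    graphics::lines(x$grid, x$lower, lty = 3)
    graphics::lines(x$grid, x$upper, lty = 3)
  }
  invisible(x)
}

#' Decision curve: net benefit across thresholds
#'
#' Net benefit at threshold `t` classifies `score >= t` as high risk:
#' `NB(t) = TP/N - FP/N * t/(1-t)`. Compared against treating everyone
#' (`prev - (1-prev) * t/(1-t)`) and treating no one (zero).
#'
#' @inheritParams roc_auc
#' @param thresholds decision thresholds in `(0, 1)`; values `>= 1` are
#'   dropped.
#' @return a `decision_curve` with `thresholds`, `net_benefit`, `treat_all`,
#'   `treat_none` and the prevalence.
#' @export
net_benefit <- function(scores, labels, thresholds = seq(0.001, 0.5, by = 0.001)) {
  check_pred(scores, labels, need_both_classes = FALSE)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(labels)
  prev <- mean(labels)
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]
  # at threshold t: positives are scores >= t
  cum_pos <- rev(cumsum(rev(y)))          # cases with score >= s[i]
  cum_all <- n - seq_len(n) + 1L
  nb <- vapply(thresholds, function(t) {
    i <- findInterval(t, s, left.open = TRUE) + 1L  # first index with s >= t
    tp <- if (i > n) 0 else cum_pos[i]
    fp <- (if (i > n) 0 else cum_all[i]) - tp
    tp / n - fp / n * t / (1 - t)
  }, numeric(1))
  structure(list(thresholds = thresholds, net_benefit = nb,
                 treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
                 treat_none = rep(0, length(thresholds)),
                 prevalence = prev), class = "decision_curve")
}

#' @export
print.decision_curve <- function(x, ...) {
  useful <- x$net_benefit > pmax(x$treat_all, 0)
  cat(sprintf("<decision_curve> %d thresholds, prevalence %.3f, model beats treat-all/none on %d thresholds\n",
              length(x$thresholds), x$prevalence, sum(useful)))
  invisible(x)
}

#' @export
plot.decision_curve <- function(x, ...) {
  graphics::plot(x$thresholds, x$net_benefit, type = "l",
                 xlab = "Threshold probability", ylab = "Net benefit",
                 ylim = range(c(0, x$net_benefit, x$prevalence)), ...)
  graphics::lines(x$thresholds, x$treat_all, col = "grey40", lty = 2)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}
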