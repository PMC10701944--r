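## The per-model evaluation bundle: recalibrate on validation, then measure
## discrimination, calibration and clinical utility on the test fold.

#' Evaluate a set of models on validation and test predictions
#'
#' For each model: fit Platt recalibration on the validation fold, apply it
#' to the test scores, then compute AUC and AUPRC with confidence
#' intervals, a spline calibration curve and a decision curve on the
#' recalibrated test scores.
#'
#' @param pred_list named list (one entry per model) of lists with elements
#'   `validation` and `test`, each a score vector.
#' @param val_labels,test_labels binary outcomes of the two folds.
#' @param thresholds decision-curve threshold grid.
#' @return an `eval_report`: `metrics` (one row per model), `calibration`,
#'   `decision`, `recalibration` (per-model Platt parameters).
#' @export
evaluate_all <- function(pred_list, val_labels, test_labels,
                         thresholds = seq(0.001, 0.5, by = 0.001)) {
  stopifnot(length(pred_list) > 0)
  metrics <- NULL
  calib <- list(); decis <- list(); recal <- list()
  for (nm in names(pred_list)) {
    pr <- pred_list[[nm]]
    params <- platt_fit(pr$validation, val_labels)
    test_cal <- platt_apply(pr$test, params)
    a_ci <- auc_ci(test_cal, test_labels)
    p_ci <- auprc_ci(test_cal, test_labels)
    metrics <- rbind(metrics, data.frame(
      model = nm,
      auc = a_ci$estimate, auc_lower = a_ci$lower, auc_upper = a_ci$upper,
      auprc = p_ci$estimate, auprc_lower = p_ci$lower, auprc_upper = p_ci$upper,
      platt_a = params$a, platt_b = params$b))
    calib[[nm]] <- smooth_calibration(test_cal, test_labels)
    decis[[nm]] <- net_benefit(test_cal, test_labels, thresholds)
    recal[[nm]] <- params
  }
  structure(list(metrics = metrics, calibration = calib, decision = decis,
                 recalibration = recal,
                 prevalence = mean(test_labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> test-fold performance (recalibrated):\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s AUC %.3f [%.3f, %.3f]  AUPRC %.3f [%.3f, %.3f]\n",
                m$model[i], m$auc[i], m$auc_lower[i], m$auc_upper[i],
                m$auprc[i], m$auprc_lower[i], m$auprc_upper[i]))
  invisible(x)
}

#' Write an evaluation report bundle to a directory
#'
#' Emits `metrics.tsv`, per-model calibration and decision curve CSVs, a
#' machine-readable `summary.json`, and (optionally) SVG figures.
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @param figures also render SVG figures.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, figures = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$metrics, file.path(dir, "metrics.tsv"), sep = "\t")
  for (nm in names(report$calibration)) {
    cc <- report$calibration[[nm]]
    data.table::fwrite(data.frame(predicted = cc$grid, observed = cc$observed,
                                  lower = cc$lower, upper = cc$upper),
                       file.path(dir, paste0("calibration_", nm, ".csv")))
    dc <- report$decision[[nm]]
    data.table::fwrite(data.frame(threshold = dc$thresholds,
                                  net_benefit = dc$net_benefit,
                                  treat_all = dc$treat_all,
                                  treat_none = dc$treat_none),
                       file.path(dir, paste0("decision_", nm, ".csv")))
    if (figures) {
      grDevices::svg(file.path(dir, paste0("calibration_", nm, ".svg")))
      plot(cc, main = nm); grDevices::dev.off()
      grDevices::svg(file.path(dir, paste0("decision_", nm, ".svg")))
      plot(dc, main = nm); grDevices::dev.off()
    }
  }
  jsonlite::write_json(
    list(prevalence = report$prevalence,
         metrics = report$metrics,
         recalibration = lapply(report$recalibration,
                                function(p) list(a = p$a, b = p$b))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = 10,
    dataframe = "rows")
  invisible(dir)
}
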