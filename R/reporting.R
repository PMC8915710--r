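# Bland-Altman agreement analysis and the comparison report across
# waveform, BNP-only, and dummy models.

#' Bland-Altman agreement analysis
#'
#' For paired predicted/actual pressures, computes per-subject means and
#' differences (predicted - actual), the bias (mean difference), 1.96-SD
#' limits of agreement, and the slope of difference on mean with its
#' p-value as a proportional-bias check.
#'
#' @param pred,actual Equal-length numeric vectors (mmHg), n >= 3.
#' @return An object of class `bland_altman`: `data` (per-subject `mean`,
#'   `diff`), `bias`, `loa_low`, `loa_high`, `slope`, `slope_p`.
#' @export
bland_altman <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop_usage("pred and actual must have equal length")
  }
  if (length(pred) < 3) stop_usage("Bland-Altman needs at least 3 pairs")
  m <- (pred + actual) / 2
  d <- pred - actual
  bias <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d > 0 && stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    slope_p <- summary(fit)$coefficients[2, 4]
  } else {
    slope <- 0
    slope_p <- NA_real_
  }
  structure(list(data = data.frame(mean = m, diff = d),
                 bias = bias,
                 loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d,
                 slope = slope, slope_p = slope_p),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f mmHg, limits of agreement [%.3f, %.3f]\n  proportional-bias slope %.3f (p = %.3g)\n",
    x$bias, x$loa_low, x$loa_high, x$slope, x$slope_p))
  invisible(x)
}

metrics_row <- function(m) {
  c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
    f1 = m$f1, auroc = m$auroc, specificity = m$specificity)
}

#' Build the model-comparison report table
#'
#' One block per analysis case (regression, classification at the 10 and
#' 15 mmHg cutoffs) listing the selected feature terms and the full metric
#' suite for the waveform model, the dummy baseline, and the BNP-only
#' comparator, as a long data.frame (`case`, `terms`, `arm`, `metric`,
#' `value`). Values are carried over verbatim from the modeling outputs -
#' nothing is recomputed. Cases not supplied are omitted with a message.
#'
#' @param regression Optional list with `fit` (`regression_fit`), `cv`
#'   ([cv_regress()] output), `bnp` ([bnp_only_model()] regression output)
#'   and `terms` (character).
#' @param classification Optional named list (e.g. `classify_15`,
#'   `classify_10`), each element a list with `model`, `dummy`, `bnp`
#'   (`classifier_metrics`) and `terms`.
#' @return A data.frame of class `report_table`.
#' @export
build_report <- function(regression = NULL, classification = NULL) {
  rows <- list()
  add <- function(case, arm, metric, value, terms) {
    rows[[length(rows) + 1]] <<- data.frame(
      case = case, terms = paste(terms, collapse = "; "),
      arm = arm, metric = metric, value = value)
  }
  if (!is.null(regression)) {
    tm <- regression$terms
    add("regression", "model", "r2", regression$fit$r2, tm)
    add("regression", "model", "adj_r2", regression$fit$adj_r2, tm)
    add("regression", "model", "p_value", regression$fit$f_p_value, tm)
    add("regression", "model", "cv_r2", regression$cv$cv_r2, tm)
    if (!is.null(regression$bnp)) {
      add("regression", "bnp", "r2", regression$bnp$fit$r2, "bnp")
      add("regression", "bnp", "adj_r2", regression$bnp$fit$adj_r2, "bnp")
      add("regression", "bnp", "p_value", regression$bnp$fit$f_p_value, "bnp")
      add("regression", "bnp", "cv_r2", regression$bnp$cv$cv_r2, "bnp")
    }
  } else {
    message("report: regression case omitted (no metrics supplied)")
  }
  for (case in names(classification)) {
    cc <- classification[[case]]
    if (is.null(cc$model)) {
      message(sprintf("report: %s case omitted (no metrics supplied)", case))
      next
    }
    for (arm in intersect(c("model", "dummy", "bnp"), names(cc))) {
      mr <- metrics_row(cc[[arm]])
      for (met in names(mr)) {
        add(case, arm, met, mr[[met]],
            if (arm == "model") cc$terms else arm)
      }
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(case = character(0), terms = character(0),
               arm = character(0), metric = character(0),
               value = numeric(0))
  }
  class(out) <- c("report_table", "data.frame")
  out
}
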