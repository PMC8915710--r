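# End-to-end conveniences tying the stages together: cohort -> features ->
# candidate pool -> selection -> cross-validated regression/classification
# against the dummy and BNP-only baselines.

#' Regression analysis of filling pressure from waveform features
#'
#' Forward-selects up to three features from the candidate pool (or takes
#' the fixed published-style set), fits OLS on the full data, computes the
#' fivefold cross-validated R-squared for the selected set, runs the
#' BNP-only comparator through the same machinery, and produces a
#' Bland-Altman analysis of both the in-sample and the pooled held-out
#' predictions against the measured pressures.
#'
#' @param fm A `feature_matrix` from [build_candidate_pool()].
#' @param features `"search"` (fresh forward selection, the default) or
#'   `"final"` (the fixed three-feature set of [final_model_features()]).
#' @param k Cap on selected features.
#' @param folds,seed Cross-validation controls.
#' @return A list: `terms`, `trace` (when searched), `fit`, `cv`, `bnp`,
#'   `bland_altman_insample`, `bland_altman_cv`.
#' @export
regression_analysis <- function(fm, features = c("search", "final"), k = 3,
                                folds = 5, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  features <- match.arg(features)
  if (features == "search") {
    trace <- forward_select(fm$x, fm$target, k = k, type = "regression")
    terms <- attr(trace, "selected")
  } else {
    trace <- NULL
    terms <- final_model_features(fm, "regression")$feature_names
  }
  Xs <- fm$x[, terms, drop = FALSE]
  fit <- fit_ols(Xs, fm$target)
  cv <- cv_regress(Xs, fm$target, folds = folds, seed = seed)
  bnp <- bnp_only_model(fm$bnp, fm$target, type = "regression",
                        folds = folds, seed = seed)
  list(terms = terms, trace = trace, fit = fit, cv = cv, bnp = bnp,
       bland_altman_insample = bland_altman(fit$fitted, fm$target),
       bland_altman_cv = bland_altman(cv$predictions, fm$target))
}

#' Classification analysis of volume overload from waveform features
#'
#' Labels subjects at the chosen cutoff, forward-selects up to three
#' features for the chosen classifier (or takes the fixed set for that
#' cutoff), and evaluates the classifier, the majority-class dummy, and
#' the BNP-only comparator with stratified fivefold cross-validation and
#' pooled metrics.
#'
#' @param fm A `feature_matrix`.
#' @param cutoff Overload cutoff in mmHg (15 primary, 10 sensitivity).
#' @param method Classifier (see [cv_classify()]).
#' @param features `"search"` or `"final"`.
#' @param k Cap on selected features.
#' @param folds,seed Cross-validation controls.
#' @return A list: `terms`, `trace`, `model`, `dummy`, `bnp`
#'   (`classifier_metrics`), `labels`, `cutoff`, `method`.
#' @export
classification_analysis <- function(fm, cutoff = 15, method = "lda",
                                    features = c("search", "final"), k = 3,
                                    folds = 5, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  features <- match.arg(features)
  labels <- label_overload(fm$target, cutoff)
  if (features == "search") {
    trace <- forward_select(fm$x, labels, k = k, type = "classification",
                            method = method)
    terms <- attr(trace, "selected")
  } else {
    trace <- NULL
    case <- if (cutoff == 10) "classify_10" else "classify_15"
    terms <- final_model_features(fm, case)$feature_names
  }
  Xs <- fm$x[, terms, drop = FALSE]
  list(terms = terms, trace = trace,
       model = cv_classify(Xs, labels, method = method, folds = folds,
                           seed = seed),
       dummy = dummy_classify(labels, folds = folds, seed = seed),
       bnp = bnp_only_model(fm$bnp, labels, type = "classification",
                            method = method, folds = folds, seed = seed),
       labels = labels, cutoff = cutoff, method = method)
}
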