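# Modeling: OLS regression of filling pressure with fivefold-CV R-squared,
# capped greedy forward feature selection, the five classifiers plus the
# majority-class dummy baseline with pooled CV metrics, and the BNP-only
# comparator.

#' Ordinary least squares fit with collinearity handling
#'
#' Fits `y ~ X` with an intercept by QR decomposition. Exactly collinear
#' columns (pivoted out at relative tolerance 1e-10) are dropped with a
#' warning before fitting; a design that is still rank-deficient afterwards
#' is an error.
#'
#' @param X Numeric matrix (subjects x features) with column names.
#' @param y Numeric response (filling pressure, mmHg).
#' @return An object of class `regression_fit`: `feature_names`,
#'   `coefficients` (intercept first), `fitted`, `residuals`, `r2`,
#'   `adj_r2`, `f_p_value`, `n`, `p`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop_usage("X and y dimensions disagree")
  if (n <= ncol(X) + 1) {
    stop_modeling("need n > p + 1 observations for OLS")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xd, tol = 1e-10)
  if (qrx$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qrx$pivot[(qrx$rank + 1):ncol(Xd)]]
    if ("(Intercept)" %in% dropped) {
      stop_modeling("design rank-deficient: intercept not estimable")
    }
    warning(sprintf("dropping exactly collinear column(s): %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    Xd <- cbind(`(Intercept)` = 1, X)
    qrx <- qr(Xd, tol = 1e-10)
    if (qrx$rank < ncol(Xd)) {
      stop_modeling("design still rank-deficient after dropping collinear columns")
    }
  }
  coef <- qr.coef(qrx, y)
  fitted <- drop(Xd %*% coef)
  resid <- y - fitted
  p <- ncol(X)
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f_p <- if (p > 0 && sse > 0) {
    f <- ((sst - sse) / p) / (sse / (n - p - 1))
    stats::pf(f, p, n - p - 1, lower.tail = FALSE)
  } else if (sse == 0) 0 else NA_real_
  structure(list(feature_names = colnames(X), coefficients = coef,
                 fitted = fitted, residuals = resid, r2 = r2,
                 adj_r2 = adj_r2, f_p_value = f_p, n = n, p = p),
            class = "regression_fit")
}

#' Predict from a `regression_fit`
#' @param object A `regression_fit`.
#' @param newdata Numeric matrix with the fit's feature columns.
#' @param ... Unused.
#' @return Predicted values (mmHg).
#' @export
predict.regression_fit <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  drop(cbind(1, nd) %*% object$coefficients)
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %d features, n = %d\n  R2 = %.3f, adj. R2 = %.3f, F-test p = %.3g\n",
              x$p, x$n, x$r2, x$adj_r2, x$f_p_value))
  invisible(x)
}

# shuffled fold assignment (plain, for regression)
make_folds <- function(n, folds, seed) {
  if (n < folds) stop_modeling("need at least as many observations as folds")
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

# stratified fold assignment (classification): shuffle within class,
# deal round-robin so every fold gets its share of the minority class
make_stratified_folds <- function(labels, folds, seed) {
  if (length(labels) < folds) {
    stop_modeling("need at least as many observations as folds")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    i <- i[sample.int(length(i))]
    fold[i] <- rep(seq_len(folds), length.out = length(i))
  }
  fold
}

#' Cross-validated R-squared for a fixed feature set
#'
#' Deterministic seeded shuffle into `folds` folds; the OLS model is refit
#' on each training fold and applied to the held-out rows; the pooled
#' cross-validated R-squared is
#' `1 - sum((y - yhat_heldout)^2) / sum((y - mean(y))^2)` over all
#' held-out predictions.
#'
#' @param X Numeric matrix (fixed feature set; no re-selection inside CV).
#' @param y Numeric response.
#' @param folds Number of folds.
#' @param seed Seed for the fold shuffle.
#' @return A list: `cv_r2`, `predictions` (pooled held-out, in row order),
#'   `fold` (fold assignment).
#' @export
cv_regress <- function(X, y, folds = 5, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  fold <- make_folds(n, folds, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (sum(tr) < ncol(X) + 2) {
      stop_modeling("a training fold has fewer than p + 2 rows; use fewer features or more data")
    }
    fit <- fit_ols(X[tr, , drop = FALSE], y[tr])
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  list(cv_r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       predictions = pred, fold = fold)
}

#' Label volume overload from filling pressure
#'
#' Strict inequality: a pressure exactly at the threshold is not overloaded.
#'
#' @param pressure Filling pressure(s), mmHg; positive.
#' @param threshold Cutoff (mmHg); 15 is the primary definition, 10 the
#'   sensitivity cutoff.
#' @return Logical vector.
#' @export
label_overload <- function(pressure, threshold = 15) {
  if (any(pressure <= 0)) stop_usage("pressure must be positive")
  if (threshold <= 0) stop_usage("threshold must be positive")
  pressure > threshold
}

# z-score standardization fitted on training rows only
fit_scaler <- function(train) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(sc, m) sweep(sweep(m, 2, sc$mu), 2, sc$sd, "/")

CLASSIFIER_METHODS <- c("lda", "logistic", "knn", "tree", "svm_rbf", "dummy")

# fit `method` on (train, trainlab) and return for `test` a list with
# `label` (logical predictions) and `score` (higher = more positive).
# knn/svm/logistic standardize using training-fold statistics.
fit_predict_classifier <- function(method, train, trainlab, test,
                                   knn_k = 5, tree_maxdepth = 3,
                                   svm_cost = 1) {
  pos <- "TRUE"
  yf <- factor(trainlab, levels = c("FALSE", "TRUE"))
  if (method %in% c("knn", "svm_rbf", "logistic")) {
    sc <- fit_scaler(train)
    train <- apply_scaler(sc, train)
    test <- apply_scaler(sc, test)
  }
  if (method == "lda") {
    m <- MASS::lda(train, grouping = yf)
    pr <- stats::predict(m, test)
    score <- pr$posterior[, pos]
    label <- pr$class == pos
  } else if (method == "logistic") {
    df <- as.data.frame(train)
    m <- suppressWarnings(stats::glm(yf ~ ., data = cbind(df, yf = yf),
                                     family = stats::binomial()))
    score <- suppressWarnings(
      stats::predict(m, newdata = as.data.frame(test), type = "response"))
    label <- score > 0.5
  } else if (method == "knn") {
    pr <- class::knn(train, test, cl = yf, k = knn_k, prob = TRUE)
    pwin <- attr(pr, "prob")
    score <- ifelse(pr == pos, pwin, 1 - pwin)
    label <- pr == pos
  } else if (method == "tree") {
    df <- as.data.frame(train)
    names(df) <- make.names(names(df))
    tdf <- as.data.frame(test)
    names(tdf) <- names(df)
    m <- rpart::rpart(yf ~ ., data = cbind(df, yf = yf), method = "class",
                      control = rpart::rpart.control(maxdepth = tree_maxdepth,
                                                     minsplit = 10,
                                                     cp = 0.01))
    score <- stats::predict(m, newdata = tdf, type = "prob")[, pos]
    label <- score > 0.5
  } else if (method == "svm_rbf") {
    gamma <- 1 / (ncol(train) * max(stats::var(as.vector(train)), 1e-12))
    m <- e1071::svm(train, yf, kernel = "radial", cost = svm_cost,
                    gamma = gamma, scale = FALSE)
    pr <- stats::predict(m, test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the decision values so higher means the positive class
    score <- if (grepl(sprintf("^%s/", pos), colnames(dv)[1])) {
      dv[, 1]
    } else {
      -dv[, 1]
    }
    label <- pr == pos
  } else if (method == "dummy") {
    maj <- sum(trainlab) > sum(!trainlab)   # tie goes to the negative class
    label <- rep(maj, nrow(test))
    score <- rep(0.5, nrow(test))           # constant: every pair tied
  } else {
    stop_usage(sprintf("unknown classifier method '%s'", method))
  }
  list(label = as.logical(label), score = as.numeric(score))
}

#' Area under the ROC curve via the rank (Mann-Whitney) statistic
#'
#' `AUROC = (sum of positive-score ranks - n1(n1+1)/2) / (n1 n0)` with
#' midranks for ties, identical to the all-pairs count with ties scored
#' one-half. A constant score gives exactly 0.5.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_usage("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pooled_metrics <- function(method, labels, pred, scores, fold) {
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    method = method,
    accuracy = (tp + tn) / length(labels),
    precision = precision,
    recall = recall,
    f1 = f1,
    specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
    auroc = auroc(scores, labels),
    scores = scores, predicted = pred, labels = labels, fold = fold
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "%s (pooled CV): accuracy %.3f, precision %.2f, recall %.2f, F1 %.2f, specificity %.2f, AUROC %.3f\n",
    x$method, x$accuracy, x$precision, x$recall, x$f1, x$specificity,
    x$auroc))
  invisible(x)
}

#' Cross-validated classification with pooled metrics
#'
#' Stratified seeded folds; the classifier is refit on each training fold
#' (with z-score standardization fitted on the training rows only for
#' `knn`, `svm_rbf` and `logistic`), held-out class scores and labels are
#' pooled, and the metric suite (accuracy, precision, recall, F1,
#' specificity, AUROC) is computed once on the pooled predictions.
#'
#' Fixed hyperparameters: `knn` uses 5 neighbors; `tree` depth <= 3;
#' `svm_rbf` cost 1 with kernel scale `1/(p * var)`. Scores for AUROC are
#' positive-class posterior probabilities (LDA, logistic, tree), the
#' winning-class vote fraction folded to the positive class (KNN), and
#' oriented decision values (SVM).
#'
#' @param X Numeric feature matrix.
#' @param labels Logical labels (both classes must be present).
#' @param method One of `"lda"`, `"logistic"`, `"knn"`, `"tree"`,
#'   `"svm_rbf"`, `"dummy"`.
#' @param folds Number of folds.
#' @param seed Seed for the stratified shuffle.
#' @return A `classifier_metrics` object.
#' @export
cv_classify <- function(X, labels, method = "lda", folds = 5, seed = 1) {
  X <- as.matrix(X)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop_modeling("both classes must be present")
  }
  if (!method %in% CLASSIFIER_METHODS) {
    stop_usage(sprintf("unknown classifier method '%s'", method))
  }
  fold <- make_stratified_folds(labels, folds, seed)
  pred <- logical(length(labels))
  score <- numeric(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2) {
      stop_modeling("a training fold contains a single class; stratification failed")
    }
    out <- fit_predict_classifier(method, X[tr, , drop = FALSE], labels[tr],
                                  X[!tr, , drop = FALSE])
    pred[!tr] <- out$label
    score[!tr] <- out$score
  }
  pooled_metrics(method, labels, pred, score, fold)
}

#' Majority-class dummy baseline
#'
#' Predicts the training-fold majority class for every held-out row with a
#' constant score. When the negative ("non-overloaded") class is the
#' majority this yields recall 0, precision 0 (by the 0/0 = 0 convention),
#' F1 0, specificity 1, and AUROC exactly 0.5 (a constant score ties every
#' positive-negative pair).
#'
#' @param labels Logical labels.
#' @param folds,seed As in [cv_classify()].
#' @return A `classifier_metrics` object.
#' @export
dummy_classify <- function(labels, folds = 5, seed = 1) {
  cv_classify(matrix(0, length(labels), 1,
                     dimnames = list(NULL, "none")),
              labels, method = "dummy", folds = folds, seed = seed)
}

#' Greedy forward feature selection capped at k features
#'
#' At each step the candidate maximizing the in-sample criterion
#' (regression: OLS R-squared; classification: resubstitution accuracy of
#' the estimator refit with the trial feature set) joins the model; ties
#' break toward the earlier column in the pool's deterministic order.
#' The first step always admits the single best candidate; thereafter
#' selection stops early when no candidate strictly improves the
#' criterion.
#' Selection is performed on the full dataset - the small-sample design
#' this pipeline mirrors, which trades fold-honest selection for stability
#' and caps the model at `k` features to limit the resulting optimism.
#'
#' @param X Candidate pool matrix with named columns.
#' @param target Numeric response (regression) or logical labels
#'   (classification).
#' @param k Maximum number of features (default 3).
#' @param type `"regression"` or `"classification"`.
#' @param method Classifier used for the classification criterion.
#' @return An object of class `selection_trace`: data.frame with `step`,
#'   `feature`, `criterion` (value after the addition), plus attribute
#'   `selected` (character vector).
#' @export
forward_select <- function(X, target, k = 3,
                           type = c("regression", "classification"),
                           method = "lda") {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) < 1) stop_usage("candidate pool is empty")
  if (k < 1) stop_usage("k must be at least 1")
  if (k > ncol(X)) stop_usage("k exceeds the pool size")
  crit <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    if (type == "regression") {
      fit_ols(Xs, target)$r2
    } else {
      out <- fit_predict_classifier(method, Xs, target, Xs)
      mean(out$label == target)
    }
  }
  selected <- character(0)
  best <- -Inf   # the first step always admits the single best candidate
  trace <- data.frame(step = integer(0), feature = character(0),
                      criterion = numeric(0))
  for (step in seq_len(k)) {
    cand <- setdiff(colnames(X), selected)
    vals <- vapply(cand, function(f) {
      tryCatch(crit(c(selected, f)), error = function(e) -Inf)
    }, numeric(1))
    i <- which.max(vals)     # first maximum = earliest pool column on ties
    if (!is.finite(vals[i]) || vals[i] <= best) break
    selected <- c(selected, cand[i])
    best <- vals[i]
    trace <- rbind(trace, data.frame(step = step, feature = cand[i],
                                     criterion = best))
  }
  if (length(selected) == 0) {
    stop_modeling("forward selection found no improving feature")
  }
  structure(trace, class = c("selection_trace", "data.frame"),
            selected = selected)
}

#' BNP-only comparator model
#'
#' Runs the same cross-validation machinery with serum BNP as the sole
#' feature: OLS regression of filling pressure (`type = "regression"`) or
#' classification of the overload label.
#'
#' @param bnp Positive BNP values (pg/ml).
#' @param target Filling pressure (regression) or logical labels.
#' @param type `"regression"` or `"classification"`.
#' @param method Classifier for the classification case.
#' @param folds,seed Cross-validation controls.
#' @return For regression, a list `fit` (`regression_fit`) and `cv`
#'   ([cv_regress()] output); for classification, a `classifier_metrics`.
#' @export
bnp_only_model <- function(bnp, target,
                           type = c("regression", "classification"),
                           method = "lda", folds = 5, seed = 1) {
  type <- match.arg(type)
  if (any(bnp <= 0)) stop_usage("BNP must be positive")
  X <- matrix(bnp, ncol = 1, dimnames = list(NULL, "bnp"))
  if (type == "regression") {
    list(fit = fit_ols(X, target),
         cv = cv_regress(X, target, folds = folds, seed = seed))
  } else {
    cv_classify(X, target, method = method, folds = folds, seed = seed)
  }
}
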