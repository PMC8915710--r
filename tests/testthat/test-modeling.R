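# OLS, cross-validation, forward selection, classifiers, dummy baseline.

test_that("OLS recovers exact linear data and rejects tiny samples", {
  set.seed(51)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- 2 + 3 * X[, "a"] - X[, "b"]
  fit <- fit_ols(X, y)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$coefficients), c(2, 3, -1), tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_error(fit_ols(X[1:3, ], y[1:3]), class = "ppgv_modeling_error")
})

test_that("an irrelevant noise column explains nothing", {
  set.seed(52)
  X <- cbind(noise = rnorm(200))
  y <- rnorm(200)
  fit <- fit_ols(X, y)
  expect_lt(fit$r2, 0.05)
  expect_lt(abs(fit$coefficients[["noise"]]), 0.2)
})

test_that("six-point fit matches the normal-equations oracle to 1e-10", {
  X <- cbind(x1 = c(1, 2, 3, 5, 7, 8), x2 = c(2, 1, 4, 3, 6, 5))
  y <- c(3.1, 2.9, 5.2, 6.8, 9.9, 10.1)
  fit <- fit_ols(X, y)
  Xd <- cbind(1, X)
  beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-10)
  r_oracle <- drop(y - Xd %*% beta_oracle)
  expect_equal(1 - sum(r_oracle^2) / sum((y - mean(y))^2), fit$r2,
               tolerance = 1e-10)
})

test_that("exact collinearity is dropped with a warning; invariants hold", {
  set.seed(53)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x, c = rnorm(30))
  y <- x + rnorm(30)
  expect_warning(fit <- fit_ols(X, y), "collinear")
  expect_false("b" %in% fit$feature_names)
  # residual-sum-zero and adj_r2 <= r2 on random fits
  for (s in 54:58) {
    set.seed(s)
    Xr <- matrix(rnorm(40 * 3), 40, 3,
                 dimnames = list(NULL, c("u", "v", "w")))
    yr <- rnorm(40)
    f <- fit_ols(Xr, yr)
    expect_lt(abs(sum(f$residuals)), 1e-8)
    expect_lte(f$adj_r2, f$r2)
  }
})

test_that("cv_regress matches an explicit-loop pooled oracle", {
  set.seed(60)
  X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + X[, 1] - 0.5 * X[, 2] + rnorm(30, 0, 0.7)
  out <- cv_regress(X, y, folds = 5, seed = 9)
  # oracle: same fold assignment, lm() per fold, pooled formula by hand
  fold <- out$fold
  pred <- rep(NA_real_, 30)
  for (f in 1:5) {
    df <- data.frame(y = y[fold != f], X[fold != f, , drop = FALSE])
    m <- lm(y ~ a + b, data = df)
    pred[fold == f] <- predict(m, newdata = as.data.frame(X[fold == f, ,
                                                            drop = FALSE]))
  }
  cv_oracle <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(out$cv_r2, cv_oracle, tolerance = 1e-10)
  expect_equal(out$predictions, pred, tolerance = 1e-10)
})

test_that("cv_regress is 1 on noiseless data and ~0 under permutation", {
  set.seed(61)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * X[, 1] + X[, 2]
  expect_equal(cv_regress(X, y, seed = 1)$cv_r2, 1, tolerance = 1e-10)
  yp <- sample(rnorm(100))
  expect_lt(cv_regress(matrix(rnorm(200), 100, 2), yp, seed = 1)$cv_r2, 0.1)
})

test_that("overload labels use a strict threshold", {
  expect_false(label_overload(15.0, 15))
  expect_true(label_overload(15.0001, 15))
  expect_true(label_overload(23.67, 15))
  expect_false(label_overload(10.59, 15))
  expect_true(label_overload(10.5, 10))
  expect_error(label_overload(-2, 15), class = "ppgv_usage_error")
})

test_that("forward selection finds an exact predictor immediately", {
  set.seed(62)
  X <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, "f4"]
  tr <- forward_select(X, y, k = 3, type = "regression")
  expect_equal(tr$feature[1], "f4")
  expect_equal(tr$criterion[1], 1)
})

test_that("first selection equals the exhaustive single-feature scan", {
  set.seed(63)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- 0.8 * X[, 3] + 0.4 * X[, 6] + rnorm(60)
  tr <- forward_select(X, y, k = 3, type = "regression")
  scan <- vapply(colnames(X), function(f) {
    summary(lm(y ~ X[, f]))$r.squared
  }, numeric(1))
  expect_equal(tr$feature[1], names(which.max(scan)))
  expect_true(all(diff(tr$criterion) > 0))
  expect_lte(nrow(tr), 3)
  expect_error(forward_select(X, y, k = 20), class = "ppgv_usage_error")
})

test_that("classification forward selection improves monotonically", {
  fm <- make_pool(40, seed = 64)
  labels <- label_overload(fm$target, 15)
  tr <- forward_select(fm$x, labels, k = 3, type = "classification",
                       method = "lda")
  expect_true(all(diff(tr$criterion) > 0))
  expect_lte(nrow(tr), 3)
})

test_that("AUROC equals the all-pairs brute force, ties counted one-half", {
  scores <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.8, 0.2, 0.55, 0.4, 0.9, 0.05, 0.55)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
              FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  # random score sets up to a few hundred points
  for (s in 65:68) {
    set.seed(s)
    n <- sample(50:400, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    lb <- runif(n) < 0.3
    if (length(unique(lb)) < 2) next
    expect_equal(auroc(sc, lb), auroc_bruteforce(sc, lb))
  }
  expect_equal(auroc(rep(0.5, 10), c(rep(TRUE, 4), rep(FALSE, 6))), 0.5)
})

test_that("classifiers separate separable classes and not shuffled ones", {
  set.seed(70)
  n <- 120
  lb <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(a = rnorm(n, ifelse(lb, 3, -3), 0.3),
             b = rnorm(n))
  for (m in c("lda", "logistic", "knn", "tree", "svm_rbf")) {
    cm <- cv_classify(X, lb, method = m, folds = 5, seed = 3)
    expect_equal(cm$accuracy, 1, tolerance = 0.02)
    expect_equal(cm$auroc, 1, tolerance = 0.02)
  }
  set.seed(71)
  lbs <- sample(lb)
  Xs <- cbind(a = rnorm(200), b = rnorm(200))
  cm0 <- cv_classify(Xs, runif(200) < 0.5, method = "lda", seed = 3)
  expect_lt(abs(cm0$auroc - 0.5), 0.1)
})

test_that("metric suite lies in [0,1] and respects f1 conventions", {
  fm <- make_pool(40, seed = 72)
  labels <- label_overload(fm$target, 15)
  cm <- cv_classify(fm$x[, c("ratio_amplitude", "age")], labels,
                    method = "lda", seed = 5)
  for (v in c(cm$accuracy, cm$precision, cm$recall, cm$f1, cm$specificity,
              cm$auroc)) {
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("a class too rare to stratify is a modeling error", {
  set.seed(73)
  lb <- c(TRUE, rep(FALSE, 29))
  X <- cbind(a = rnorm(30))
  expect_error(cv_classify(X, lb, method = "lda", folds = 5, seed = 1),
               class = "ppgv_modeling_error")
  expect_error(cv_classify(X, rep(TRUE, 30), method = "lda"),
               class = "ppgv_modeling_error")
})

test_that("dummy baseline has the majority-class identities", {
  for (s in 74:78) {
    set.seed(s)
    lb <- runif(40) < 0.3
    if (sum(lb) < 5 || sum(lb) >= 20) next
    dm <- dummy_classify(lb, folds = 5, seed = s)
    expect_equal(dm$recall, 0)
    expect_equal(dm$precision, 0)
    expect_equal(dm$f1, 0)
    expect_equal(dm$specificity, 1)
    expect_equal(dm$auroc, 0.5)
    # counting oracle: accuracy = pooled majority-class fraction
    expect_equal(dm$accuracy, mean(!lb))
  }
})

test_that("BNP-only comparator handles degenerate inputs", {
  set.seed(80)
  y <- rnorm(50, 15, 5)
  suppressWarnings(
    out <- bnp_only_model(rep(100, 50), y, type = "regression", seed = 2))
  expect_lte(out$cv$cv_r2, 0)
  exact <- bnp_only_model(pmax(y, 1), pmax(y, 1), type = "regression",
                          seed = 2)
  expect_equal(exact$cv$cv_r2, 1, tolerance = 1e-10)
  expect_error(bnp_only_model(c(-1, 2, 3), y[1:3], type = "regression"),
               class = "ppgv_usage_error")
})

test_that("cv_r2 does not exceed in-sample r2 on noisy cohorts (sign test)", {
  wins <- 0
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    set.seed(s + 900)
    p <- draw_filling_pressure(sim_config(seed = s), 40)
    # noisy monotone transforms of pressure stand in for subject features
    X <- cbind(f1 = plogis((p - 15) / 3) + rnorm(40, 0, 0.08),
               f2 = p * 0.02 + rnorm(40, 0, 0.1),
               f3 = rnorm(40))
    fit <- fit_ols(X, p)
    cv <- cv_regress(X, p, folds = 5, seed = s)
    if (cv$cv_r2 <= fit$r2) wins <- wins + 1
  }
  expect_lt(binom.test(wins, n_rep, 0.5, alternative = "greater")$p.value,
            0.01)
  expect_gte(wins / n_rep, 0.8)
})
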