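# small separable fixture: feature "signal" carries the label, "noise" doesn't
separable <- local({
  set.seed(21)
  n <- 120
  y <- rep(c(1L, 0L), each = n / 2)
  data.frame(signal = y + rnorm(n, sd = 0.05), noise = rnorm(n), y = y)
})

test_that("random forest separates a clean signal and is seed-reproducible", {
  x <- separable[, c("signal", "noise")]
  fit <- rf_fit(x, separable$y, ntree = 60, seed = 5)
  p <- predict(fit, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(f1_score(confusion_counts(p, separable$y)), 1)
  expect_lt(fit$oob_error, 0.05)

  fit2 <- rf_fit(x, separable$y, ntree = 60, seed = 5)
  expect_identical(predict(fit2, x), p)
  expect_identical(fit2$mda, fit$mda)

  fit3 <- rf_fit(x, separable$y, ntree = 60, seed = 6)
  expect_false(identical(fit3$trees, fit$trees))

  expect_gt(fit$mda["signal"], fit$mda["noise"])
  expect_gt(fit$mdg["signal"], fit$mdg["noise"])
  expect_error(rf_fit(x, rep(1, nrow(x))), "both classes")
  expect_error(rf_fit(transform(x, signal = NA), separable$y), "NaN/NA")
})

test_that("rf prediction enforces the training column contract", {
  x <- separable[, c("signal", "noise")]
  fit <- rf_fit(x, separable$y, ntree = 30, seed = 1)
  expect_error(predict(fit, x[, "signal", drop = FALSE]), "missing")
  # reordered columns are realigned by name
  expect_equal(predict(fit, x[, c("noise", "signal")]), predict(fit, x))
  expect_length(predict(fit, x[0, ]), 0L)
})

test_that("RBF SVM separates the same fixture with Platt probabilities", {
  x <- separable[, c("signal", "noise")]
  fit <- svm_fit(x, separable$y, cost = 4, lambda = 0.5)
  p <- predict(fit, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(f1_score(confusion_counts(p, separable$y)), 1)
  expect_error(svm_fit(x, rep(0, nrow(x))), "both classes")
})

test_that("train_model picks hyperparameters by OOB error / CV F1", {
  x <- separable[, c("signal", "noise")]
  m1 <- train_model(x, separable$y,
                    model_spec("rf", ntree = 50, mtry_grid = 2L, seed = 3))
  expect_equal(m1$params$mtry, 2L)  # degenerate grid: that value chosen

  m2 <- train_model(x, separable$y,
                    model_spec("rf", ntree = 50, mtry_grid = c(1L, 2L), seed = 3))
  expect_equal(m2$params$mtry,
               as.integer(names(which.min(m2$params$oob_grid))))
  m2b <- train_model(x, separable$y,
                     model_spec("rf", ntree = 50, mtry_grid = c(1L, 2L), seed = 3))
  expect_identical(m2$params, m2b$params)

  m3 <- train_model(x, separable$y,
                    model_spec("svm", cost_grid = c(1, 4), lambda_grid = 0.5,
                               cv_folds = 3, seed = 3))
  expect_true(m3$params$cost %in% c(1, 4))
  p <- predict_proba(m3, x)
  expect_equal(f1_score(confusion_counts(p, separable$y)), 1)
})

test_that("permutation importance flags the oracle feature, not constants", {
  set.seed(30)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  x <- data.frame(oracle = y, constant = 1, junk = rnorm(n))
  m <- train_model(x, y, model_spec("rf", ntree = 50, mtry_grid = 2L, seed = 1))
  imp <- permutation_importance(m, x, y, n_repeats = 5, seed = 2)
  expect_equal(nrow(imp), 3L)
  expect_equal(imp$mda[imp$feature == "constant"], 0, tolerance = 1e-12)
  expect_equal(imp$feature[which.max(imp$mda)], "oracle")
  expect_true(all(c("oob_mda", "mdg") %in% names(imp)))

  msvm <- train_model(x, y, model_spec("svm", cost_grid = 1, lambda_grid = 0.5,
                                       cv_folds = 3, seed = 1))
  expect_error(permutation_importance(msvm, x, y, include_mdg = TRUE),
               "Gini.*random forests")
  imp_svm <- permutation_importance(msvm, x, y, n_repeats = 2, seed = 2)
  expect_false("mdg" %in% names(imp_svm))
})

test_that("importance stability reports per-feature spread and F1 range", {
  set.seed(31)
  n <- 400
  y <- rep(c(1L, 0L), each = n / 2)
  x <- data.frame(planted = y + rnorm(n, sd = 0.4), noise1 = rnorm(n),
                  noise2 = rnorm(n))
  rep1 <- importance_stability(x, y, n_models = 4, train_pos = 60,
                               train_neg = 60, test_pos = 30, test_neg = 30,
                               seed = 9, ntree = 40)
  rep2 <- importance_stability(x, y, n_models = 4, train_pos = 60,
                               train_neg = 60, test_pos = 30, test_neg = 30,
                               seed = 9, ntree = 40)
  expect_identical(rep1$importance, rep2$importance)
  expect_identical(rep1$f1, rep2$f1)
  expect_length(rep1$f1, 4L)
  imp <- rep1$importance
  planted_mean <- imp$mean_mda[imp$feature == "planted"]
  expect_gt(planted_mean, max(imp$mean_mda[imp$feature != "planted"]))
  # unassociated features fluctuate little relative to the planted mean
  expect_lt(max(imp$sd_mda[imp$feature != "planted"]), planted_mean)
  expect_error(importance_stability(x, y, n_models = 2, train_pos = 1000,
                                    train_neg = 10, test_pos = 5, test_neg = 5,
                                    seed = 1),
               "not enough")
})
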