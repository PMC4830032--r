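#' Model specification for the binary classifiers
#'
#' @param algorithm `"rf"` (random forest) or `"svm"` (RBF-kernel SVM).
#' @param ntree number of trees for rf (default 500, satisfactory in most
#'   cases).
#' @param mtry_grid grid of candidate `mtry` values for rf; the value with
#'   minimal out-of-bag error wins. Default: `floor(sqrt(p))` scaled by
#'   1/2, 1 and 2 at training time.
#' @param cost_grid,lambda_grid grids for the SVM cost C and kernel width
#'   lambda; logarithmic defaults (`2^(-2..6)`, `2^(-8..2)`) since only the
#'   optima, not the grids, are conventionally reported.
#' @param cv_folds cross-validation folds for the SVM grid search
#'   (default 10); rf needs none thanks to the OOB estimate.
#' @param seed integer seed driving bootstraps, fold assignment and
#'   tie-breaking.
#' @return A `model_spec` list.
#' @export
model_spec <- function(algorithm = c("rf", "svm"), ntree = 500L,
                       mtry_grid = NULL, cost_grid = 2^(-2:6),
                       lambda_grid = 2^(-8:2), cv_folds = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(ntree >= 1, length(cost_grid) > 0, length(lambda_grid) > 0,
            cv_folds >= 2)
  structure(list(algorithm = algorithm, ntree = as.integer(ntree),
                 mtry_grid = mtry_grid, cost_grid = cost_grid,
                 lambda_grid = lambda_grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a binary classifier on a feature table
#'
#' For `"rf"`, the `mtry` tuning parameter is chosen by grid search on the
#' out-of-bag error (an unbiased internal estimate, so no cross-validation
#' is run). For `"svm"`, the cost C and kernel width lambda are chosen by
#' grid search maximizing mean F1 over `cv_folds`-fold cross-validation;
#' features are z-scored inside the SVM using training statistics. Both
#' routes are fully seeded.
#'
#' @param features a `feature_table` (pair columns ignored) or numeric
#'   matrix.
#' @param labels vector of labels aligned with the feature rows.
#' @param spec a [model_spec()].
#' @return A `trained_model`: algorithm, chosen hyperparameters, the fitted
#'   model, and the training feature column order.
#' @export
train_model <- function(features, labels, spec = model_spec()) {
  x <- feature_matrix(features)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(x))
    stop("labels do not align with feature rows", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels must cover both classes", call. = FALSE)
  if (anyNA(x)) stop("NaN/NA in feature matrix", call. = FALSE)

  if (spec$algorithm == "rf") {
    grid <- spec$mtry_grid
    if (is.null(grid)) {
      base <- max(1L, floor(sqrt(ncol(x))))
      grid <- sort(unique(pmin(ncol(x), pmax(1L, c(base %/% 2L, base, 2L * base)))))
    }
    fits <- lapply(grid, function(m)
      rf_fit(x, y, ntree = spec$ntree, mtry = m, seed = spec$seed))
    oob <- vapply(fits, function(f) f$oob_error, 0)
    best <- which.min(oob)
    model <- fits[[best]]
    params <- list(mtry = grid[best], ntree = spec$ntree,
                   oob_grid = stats::setNames(oob, grid))
  } else {
    grid <- expand.grid(cost = spec$cost_grid, lambda = spec$lambda_grid)
    set.seed(spec$seed)
    folds <- sample(rep_len(seq_len(spec$cv_folds), nrow(x)))
    cv_f1 <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(spec$cv_folds), function(k) {
        tr <- folds != k
        if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
        fit <- svm_fit(x[tr, , drop = FALSE], y[tr],
                       cost = grid$cost[g], lambda = grid$lambda[g])
        p <- predict(fit, x[!tr, , drop = FALSE])
        suppressWarnings(f1_score(confusion_counts(p, y[!tr])))
      }, 0), na.rm = TRUE)
    }, 0)
    best <- which.max(cv_f1)
    model <- svm_fit(x, y, cost = grid$cost[best], lambda = grid$lambda[best])
    params <- list(cost = grid$cost[best], lambda = grid$lambda[best],
                   cv_f1 = cv_f1[best])
  }
  structure(list(algorithm = spec$algorithm, model = model, params = params,
                 feature_names = colnames(x), spec = spec),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", x$algorithm, ": ",
      paste(names(x$params)[1:2], unlist(x$params[1:2]), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predicted probability of the positive class
#'
#' Random forests report the ensemble vote fraction; SVMs report the
#' Platt-scaled decision value.
#'
#' @param model a `trained_model` (or a bare `dti_rf` / `dti_svm`).
#' @param features feature table or matrix with the training columns.
#' @return Numeric vector in `[0, 1]`, one value per row.
#' @export
predict_proba <- function(model, features) {
  x <- feature_matrix(features)
  if (inherits(model, "trained_model")) model <- model$model
  predict(model, x)
}

#' Evaluate a trained model on labeled pairs
#'
#' @param model a `trained_model`.
#' @param features feature table/matrix of the evaluation pairs.
#' @param labels their true labels.
#' @param threshold probability cutoff for the confusion counts and F1
#'   (default 0.5).
#' @param alpha BEDROC early-recognition parameter (default 20).
#' @param auc_method passed to [roc_pr_curves()].
#' @return An `eval_report`: confusion counts, `f1`, `roc`/`pr` points,
#'   `auc_roc`, `auc_pr`, `bedroc`, plus the settings used.
#' @export
evaluate_model <- function(model, features, labels, threshold = 0.5,
                           alpha = 20.0, auc_method = "trapezoid") {
  scores <- predict_proba(model, features)
  cc <- confusion_counts(scores, labels, threshold)
  curves <- roc_pr_curves(scores, labels, auc_method)
  structure(list(confusion = cc, f1 = suppressWarnings(f1_score(cc)),
                 roc = curves$roc, pr = curves$pr,
                 auc_roc = curves$auc_roc, auc_pr = curves$auc_pr,
                 bedroc = bedroc(scores, labels, alpha = alpha),
                 alpha = alpha, threshold = threshold,
                 auc_method = curves$auc_method, scores = scores),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> F1 %.3f | AUCROC %.3f | AUCPR %.3f | ",
                     "BEDROC(%.0f) %.3f  [AUC: %s]\n"),
              x$f1, x$auc_roc, x$auc_pr, x$alpha, x$bedroc, x$auc_method))
  cc <- x$confusion
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d @ threshold %.2f\n",
              cc$TP, cc$FP, cc$FN, cc$TN, x$threshold))
  invisible(x)
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- feature_columns(features)
    if (length(cols) == 0L)
      cols <- names(features)[vapply(features, is.numeric, TRUE)]
    x <- as.matrix(features[, cols, drop = FALSE])
  } else {
    x <- as.matrix(features)
  }
  storage.mode(x) <- "double"
  x
}
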