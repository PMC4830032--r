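#' Fit a random forest binary classifier
#'
#' A compiled implementation of the classic bagged-CART ensemble: each of
#' `ntree` trees is grown without pruning from a bootstrap sample, choosing
#' at every node the best Gini split among `mtry` randomly drawn features.
#' The out-of-bag (OOB) samples give an internal generalization estimate
#' (no cross-validation needed), an OOB permutation importance per feature
#' (mean decrease in accuracy, MDA) and the accumulated impurity decrease
#' (mean decrease in Gini, MDG).
#'
#' @param x numeric matrix or data.frame of features (rows = pairs).
#' @param y labels: logical, 0/1, or factor/character with levels
#'   `"negative"` < `"positive"`.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param min_node minimum node size to attempt a split on (default 1:
#'   grow to purity).
#' @param importance compute OOB permutation importance (default `TRUE`).
#' @param seed optional integer; when given, `set.seed(seed)` is applied so
#'   the fit is reproducible.
#' @return An object of class `dti_rf`: trees, `oob_error`, `mda`, `mda_sd`,
#'   `mdg` (named by feature), `feature_names`, `ntree`, `mtry`.
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = NULL, min_node = 1L,
                   importance = TRUE, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L)
    stop("training labels must cover both classes", call. = FALSE)
  if (anyNA(x)) stop("NaN/NA in feature matrix", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- rf_train_cpp(x, as.integer(y), as.integer(ntree), as.integer(mtry),
                      as.integer(min_node), isTRUE(importance))
  names(fit$mda) <- names(fit$mda_sd) <- names(fit$mdg) <- colnames(x)
  fit$feature_names <- colnames(x)
  class(fit) <- "dti_rf"
  fit
}

#' @export
print.dti_rf <- function(x, ...) {
  cat("<dti_rf> ", x$ntree, " trees, mtry ", x$mtry,
      ", OOB error ", signif(x$oob_error, 4), "\n", sep = "")
  invisible(x)
}

#' Positive-class vote fraction of a random forest
#'
#' @param object a `dti_rf`.
#' @param newdata feature matrix/data.frame with the training columns (order
#'   is checked by name when names are available).
#' @param ... unused.
#' @return Numeric vector in `[0, 1]`: the fraction of trees voting positive.
#' @export
predict.dti_rf <- function(object, newdata, ...) {
  newdata <- align_feature_matrix(newdata, object$feature_names)
  if (nrow(newdata) == 0L) return(numeric(0))
  rf_predict_cpp(object$trees, newdata)
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("positive", "negative")))
      stop("character labels must be 'positive'/'negative'", call. = FALSE)
    return(as.integer(y == "positive"))
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("numeric labels must be 0/1", call. = FALSE)
  y
}

align_feature_matrix <- function(x, feature_names) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x)) && !is.null(feature_names)) {
    if (!all(feature_names %in% colnames(x)))
      stop("feature columns missing at prediction time: ",
           paste(utils::head(setdiff(feature_names, colnames(x)), 5),
                 collapse = ", "), call. = FALSE)
    x <- x[, feature_names, drop = FALSE]
  } else if (!is.null(feature_names) && ncol(x) != length(feature_names)) {
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         length(feature_names), call. = FALSE)
  }
  x
}
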