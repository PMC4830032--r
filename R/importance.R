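#' Permutation feature importance (mean decrease in accuracy)
#'
#' For each feature, its values are permuted across all evaluated pairs and
#' the drop in classification accuracy (at the 0.5 threshold) is averaged
#' over `n_repeats` seeded permutations. For random forests the report also
#' carries the model's internal importance bookkeeping: the out-of-bag MDA
#' collected during training and the mean decrease in Gini impurity (MDG).
#' Requesting MDG for an SVM is an error, since only tree ensembles track
#' impurity.
#'
#' @param model a `trained_model` (rf or svm).
#' @param features feature table/matrix to permute.
#' @param labels true labels for the accuracy measurements.
#' @param n_repeats permutations per feature (default 5).
#' @param seed integer seed.
#' @param include_mdg attach the rf's Gini importance (default: yes for rf).
#' @return An `importance_report` data.frame: `feature`, `mda`, `mda_sd`,
#'   and for rf `oob_mda`, `mdg`.
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 5L,
                                   seed = 1L,
                                   include_mdg = NULL) {
  stopifnot(n_repeats >= 1)
  x <- feature_matrix(features)
  y <- as_binary_labels(labels)
  algorithm <- if (inherits(model, "trained_model")) model$algorithm
               else if (inherits(model, "dti_rf")) "rf" else "svm"
  if (is.null(include_mdg)) include_mdg <- algorithm == "rf"
  if (include_mdg && algorithm != "rf")
    stop("mean decrease in Gini is only defined for random forests",
         call. = FALSE)

  acc <- function(m) mean((predict_proba(model, m) >= 0.5) == y)
  acc0 <- acc(x)
  set.seed(as.integer(seed))
  p <- ncol(x)
  drops <- matrix(0, n_repeats, p)
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(p)) {
      xp <- x
      xp[, f] <- x[sample.int(nrow(x)), f]
      drops[r, f] <- acc0 - acc(xp)
    }
  }
  rep <- data.frame(feature = colnames(x),
                    mda = colMeans(drops),
                    mda_sd = apply(drops, 2, stats::sd),
                    stringsAsFactors = FALSE)
  if (include_mdg) {
    fit <- if (inherits(model, "trained_model")) model$model else model
    rep$oob_mda <- fit$mda[colnames(x)]
    rep$mdg <- fit$mdg[colnames(x)]
  }
  class(rep) <- c("importance_report", "data.frame")
  rep
}

#' Stability of feature importance across replicate models
#'
#' Re-trains many random forests on small randomly drawn training sets and
#' records each model's out-of-bag permutation importance vector and its F1
#' on a disjoint randomly drawn test set, quantifying how much feature
#' rankings move with the training data. Defaults mirror the reference
#' experiment: 1,000 replicate models, 100 positive + 100 negative training
#' pairs, 50 + 50 disjoint test pairs each.
#'
#' Each replicate derives its own seed from `seed`, so any subset of
#' replicates can be regenerated independently.
#'
#' @param features feature table/matrix of the labeled pair pool.
#' @param labels their labels.
#' @param n_models replicate models (default 1000).
#' @param train_pos,train_neg,test_pos,test_neg per-replicate sample sizes.
#' @param seed integer master seed.
#' @param ntree,mtry forest size per replicate (`ntree` defaults to 500; use
#'   fewer for quick experiments).
#' @return A `stability_report`: `importance` (data.frame of per-feature
#'   mean/sd of MDA across replicates), `f1` (per-replicate test F1),
#'   `f1_range`, and the sampling settings.
#' @export
importance_stability <- function(features, labels, n_models = 1000L,
                                 train_pos = 100L, train_neg = 100L,
                                 test_pos = 50L, test_neg = 50L,
                                 seed = 1L, ntree = 500L, mtry = NULL) {
  x <- feature_matrix(features)
  y <- as_binary_labels(labels)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) < train_pos + test_pos || length(neg) < train_neg + test_neg)
    stop("not enough labeled pairs for disjoint train/test draws",
         call. = FALSE)

  p <- ncol(x)
  imp_sum <- numeric(p); imp_sq <- numeric(p)
  f1s <- numeric(n_models)
  for (r in seq_len(n_models)) {
    set.seed(derive_seed(seed, r))
    pos_draw <- sample(pos, train_pos + test_pos)
    neg_draw <- sample(neg, train_neg + test_neg)
    tr <- c(pos_draw[seq_len(train_pos)], neg_draw[seq_len(train_neg)])
    te <- c(pos_draw[train_pos + seq_len(test_pos)],
            neg_draw[train_neg + seq_len(test_neg)])
    fit <- rf_fit(x[tr, , drop = FALSE], y[tr], ntree = ntree, mtry = mtry,
                  seed = derive_seed(seed, r, 1L))
    imp_sum <- imp_sum + fit$mda
    imp_sq <- imp_sq + fit$mda^2
    f1s[r] <- suppressWarnings(
      f1_score(confusion_counts(predict(fit, x[te, , drop = FALSE]), y[te])))
  }
  mean_imp <- imp_sum / n_models
  var_imp <- pmax(0, imp_sq / n_models - mean_imp^2) * n_models /
    max(1, n_models - 1)
  structure(list(
    importance = data.frame(feature = colnames(x), mean_mda = mean_imp,
                            sd_mda = sqrt(var_imp), stringsAsFactors = FALSE),
    f1 = f1s, f1_range = range(f1s),
    settings = list(n_models = n_models, train_pos = train_pos,
                    train_neg = train_neg, test_pos = test_pos,
                    test_neg = test_neg, seed = seed, ntree = ntree)),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  s <- x$settings
  cat("<stability_report> ", s$n_models, " models; F1 range [",
      sprintf("%.3f", x$f1_range[1]), ", ", sprintf("%.3f", x$f1_range[2]),
      "]\n", sep = "")
  top <- x$importance[order(-x$importance$mean_mda), ][1:min(5, nrow(x$importance)), ]
  cat("top features by mean MDA:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

# derive a stage seed from a master seed; kept below 2^31
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 48271 + i * 1009 + j * 65537) %% 2147483629) + 1L
}
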