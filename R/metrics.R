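#' Confusion counts at a probability threshold
#'
#' @param scores predicted positive-class probabilities.
#' @param labels true labels (as in [rf_fit()]).
#' @param threshold classification cutoff (default 0.5).
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
                 FN = sum(pred == 0 & y == 1), TN = sum(pred == 0 & y == 0)),
            class = "confusion_counts")
}

#' F1 score from confusion counts
#'
#' The harmonic mean of precision and recall, computed directly as
#' `2*TP / (2*TP + FP + FN)`. When that denominator is zero (no positives
#' anywhere) the score is defined as 0 with a warning.
#'
#' @param cc a `confusion_counts`, or the TP count if `FP`/`FN` are given.
#' @param FP,FN false positive / false negative counts (when `cc` is TP).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(cc, FP = NULL, FN = NULL) {
  if (!inherits(cc, "confusion_counts"))
    cc <- structure(list(TP = cc, FP = FP, FN = FN), class = "confusion_counts")
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) {
    warning("F1 undefined (no positives predicted or present); returning 0",
            call. = FALSE)
    return(0)
  }
  2 * cc$TP / denom
}

#' ROC and precision-recall curves with AUCs
#'
#' Sweeps the threshold over the unique scores (ties grouped), producing the
#' ROC polygon and PR points plus their areas. The default ROC area is the
#' trapezoidal integral, which equals the Mann-Whitney statistic with ties
#' counted 1/2. `auc_method = "spline"` instead integrates a natural cubic
#' spline through the curve points; reports should name the mode, since the
#' two differ slightly on coarse curves. AUCPR uses the same integration over
#' the recall grid (the PR point at recall 0 takes the precision of the
#' highest-score group).
#'
#' @param scores predicted probabilities or arbitrary ranking scores.
#' @param labels true labels; both classes must be present.
#' @param auc_method `"trapezoid"` (default) or `"spline"`.
#' @return List with `roc` (data.frame fpr/tpr), `pr` (recall/precision),
#'   `auc_roc`, `auc_pr`, `auc_method`.
#' @export
roc_pr_curves <- function(scores, labels, auc_method = c("trapezoid", "spline")) {
  auc_method <- match.arg(auc_method)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("both classes required to compute ROC/PR curves", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y)[grp_last]
  n_seen <- grp_last
  fp <- n_seen - tp
  P <- sum(y)
  N <- length(y) - P

  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  pr <- data.frame(recall = tp / P, precision = tp / n_seen)
  pr <- rbind(data.frame(recall = 0, precision = pr$precision[1L]), pr)

  integrate_curve <- function(x, y) {
    if (auc_method == "trapezoid")
      return(sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
    keep <- !duplicated(x)  # spline needs strictly increasing x
    if (sum(keep) < 4)
      return(sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
    f <- stats::splinefun(x[keep], y[keep], method = "natural")
    stats::integrate(f, min(x), max(x), subdivisions = 1000L)$value
  }
  list(roc = roc, pr = pr,
       auc_roc = integrate_curve(roc$fpr, roc$tpr),
       auc_pr = integrate_curve(pr$recall, pr$precision),
       auc_method = auc_method)
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Early-recognition metric: actives found near the top of the ranked list
#' are weighted exponentially more than late ones. With `n` actives among
#' `N` scored pairs, 1-based descending-score ranks `r_i` of the actives, and
#' `Ra = n/N`:
#' \deqn{RIE = \frac{\sum_i e^{-\alpha r_i / N}}
#'                  {\frac{n}{N}\,\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}
#' \deqn{BEDROC = RIE \cdot
#'   \frac{Ra \,\sinh(\alpha/2)}{\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha Ra)}
#'   + \frac{1}{1 - e^{\alpha (1 - Ra)}}}
#' Ties are broken by a seeded random shuffle; path-count features produce
#' heavily tied scores at 0, so the tie policy matters and is reported
#' explicitly here.
#'
#' @param scores ranking scores (higher = more likely active).
#' @param labels true labels.
#' @param alpha early-recognition weight (default 20: the top ~8% of the
#'   list contributes ~80% of the score).
#' @param tie_seed integer seed for the tie-breaking shuffle.
#' @return BEDROC in `[0, 1]`.
#' @export
bedroc <- function(scores, labels, alpha = 20.0, tie_seed = 1L) {
  stopifnot(alpha > 0)
  y <- as_binary_labels(labels)
  N <- length(y)
  n <- sum(y)
  if (n == 0L || n == N)
    stop("BEDROC needs both actives and inactives", call. = FALSE)
  set.seed(as.integer(tie_seed))
  ord <- order(-scores, sample.int(N))
  r <- which(y[ord] == 1L)

  Ra <- n / N
  rie <- sum(exp(-alpha * r / N)) /
    (n * (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}
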