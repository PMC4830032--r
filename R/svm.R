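#' Fit a soft-margin RBF-kernel SVM (dual QP)
#'
#' Solves the dual quadratic program of the C-SVM with Gaussian kernel
#' `K(u, v) = exp(-lambda * ||u - v||^2)` using `quadprog` (a small ridge is
#' added to the kernel for numerical positive-definiteness). Features are
#' z-scored with training statistics stored in the model. Class probabilities
#' come from Platt scaling: a logistic fit of the labels on the decision
#' values. The dense QP limits this implementation to a few thousand
#' training pairs, which covers the package's intended (synthetic-scale) use.
#'
#' @param x numeric feature matrix/data.frame.
#' @param y labels as in [rf_fit()].
#' @param cost soft-margin cost C.
#' @param lambda RBF kernel width (the gamma of the Gaussian form).
#' @return A `dti_svm` with support-vector coefficients, intercept, scaling
#'   statistics and Platt coefficients.
#' @export
svm_fit <- function(x, y, cost = 1, lambda = 0.1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y01 <- as_binary_labels(y)
  if (length(unique(y01)) < 2L)
    stop("training labels must cover both classes", call. = FALSE)
  if (anyNA(x)) stop("NaN/NA in feature matrix", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  n <- nrow(xs)
  ys <- ifelse(y01 == 1, 1, -1)

  K <- rbf_kernel(xs, xs, lambda)
  Dmat <- (ys %o% ys) * K + diag(1e-8, n)
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)

  sv <- alpha > 1e-6
  coefs <- alpha[sv] * ys[sv]
  margin <- sv & alpha < cost - 1e-6
  f_no_b <- as.numeric(K[, sv, drop = FALSE] %*% coefs)
  b <- if (any(margin)) mean(ys[margin] - f_no_b[margin])
       else mean(ys[sv] - f_no_b[sv])
  dec <- f_no_b + b

  # Platt scaling on training decision values; separable data saturates the
  # logistic fit, which is expected and harmless (plogis just clips)
  platt <- suppressWarnings(
    stats::glm.fit(cbind(1, dec), y01,
                   family = stats::binomial())$coefficients)

  structure(list(sv = xs[sv, , drop = FALSE], coefs = coefs, b = b,
                 lambda = lambda, cost = cost, center = ctr, scale = scl,
                 platt = platt, feature_names = colnames(x)),
            class = "dti_svm")
}

rbf_kernel <- function(a, b, lambda) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-lambda * d2)
}

svm_decision <- function(object, newdata) {
  x <- align_feature_matrix(newdata, object$feature_names)
  xs <- scale(x, center = object$center, scale = object$scale)
  as.numeric(rbf_kernel(xs, object$sv, object$lambda) %*% object$coefs) +
    object$b
}

#' Positive-class probability of an RBF SVM (Platt-scaled decision values)
#'
#' @param object a `dti_svm`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Numeric vector in `[0, 1]`.
#' @export
predict.dti_svm <- function(object, newdata, ...) {
  if (NROW(newdata) == 0L) return(numeric(0))
  dec <- svm_decision(object, newdata)
  stats::plogis(object$platt[1] + object$platt[2] * dec)
}

#' @export
print.dti_svm <- function(x, ...) {
  cat("<dti_svm> RBF kernel, C = ", x$cost, ", lambda = ", x$lambda,
      ", ", nrow(x$sv), " support vectors\n", sep = "")
  invisible(x)
}
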