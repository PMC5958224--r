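# Linear maximum-margin classifier (L2-regularized L1-loss SVM), solved by
# dual coordinate descent (Hsieh et al. 2008, the LIBLINEAR algorithm).
# Deterministic: cyclic coordinate order, no randomization.

#' Fit a linear maximum-margin classifier
#'
#' Solves `min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w . x_i)` in the dual
#' with coordinate descent. The bias is handled by augmenting features with
#' a constant term. Labels may be any two distinct values; internally the
#' first sorted level maps to -1.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Labels, length `nrow(x)`, exactly two distinct values.
#' @param C Soft-margin cost (default 1).
#' @param max_passes Maximum full passes over the data.
#' @param tol Convergence tolerance on the projected gradient spread.
#' @return An object of class `linear_svm`: weights `w`, bias `b`, the label
#'   `levels` (levels\[1\] = negative class), and `C`.
#' @export
linear_svm <- function(x, y, C = 1, max_passes = 1000, tol = 1e-8) {
  x <- as.matrix(x)
  lev <- sort(unique(y))
  if (length(lev) != 2) stopf("need exactly two classes, got %d",
                              length(lev))
  yy <- ifelse(y == lev[2], 1, -1)
  n <- nrow(x)
  xa <- cbind(x, 1)  # bias term
  d <- ncol(xa)
  qii <- rowSums(xa^2)
  alpha <- numeric(n)
  w <- numeric(d)
  for (pass in seq_len(max_passes)) {
    pg_max <- -Inf; pg_min <- Inf
    for (i in seq_len(n)) {
      g <- yy[i] * sum(w * xa[i, ]) - 1
      pg <- g
      if (alpha[i] == 0) pg <- min(g, 0)
      if (alpha[i] == C) pg <- max(g, 0)
      if (pg != 0) {
        pg_max <- max(pg_max, pg); pg_min <- min(pg_min, pg)
        a_old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - g / qii[i], 0), C)
        w <- w + (alpha[i] - a_old) * yy[i] * xa[i, ]
      }
    }
    if (!is.finite(pg_max) || pg_max - pg_min < tol) break
  }
  structure(list(w = w[-d], b = w[d], levels = lev, C = C),
            class = "linear_svm")
}

#' Predict with a linear maximum-margin classifier
#'
#' @param object A [linear_svm()] fit.
#' @param newdata Numeric matrix, samples x features.
#' @param ... Unused.
#' @return Vector of predicted labels (the fit's `levels`).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w + object$b
  ifelse(score >= 0, object$levels[2], object$levels[1])
}
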