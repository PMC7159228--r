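#' Fit a soft-margin support vector machine
#'
#' Trains a two-class SVM by dual coordinate descent. The linear kernel
#' (default) solves the primal-equivalent dual of the L2-regularized hinge
#' loss and exposes the weight vector, which downstream recursive feature
#' elimination uses as its importance score. An RBF kernel is available for
#' prediction-only use cases; its feature importances are obtained by
#' permutation instead of weights.
#'
#' Class probabilities come from Platt sigmoid scaling fitted on the
#' training decision values: `P(positive | f) = 1 / (1 + exp(A f + B))`.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param y labels; coerced so that `positive_level` maps to +1.
#' @param cost positive error-penalty parameter (the paper-style `cost`).
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma RBF bandwidth; defaults to `1/ncol(x)`.
#' @param class_weights optional named vector (names = class labels) of
#'   multiplicative weights on `cost`, e.g. inverse class frequencies.
#' @param positive_level which level of `y` is the positive class; defaults
#'   to the lexicographically larger level (so 1 beats 0, "pos" beats "neg").
#' @param max_passes,tol optimizer controls.
#' @return an object of class `dili_svm` with `predict()` support.
#' @export
svm_fit <- function(x, y, cost = 1, kernel = c("linear", "rbf"),
                    gamma = NULL, class_weights = NULL,
                    positive_level = NULL, max_passes = 2000, tol = 1e-4) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.numeric(cost) || cost <= 0) stop("`cost` must be positive")
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("svm_fit requires exactly two classes")
  if (is.null(positive_level)) positive_level <- lev[2]
  if (!positive_level %in% lev) stop("positive_level not found in y")
  yy <- ifelse(y == positive_level, 1, -1)

  Ci <- rep(cost, nrow(x))
  if (!is.null(class_weights)) {
    if (is.null(names(class_weights)) || !all(lev %in% names(class_weights)))
      stop("class_weights must be named with the class labels")
    Ci <- cost * unname(class_weights[y])
  }

  if (kernel == "linear") {
    xa <- cbind(x, `(bias)` = 1)
    fit <- svm_dcd_linear(xa, yy, Ci, max_passes, tol)
    w <- as.numeric(fit$w)
    p <- ncol(x)
    obj <- list(kernel = "linear", w = setNames(w[seq_len(p)], colnames(x)),
                b = w[p + 1L], alpha = as.numeric(fit$alpha),
                cost = cost, gamma = NULL,
                positive_level = positive_level, levels = lev,
                features = colnames(x))
    f <- drop(x %*% obj$w) + obj$b
  } else {
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    K <- rbf_kernel(x, x, gamma)
    fit <- svm_dcd_kernel(K, yy, Ci, max_passes, tol)
    alpha <- as.numeric(fit$alpha)
    sv <- which(alpha > 1e-12)
    # bias from KKT midpoint of free support vectors (fallback: all SVs)
    f0 <- as.numeric(fit$f)
    free <- sv[alpha[sv] < Ci[sv] - 1e-12]
    idx <- if (length(free)) free else sv
    b <- mean(yy[idx] - f0[idx])
    obj <- list(kernel = "rbf", sv_x = x[sv, , drop = FALSE],
                sv_coef = alpha[sv] * yy[sv], b = b,
                cost = cost, gamma = gamma,
                positive_level = positive_level, levels = lev,
                features = colnames(x))
    f <- f0 + b
  }
  obj$platt <- platt_scale(f, yy)
  class(obj) <- "dili_svm"
  obj
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Platt (1999) sigmoid fit with the Lin-Weng-Keerthi (2007) stabilized
# Newton iteration; targets are the usual smoothed class frequencies.
platt_scale <- function(f, yy, max_iter = 100) {
  n_pos <- sum(yy > 0); n_neg <- sum(yy < 0)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(yy > 0, hi, lo)
  A <- 0; B <- log((n_neg + 1) / (n_pos + 1))
  nll <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- nll(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g <- c(sum(f * d1), sum(d1))
    if (max(abs(g)) < 1e-10) break
    H <- matrix(c(sum(f * f * d2), sum(f * d2), sum(f * d2), sum(d2)), 2) +
      diag(1e-12, 2)
    step <- solve(H, g)  # descent direction is -step
    stepsize <- 1
    repeat {
      A2 <- A - stepsize * step[1]; B2 <- B - stepsize * step[2]
      v2 <- nll(A2, B2)
      if (v2 < val - 1e-4 * stepsize * sum(g * step)) {
        A <- A2; B <- B2; val <- v2; break
      }
      stepsize <- stepsize / 2
      if (stepsize < 1e-10) break
    }
    if (stepsize < 1e-10) break
  }
  c(A = A, B = B)
}

#' Decision values and class probabilities from a fitted SVM
#'
#' @param object a `dili_svm` fit.
#' @param newdata numeric matrix with the same feature columns as training.
#' @param type `"probability"` (Platt-scaled, default) or `"decision"`.
#' @param ... unused.
#' @return numeric vector, one value per row of `newdata`.
#' @export
predict.dili_svm <- function(object, newdata,
                             type = c("probability", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(newdata)))
      stop("newdata is missing model features")
    newdata <- newdata[, object$features, drop = FALSE]
  }
  f <- if (object$kernel == "linear") {
    drop(newdata %*% object$w) + object$b
  } else {
    drop(rbf_kernel(newdata, object$sv_x, object$gamma) %*% object$sv_coef) +
      object$b
  }
  if (type == "decision") return(f)
  z <- object$platt["A"] * f + object$platt["B"]
  unname(1 / (1 + exp(z)))
}

#' @export
print.dili_svm <- function(x, ...) {
  cat("Two-class SVM (", x$kernel, " kernel), cost = ", x$cost, "\n", sep = "")
  if (x$kernel == "linear")
    cat("  features:", length(x$w), " bias:", signif(x$b, 4), "\n")
  else
    cat("  support vectors:", nrow(x$sv_x), " gamma:", signif(x$gamma, 4), "\n")
  cat("  positive class:", x$positive_level, "\n")
  invisible(x)
}
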