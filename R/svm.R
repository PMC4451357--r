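# Soft-margin kernel SVM trained by sequential minimal optimization (SMO).
#
# Kernels:
#   linear   k(x, y) = x'y
#   rbf      k(x, y) = exp(-||x - y||^2 / sigma^2)   (denominator sigma^2)
#   pol      k(x, y) = (x'y + c)^d
#
# The dual problem max_a sum(a) - 1/2 a' (yy' * K) a, 0 <= a <= C,
# sum(a_i y_i) = 0 is solved with the simplified SMO scheme: sweep over
# multipliers violating the KKT conditions, pair each with a second index
# (seeded-random choice), solve the 2-variable subproblem analytically, and
# stop when a full sweep produces no updates.

#' Kernel specification
#'
#' @param kind `"linear"`, `"rbf"` or `"pol"`.
#' @param C soft-margin penalty (> 0).
#' @param sigma RBF length scale; the kernel is `exp(-||x-y||^2 / sigma^2)`.
#' @param degree,offset polynomial degree `d` (integer >= 1) and additive
#'   offset `c` (>= 0) of `(x'y + c)^d`.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf", "pol"), C = 1,
                        sigma = 1, degree = 3L, offset = 1) {
  kind <- match.arg(kind)
  check_scalar_number(C, "C", lower = 1e-12)
  check_scalar_number(sigma, "sigma", lower = 1e-12)
  check_scalar_number(degree, "degree", lower = 1, integer = TRUE)
  check_scalar_number(offset, "offset", lower = 0)
  structure(list(kind = kind, C = C, sigma = sigma,
                 degree = as.integer(degree), offset = offset),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$kind,
                  linear = "",
                  rbf = sprintf(", sigma = %.4g", x$sigma),
                  pol = sprintf(", degree = %d, offset = %.4g", x$degree, x$offset))
  cat(sprintf("kernel_spec: %s (C = %.4g%s)\n", x$kind, x$C, extra))
  invisible(x)
}

#' Evaluate a kernel on two vectors
#'
#' @param spec a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, y) {
  if (length(x) != length(y)) stop_eb("kernel arguments differ in dimension")
  switch(spec$kind,
         linear = sum(x * y),
         rbf = exp(-sum((x - y)^2) / spec$sigma^2),
         pol = (sum(x * y) + spec$offset)^spec$degree)
}

#' Kernel (Gram) matrix between two point sets
#'
#' @param spec a [kernel_spec()].
#' @param X n x p matrix; rows are points.
#' @param Y optional m x p matrix (defaults to `X`).
#' @return n x m Gram matrix.
#' @export
kernel_matrix <- function(spec, X, Y = NULL) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop_eb("kernel arguments differ in dimension")
  G <- tcrossprod(X, Y)
  switch(spec$kind,
         linear = G,
         pol = (G + spec$offset)^spec$degree,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * G
           d2[d2 < 0] <- 0
           exp(-d2 / spec$sigma^2)
         })
}

#' Train a soft-margin kernel SVM by SMO
#'
#' Labels use the pipeline convention 1 = AD (positive class), 0 = NC.
#' Features may optionally be standardized by their training statistics
#' (recommended: kernel SVMs are scale sensitive); the statistics are stored
#' in the model and applied at prediction time.
#'
#' @param x N x p feature matrix (finite values).
#' @param y 0/1 labels, both classes present.
#' @param spec a [kernel_spec()].
#' @param tol KKT violation tolerance.
#' @param max_passes sweeps without progress before stopping.
#' @param max_iter hard cap on sweeps.
#' @param scale standardize columns by training mean/SD (default TRUE).
#' @param seed seed for SMO's random partner choice (default 0;
#'   deterministic).
#' @return an `eb_svm` model: support vectors, dual coefficients
#'   `alpha_y = alpha * y`, bias `b`, the kernel spec, scaling stats.
#' @export
train_svm_smo <- function(x, y, spec = kernel_spec(), tol = 1e-3,
                          max_passes = 10L, max_iter = 2000L,
                          scale = TRUE, seed = 0L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_eb("non-finite feature values")
  y <- as.integer(y)
  if (length(y) != nrow(x) || !all(y %in% c(0L, 1L)))
    stop_eb("y must be one 0/1 label per row of x")
  if (length(unique(y)) < 2L) stop_eb("both classes must be present")

  center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (scale) {
    center <- colMeans(x)
    scl <- col_sds(x)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scl, `/`)
  }

  n <- nrow(x)
  ys <- ifelse(y == 1L, 1, -1)
  C <- spec$C
  K <- kernel_matrix(spec, x)

  restore <- push_seed(seed)
  on.exit(restore())

  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L

  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * ys) + b - ys[i]
      if ((ys[i] * Ei < -tol && alpha[i] < C) ||
          (ys[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        Ej <- sum(K[j, ] * alpha * ys) + b - ys[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (ys[i] != ys[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - ys[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + ys[i] * ys[j] * (aj_old - aj)
        b1 <- b - Ei - ys[i] * (ai - ai_old) * K[i, i] -
          ys[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - ys[i] * (ai - ai_old) * K[i, j] -
          ys[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iter <- iter + 1L
  }

  sv <- alpha > 1e-8
  structure(
    list(sv_x = x[sv, , drop = FALSE], sv_alpha_y = (alpha * ys)[sv],
         sv_y = y[sv], alpha = alpha, b = b, spec = spec,
         center = center, scale = scl, scaled = scale,
         n_train = n, iterations = iter,
         dual_objective = sum(alpha) -
           0.5 * sum((alpha * ys) * (K %*% (alpha * ys)))),
    class = "eb_svm"
  )
}

#' @export
print.eb_svm <- function(x, ...) {
  cat(sprintf("eb_svm: %s kernel, %d support vectors of %d points, b = %.4g\n",
              x$spec$kind, nrow(x$sv_x), x$n_train, x$b))
  invisible(x)
}

#' Decision values of a trained SVM
#'
#' @param model an `eb_svm`.
#' @param x feature matrix in the original (unscaled) space.
#' @return numeric vector `sum_i alpha_i y_i k(x_i, x) + b`.
#' @export
decision_values <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop_eb("feature dimension mismatch: model expects ", length(model$center))
  if (model$scaled)
    x <- sweep(sweep(x, 2L, model$center), 2L, model$scale, `/`)
  if (nrow(model$sv_x) == 0L) return(rep(model$b, nrow(x)))
  as.vector(kernel_matrix(model$spec, x, model$sv_x) %*% model$sv_alpha_y) +
    model$b
}

#' Predict class labels (1 = AD, 0 = NC)
#'
#' @param object an `eb_svm` model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return integer 0/1 labels; nonnegative decision values map to 1 (AD).
#' @export
predict.eb_svm <- function(object, newdata, ...) {
  as.integer(decision_values(object, newdata) >= 0)
}
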