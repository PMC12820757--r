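# pairwise L1 and squared-L2 cross-distance helpers (dense, base R)
.dist_l1 <- function(x, x2 = NULL) {
  if (is.null(x2))
    return(unname(as.matrix(stats::dist(x, method = "manhattan"))))
  t2 <- t(x2)
  t(vapply(seq_len(nrow(x)), function(i) colSums(abs(t2 - x[i, ])),
           numeric(nrow(x2))))
}

.dist_l2sq <- function(x, x2 = NULL) {
  if (is.null(x2)) x2 <- x
  n1 <- rowSums(x^2); n2 <- rowSums(x2^2)
  d <- outer(unname(n1), unname(n2), "+") - 2 * unname(tcrossprod(x, x2))
  d[d < 0] <- 0
  d
}

#' Kernel matrix between descriptor rows
#'
#' Laplacian kernel `exp(-||x - x'||_1 / sigma)` or Gaussian kernel
#' `exp(-||x - x'||_2^2 / (2 sigma^2))`. Both give `k(x, x) = 1` and entries
#' in (0, 1].
#'
#' @param x,x2 numeric matrices with equal feature widths; `x2 = NULL` means
#'   the symmetric matrix `K(x, x)`.
#' @param kernel `"laplacian"` or `"gaussian"`.
#' @param sigma length-scale hyperparameter, > 0.
#' @return `nrow(x) x nrow(x2)` kernel matrix.
#' @export
kernel_matrix <- function(x, x2 = NULL, kernel = c("laplacian", "gaussian"),
                          sigma = 1) {
  kernel <- match.arg(kernel)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  x <- as.matrix(x)
  if (!is.null(x2)) {
    x2 <- as.matrix(x2)
    if (ncol(x) != ncol(x2))
      stop("feature width mismatch: ", ncol(x), " vs ", ncol(x2),
           call. = FALSE)
  }
  if (kernel == "laplacian") exp(-.dist_l1(x, x2) / sigma)
  else exp(-.dist_l2sq(x, x2) / (2 * sigma^2))
}

.kernel_from_dist <- function(d, kernel, sigma) {
  if (kernel == "laplacian") exp(-d / sigma) else exp(-d / (2 * sigma^2))
}

#' Fit a kernel ridge regression model
#'
#' Solves the regularized dual system `(K + lambda I) alpha = y` by a
#' symmetric positive-definite (Cholesky) solve and returns a classed model;
#' predictions are `yhat(x) = sum_i alpha_i k(x, x_i)`. The achieved residual
#' `||(K + lambda I) alpha - y||_inf` is checked against `1e-8 ||y||_inf` at
#' fit time.
#'
#' @param x numeric training matrix (rows = molecules).
#' @param y numeric targets.
#' @param kernel `"laplacian"` (default) or `"gaussian"`.
#' @param sigma kernel length scale, > 0.
#' @param lambda ridge regularization, >= 0. With `lambda = 0` the kernel
#'   matrix must be well conditioned; a singular solve raises a conditioning
#'   error advising `lambda > 0`.
#' @return object of class `"qd_krr"` with components `kernel`, `sigma`,
#'   `lambda`, `x_train`, `alpha`, `y`, `fitted`, `solve_residual`.
#' @export
#' @examples
#' x <- matrix(seq(0, 1, length.out = 20))
#' fit <- krr(x, sin(2 * pi * x[, 1]), sigma = 0.3, lambda = 1e-10)
#' max(abs(predict(fit, x) - sin(2 * pi * x[, 1]))) < 1e-4
krr <- function(x, y, kernel = c("laplacian", "gaussian"), sigma = 1,
                lambda = 1e-10) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (!all(is.finite(y))) stop("targets must be finite", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  k <- kernel_matrix(x, NULL, kernel, sigma)
  a <- k + diag(lambda, nrow(k))
  alpha <- tryCatch(
    drop(chol2inv(chol(a)) %*% y),
    error = function(e) {
      alt <- tryCatch(drop(solve(a, y)), error = function(e2) NULL)
      if (is.null(alt))
        stop("kernel system is singular; use lambda > 0", call. = FALSE)
      alt
    })
  res <- max(abs(a %*% alpha - y))
  tol <- 1e-8 * max(abs(y), 1e-300)
  for (it in 1:5) {
    # iterative refinement until the dual residual meets the invariant
    if (res <= tol) break
    alpha <- alpha + drop(solve(a, y - a %*% alpha))
    res <- max(abs(a %*% alpha - y))
  }
  if (res > tol)
    stop("kernel system too ill-conditioned (residual ", format(res),
         "); increase lambda", call. = FALSE)
  fitted <- drop(k %*% alpha)
  structure(list(kernel = kernel, sigma = sigma, lambda = lambda,
                 x_train = x, alpha = alpha, y = y, fitted = fitted,
                 solve_residual = res),
            class = "qd_krr")
}

#' @export
print.qd_krr <- function(x, ...) {
  cat(sprintf(
    "Kernel ridge regression (%s kernel)\n  n = %d, d = %d, sigma = %.4g, lambda = %.4g\n",
    x$kernel, nrow(x$x_train), ncol(x$x_train), x$sigma, x$lambda))
  cat(sprintf("  training RMSE = %.4g\n",
              sqrt(mean((x$fitted - x$y)^2))))
  invisible(x)
}

#' @export
predict.qd_krr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != ncol(object$x_train))
    stop("feature width mismatch: model expects ", ncol(object$x_train),
         call. = FALSE)
  k <- kernel_matrix(newdata, object$x_train, object$kernel, object$sigma)
  drop(k %*% object$alpha)
}

#' @export
coef.qd_krr <- function(object, ...) object$alpha

#' @export
residuals.qd_krr <- function(object, ...) object$fitted - object$y

#' @export
summary.qd_krr <- function(object, ...) {
  out <- list(model = object,
              train = regression_metrics(object$y, object$fitted))
  class(out) <- "summary.qd_krr"
  out
}

#' @export
print.summary.qd_krr <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training MAE = %.4g, R2 = %.4g\n",
              x$train$MAE, x$train$R2))
  invisible(x)
}

#' Delta-learning kernel ridge fit
#'
#' Trains the kernel machine on the residual `y_target - y_baseline` and adds
#' the baseline back at prediction time, so a cheap estimate (e.g. a
#' tight-binding property) is corrected towards a high-fidelity target.
#'
#' The correction is mean-centered before the kernel fit (the mean acts as an
#' intercept added back at prediction time), so a constant shift between
#' baseline and target is recovered exactly.
#'
#' @param x training descriptor rows.
#' @param y_target high-fidelity targets.
#' @param y_baseline cheap baseline values aligned with `y_target`.
#' @inheritParams krr
#' @return object of class `"qd_krr_delta"`; its `predict` method takes the
#'   new rows and their baseline values.
#' @export
delta_krr <- function(x, y_target, y_baseline,
                      kernel = c("laplacian", "gaussian"),
                      sigma = 1, lambda = 1e-10) {
  y_target <- as.numeric(y_target); y_baseline <- as.numeric(y_baseline)
  if (length(y_target) != length(y_baseline))
    stop("target/baseline length mismatch", call. = FALSE)
  delta <- y_target - y_baseline
  intercept <- mean(delta)
  fit <- krr(x, delta - intercept, kernel = kernel, sigma = sigma,
             lambda = lambda)
  structure(list(correction = fit, intercept = intercept),
            class = "qd_krr_delta")
}

#' @export
predict.qd_krr_delta <- function(object, newdata, baseline, ...) {
  baseline <- as.numeric(baseline)
  if (nrow(as.matrix(newdata)) != length(baseline))
    stop("newdata/baseline length mismatch", call. = FALSE)
  baseline + object$intercept + predict(object$correction, newdata)
}

#' @export
print.qd_krr_delta <- function(x, ...) {
  cat("Delta-learning wrapper around:\n")
  print(x$correction)
  invisible(x)
}
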