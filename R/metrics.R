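#' Regression error report
#'
#' Computes MAE, RMSE, the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`, and the residual vector with the convention
#' residual = prediction - true. When the true values have zero variance, R2
#' is undefined and flagged as `NA` with `r2_defined = FALSE`.
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @return object of class `"qd_eval"`: `MAE`, `RMSE`, `R2`, `r2_defined`,
#'   `residuals`, `n`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(2, 3, 4))  # MAE 1, RMSE 1, R2 -0.5
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal non-zero length", call. = FALSE)
  res <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2_defined <- ss_tot > 0
  structure(list(MAE = mean(abs(res)), RMSE = sqrt(mean(res^2)),
                 R2 = if (r2_defined) 1 - sum(res^2) / ss_tot else NA_real_,
                 r2_defined = r2_defined, residuals = res,
                 n = length(res)),
            class = "qd_eval")
}

#' @export
print.qd_eval <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.6g  RMSE = %.6g  R2 = %s\n", x$n, x$MAE,
              x$RMSE, if (x$r2_defined) sprintf("%.6g", x$R2)
              else "undefined (zero-variance truth)"))
  invisible(x)
}

#' Learning curve over nested training subsets
#'
#' Reserves a fixed, seeded held-out test set, draws one seeded permutation of
#' the remaining rows, and trains on its first `n` elements for each requested
#' size — so smaller training sets are subsets of larger ones and the curve is
#' comparable across sizes. Deterministic given `seed`.
#'
#' @param x descriptor matrix.
#' @param y targets.
#' @param sizes increasing training-set sizes.
#' @param fit function `(x, y) -> model` whose result has a `predict` method;
#'   defaults to a Laplacian-kernel [krr()] with a median-heuristic length
#'   scale.
#' @param n_test held-out test size (default: all rows not used at the
#'   largest training size).
#' @param seed RNG seed for the test/train partition.
#' @return data frame with columns `n_train`, `mae`, `rmse`, `r2`.
#' @export
learning_curve <- function(x, y, sizes, fit = NULL, n_test = NULL,
                           seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  sizes <- sort(unique(as.integer(sizes)))
  if (is.null(n_test)) n_test <- n - max(sizes)
  if (n_test < 1L || max(sizes) + n_test > n)
    stop("sizes exceed availability: need max(sizes) + n_test <= ", n,
         call. = FALSE)
  if (is.null(fit)) {
    fit <- function(xtr, ytr) {
      d <- .dist_l1(xtr)
      med <- stats::median(d[upper.tri(d)])
      krr(xtr, ytr, kernel = "laplacian", sigma = max(med, 1e-8),
          lambda = 1e-8)
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  test <- perm[seq_len(n_test)]
  pool <- perm[-seq_len(n_test)]
  rows <- lapply(sizes, function(m) {
    tr <- pool[seq_len(m)]
    model <- fit(x[tr, , drop = FALSE], y[tr])
    ev <- regression_metrics(y[test], predict(model, x[test, , drop = FALSE]))
    data.frame(n_train = m, mae = ev$MAE, rmse = ev$RMSE, r2 = ev$R2)
  })
  do.call(rbind, rows)
}
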