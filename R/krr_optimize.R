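#' Configuration for joint split/hyperparameter optimization
#'
#' @param n_train,n_val training and validation set sizes; their sum must not
#'   exceed the number of available rows (the remainder forms the test set).
#' @param n_splits number of random train/validation split replicates.
#' @param seed RNG seed controlling splits and optimizer starts.
#' @param kernel kernel kind for the search.
#' @param log_sigma_bounds,log_lambda_bounds log10-space box constraints for
#'   the two hyperparameters (defaults `[-2, 6]` and `[-12, 0]`).
#' @param n_starts seeded multi-start count per split.
#' @param maxit L-BFGS-B iteration budget per start.
#' @return object of class `"qd_krr_config"`.
#' @export
krr_config <- function(n_train, n_val, n_splits = 1L, seed = 1L,
                       kernel = c("laplacian", "gaussian"),
                       log_sigma_bounds = c(-2, 6),
                       log_lambda_bounds = c(-12, 0),
                       n_starts = 3L, maxit = 50L) {
  kernel <- match.arg(kernel)
  stopifnot(n_train >= 2L, n_val >= 1L, n_splits >= 1L, n_starts >= 1L)
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_splits = as.integer(n_splits), seed = as.integer(seed),
                 kernel = kernel, log_sigma_bounds = log_sigma_bounds,
                 log_lambda_bounds = log_lambda_bounds,
                 n_starts = as.integer(n_starts), maxit = as.integer(maxit)),
            class = "qd_krr_config")
}

#' Optimize a kernel ridge model over random splits and hyperparameters
#'
#' For each of `n_splits` seeded random train/validation splits, minimizes the
#' validation mean absolute error over `(log10 sigma, log10 lambda)` with
#' box-constrained L-BFGS-B (finite-difference gradients) from several seeded
#' starting points, then refits on the winning training split at the winning
#' hyperparameters. The validation set is never folded into the final fit, so
#' the reported validation MAE stays honest. Deterministic given
#' `config$seed`.
#'
#' @param x descriptor matrix.
#' @param y numeric targets.
#' @param config a [krr_config()].
#' @return object of class `"qd_krr_opt"`: `model` (the refit [krr()]),
#'   `report` (one row per split: sigma, lambda, validation MAE), `best`
#'   (winning split index), `test_idx` (rows never used in any split of the
#'   winning partition).
#' @export
krr_optimize <- function(x, y, config) {
  stopifnot(inherits(config, "qd_krr_config"))
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (config$n_train + config$n_val > n)
    stop("n_train + n_val exceeds the number of rows", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  lb <- c(config$log_sigma_bounds[1], config$log_lambda_bounds[1])
  ub <- c(config$log_sigma_bounds[2], config$log_lambda_bounds[2])
  report <- vector("list", config$n_splits)
  best <- NULL
  for (s in seq_len(config$n_splits)) {
    idx <- sample.int(n, config$n_train + config$n_val)
    tr <- idx[seq_len(config$n_train)]
    va <- idx[config$n_train + seq_len(config$n_val)]
    d_tt <- if (config$kernel == "laplacian") .dist_l1(x[tr, , drop = FALSE])
            else .dist_l2sq(x[tr, , drop = FALSE])
    d_vt <- if (config$kernel == "laplacian")
      .dist_l1(x[va, , drop = FALSE], x[tr, , drop = FALSE])
    else .dist_l2sq(x[va, , drop = FALSE], x[tr, , drop = FALSE])
    # median heuristic anchors one start; others sample the box
    med <- stats::median(d_tt[upper.tri(d_tt)])
    if (config$kernel == "gaussian") med <- sqrt(med)
    anchor <- min(max(log10(max(med, 1e-12)), lb[1]), ub[1])
    starts <- rbind(c(anchor, -8),
                    cbind(stats::runif(config$n_starts - 1L, lb[1], ub[1]),
                          stats::runif(config$n_starts - 1L, lb[2], ub[2])))
    starts <- starts[seq_len(config$n_starts), , drop = FALSE]
    obj <- function(par) {
      sig <- 10^par[1]; lam <- 10^par[2]
      k_tt <- .kernel_from_dist(d_tt, config$kernel, sig)
      a <- k_tt + diag(lam, nrow(k_tt))
      alpha <- tryCatch(drop(solve(a, y[tr])), error = function(e) NULL)
      if (is.null(alpha)) return(1e10)
      # infeasible if the dual residual violates the model invariant
      res <- max(abs(a %*% alpha - y[tr]))
      if (res > 1e-9 * max(abs(y[tr]), 1e-300)) {
        alpha <- alpha + drop(solve(a, y[tr] - a %*% alpha))
        res <- max(abs(a %*% alpha - y[tr]))
        if (res > 1e-8 * max(abs(y[tr]), 1e-300)) return(1e10)
      }
      val <- mean(abs(.kernel_from_dist(d_vt, config$kernel, sig) %*% alpha -
                        y[va]))
      if (!is.finite(val))
        stop("bounds error: non-finite validation objective", call. = FALSE)
      val
    }
    split_best <- NULL
    for (st in seq_len(nrow(starts))) {
      fit <- stats::optim(starts[st, ], obj, method = "L-BFGS-B",
                          lower = lb, upper = ub,
                          control = list(maxit = config$maxit))
      if (is.null(split_best) || fit$value < split_best$value)
        split_best <- fit
    }
    report[[s]] <- data.frame(split = s,
                              sigma = 10^split_best$par[1],
                              lambda = 10^split_best$par[2],
                              val_mae = split_best$value)
    if (is.null(best) || split_best$value < best$val_mae)
      best <- list(split = s, tr = tr, va = va,
                   sigma = 10^split_best$par[1],
                   lambda = 10^split_best$par[2],
                   val_mae = split_best$value)
  }
  report <- do.call(rbind, report)
  model <- krr(x[best$tr, , drop = FALSE], y[best$tr],
               kernel = config$kernel, sigma = best$sigma,
               lambda = best$lambda)
  structure(list(model = model, report = report, best = best$split,
                 train_idx = best$tr, val_idx = best$va,
                 test_idx = setdiff(seq_len(n), c(best$tr, best$va)),
                 config = config),
            class = "qd_krr_opt")
}

#' @export
print.qd_krr_opt <- function(x, ...) {
  cat(sprintf(
    "KRR split/hyperparameter optimization (%d split%s, %s kernel)\n",
    nrow(x$report), if (nrow(x$report) > 1) "s" else "",
    x$config$kernel))
  cat(sprintf(
    "  winner: split %d, sigma = %.4g, lambda = %.4g, val MAE = %.4g\n",
    x$best, x$model$sigma, x$model$lambda,
    x$report$val_mae[x$best]))
  invisible(x)
}

#' @export
predict.qd_krr_opt <- function(object, newdata, ...)
  predict(object$model, newdata, ...)
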