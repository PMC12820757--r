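#' Farthest point sampling in descriptor space
#'
#' Greedy max-min selection: starting from a seed row, each subsequent index
#' maximizes the minimum Euclidean distance to the already-selected set. Ties
#' are broken by the lowest index, so the result is deterministic. The default
#' seed point is the medoid (the row with minimal total distance to all
#' others).
#'
#' @param x numeric matrix of descriptor rows.
#' @param n number of points to select, `1 <= n <= nrow(x)`.
#' @param start optional 1-based index of the first selected row.
#' @return integer vector of `n` selected row indices, in selection order.
#' @export
#' @examples
#' fps_select(matrix(c(0, 1, 10)), 2, start = 1)  # c(1, 3)
fps_select <- function(x, n, start = NULL) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (n < 1L || n > m) stop("n must be in 1..", m, call. = FALSE)
  d <- as.matrix(stats::dist(x))
  if (is.null(start)) start <- which.min(rowSums(d))  # medoid
  sel <- integer(n)
  sel[1] <- as.integer(start)
  if (n == 1L) return(sel)
  min_d <- d[, sel[1]]
  for (k in 2L:n) {
    min_d[sel[seq_len(k - 1L)]] <- -Inf
    sel[k] <- which.max(min_d)  # which.max takes the lowest index on ties
    min_d <- pmin(min_d, d[, sel[k]])
  }
  sel
}

#' Default boosted-tree search space
#'
#' The ranges a practitioner would scan for this learner: `eta` log-uniform in
#' `[0.01, 0.3]`, `max_depth` in 3..10, `n_rounds` in 100..1000, `lambda`
#' log-uniform in `[1e-3, 10]`, `gamma` uniform in `[0, 5]`. Held in config
#' (a plain list), not hard-coded, so tests and callers can shrink it.
#'
#' @return named list of parameter ranges for [tune_boost()].
#' @export
default_boost_space <- function() {
  list(eta = list(type = "loguniform", lo = 0.01, hi = 0.3),
       max_depth = list(type = "choice", values = 3:10),
       n_rounds = list(type = "choice", values = seq(100L, 1000L, by = 100L)),
       lambda = list(type = "loguniform", lo = 1e-3, hi = 10),
       gamma = list(type = "uniform", lo = 0, hi = 5))
}

.sample_space <- function(space) {
  out <- list()
  for (nm in names(space)) {
    sp <- space[[nm]]
    out[[nm]] <- switch(sp$type,
      loguniform = exp(stats::runif(1, log(sp$lo), log(sp$hi))),
      uniform = stats::runif(1, sp$lo, sp$hi),
      choice = sp$values[sample.int(length(sp$values), 1L)],
      stop("unknown space entry type ", sQuote(sp$type), call. = FALSE))
  }
  out
}

#' Cross-validated hyperparameter search for the boosted learner
#'
#' Seeded sequential random search over a parameter space; each trial is
#' scored by the mean cross-validated negative RMSE (maximized) over `folds`
#' folds fixed before the first trial. Deterministic given `seed`: the trial
#' sequence depends only on the seed, so increasing `trials` extends the same
#' sequence and can never worsen the returned score.
#'
#' @param x feature matrix.
#' @param y targets.
#' @param space named list of ranges as in [default_boost_space()]; entries
#'   may be `list(type = "loguniform"/"uniform", lo, hi)` or
#'   `list(type = "choice", values)`.
#' @param trials number of trials, >= 1.
#' @param folds number of CV folds, >= 2.
#' @param seed RNG seed.
#' @return list with `best_params` (a [gbt_params()]), `best_score` (mean CV
#'   negative RMSE), and `log` (one row per trial).
#' @export
tune_boost <- function(x, y, space = default_boost_space(), trials = 20L,
                       folds = 5L, seed = 1L) {
  if (!length(space)) stop("empty search space", call. = FALSE)
  stopifnot(trials >= 1L, folds >= 2L)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  log_rows <- vector("list", trials)
  best <- NULL
  for (t in seq_len(trials)) {
    par <- .sample_space(space)
    params <- gbt_params(
      lambda = if (is.null(par$lambda)) 1 else par$lambda,
      gamma = if (is.null(par$gamma)) 0 else par$gamma,
      eta = if (is.null(par$eta)) 0.3 else par$eta,
      max_depth = if (is.null(par$max_depth)) 6L else par$max_depth,
      n_rounds = if (is.null(par$n_rounds)) 100L else par$n_rounds,
      min_child = if (is.null(par$min_child)) 1L else par$min_child)
    neg_rmse <- vapply(seq_len(folds), function(f) {
      te <- fold_id == f
      fit <- gbt(x[!te, , drop = FALSE], y[!te], params)
      -sqrt(mean((predict(fit, x[te, , drop = FALSE]) - y[te])^2))
    }, numeric(1))
    score <- mean(neg_rmse)
    log_rows[[t]] <- cbind(data.frame(trial = t, score = score),
                           as.data.frame(par))
    if (is.null(best) || score > best$score)
      best <- list(params = params, score = score, trial = t)
  }
  list(best_params = best$params, best_score = best$score,
       log = do.call(rbind, log_rows))
}
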