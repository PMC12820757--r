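#' Parameters for the second-order boosted tree learner
#'
#' The loss is fixed to squared error with the 1/2 convention, so the
#' per-sample gradient is `g = yhat - y` and the Hessian is `h = 1`. `lambda`
#' is the L2 leaf-weight regularizer and `gamma` the per-leaf complexity
#' penalty entering the split gain; `eta` shrinks each tree's contribution.
#'
#' @param lambda leaf L2 regularizer, >= 0.
#' @param gamma per-leaf complexity penalty, >= 0.
#' @param eta learning rate in (0, 1].
#' @param max_depth maximum tree depth (0 = a single leaf).
#' @param n_rounds number of boosting rounds, >= 1.
#' @param min_child minimum samples per leaf.
#' @return object of class `"qd_gbt_params"`.
#' @export
gbt_params <- function(lambda = 1, gamma = 0, eta = 0.3, max_depth = 6L,
                       n_rounds = 100L, min_child = 1L) {
  stopifnot(lambda >= 0, gamma >= 0, eta > 0, eta <= 1, max_depth >= 0,
            n_rounds >= 1, min_child >= 1)
  structure(list(lambda = lambda, gamma = gamma, eta = eta,
                 max_depth = as.integer(max_depth),
                 n_rounds = as.integer(n_rounds),
                 min_child = as.integer(min_child)),
            class = "qd_gbt_params")
}

#' Optimal leaf weight from aggregated gradients
#'
#' For a leaf holding samples with gradient sum `G` and Hessian sum `H`, the
#' weight minimizing the second-order objective is `-G / (H + lambda)`.
#'
#' @param G sum of gradients in the leaf.
#' @param H sum of Hessians in the leaf.
#' @param lambda leaf L2 regularizer; `H + lambda` must be > 0.
#' @return the optimal weight.
#' @export
#' @examples
#' optimal_leaf_weight(-6, 2, 0)  # 3
optimal_leaf_weight <- function(G, H, lambda = 0) {
  if (H + lambda <= 0) stop("H + lambda must be > 0", call. = FALSE)
  -G / (H + lambda)
}

# structure gain of a candidate split (the 1/2 [...] - gamma form)
.split_gain <- function(GL, HL, GR, HR, lambda, gamma) {
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           (GL + GR)^2 / (HL + HR + lambda)) - gamma
}

#' Grow one regression tree on gradients and Hessians
#'
#' Exact greedy construction: at every node, all features and all midpoints
#' between consecutive distinct sorted values are scanned, and the split with
#' the largest structure gain
#' `1/2 [G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - (G_L+G_R)^2/(H_L+H_R+lambda)] - gamma`
#' is taken if the gain is strictly positive and depth/leaf-size constraints
#' allow; otherwise the node becomes a leaf with weight `-G/(H+lambda)`.
#' Ties are broken deterministically by lowest feature index, then lowest
#' threshold (first strict improvement wins).
#'
#' @param x numeric feature matrix.
#' @param g,h per-sample gradients and Hessians (finite, equal length).
#' @param params a [gbt_params()].
#' @return nested list of nodes; internal nodes carry `feature`, `threshold`,
#'   `gain`, `left`, `right`; leaves carry `weight`. Every node stores its
#'   `G`, `H` and sample count `n`.
#' @export
grow_tree <- function(x, g, h, params) {
  stopifnot(inherits(params, "qd_gbt_params"))
  x <- as.matrix(x)
  g <- as.numeric(g); h <- as.numeric(h)
  if (nrow(x) == 0L) stop("empty input", call. = FALSE)
  if (length(g) != nrow(x) || length(h) != nrow(x))
    stop("g and h must have one entry per row", call. = FALSE)
  if (!all(is.finite(g)) || !all(is.finite(h)))
    stop("gradients and Hessians must be finite", call. = FALSE)
  .grow_node(x, g, h, params, depth = 0L)
}

.grow_node <- function(x, g, h, params, depth) {
  G <- sum(g); H <- sum(h); n <- nrow(x)
  leaf <- list(leaf = TRUE, weight = optimal_leaf_weight(G, H, params$lambda),
               G = G, H = H, n = n)
  if (depth >= params$max_depth || n < 2L * params$min_child) return(leaf)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    ord <- order(x[, f])
    xv <- x[ord, f]; gs <- cumsum(g[ord]); hs <- cumsum(h[ord])
    # candidate boundaries: after position i where xv[i] < xv[i+1]
    cand <- which(xv[-n] < xv[-1])
    cand <- cand[cand >= params$min_child & (n - cand) >= params$min_child]
    for (i in cand) {
      gain <- .split_gain(gs[i], hs[i], G - gs[i], H - hs[i],
                          params$lambda, params$gamma)
      if (gain > 0 && (is.null(best) || gain > best$gain))
        best <- list(feature = f, threshold = (xv[i] + xv[i + 1]) / 2,
                     gain = gain)
    }
  }
  if (is.null(best)) return(leaf)
  go_left <- x[, best$feature] < best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       gain = best$gain, G = G, H = H, n = n,
       left = .grow_node(x[go_left, , drop = FALSE], g[go_left], h[go_left],
                         params, depth + 1L),
       right = .grow_node(x[!go_left, , drop = FALSE], g[!go_left],
                          h[!go_left], params, depth + 1L))
}

# vectorized routing of rows through one tree
.tree_predict <- function(node, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$weight; return() }
    left <- x[idx, node$feature] < node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(node, seq_len(nrow(x)))
  out
}

#' Fit a second-order gradient-boosted tree ensemble
#'
#' Base prediction is `mean(y)`; each round grows one tree on the current
#' gradients/Hessians of the squared-error loss and adds it with factor
#' `eta`. Training loss is non-increasing over rounds for `eta <= 1`.
#'
#' @param x numeric feature matrix.
#' @param y numeric targets (finite).
#' @param params a [gbt_params()].
#' @return object of class `"qd_gbt"` with `base`, `trees`, `params`,
#'   `train_rmse` (per-round trajectory).
#' @export
#' @examples
#' x <- matrix(0:3); y <- c(0, 0, 10, 10)
#' fit <- gbt(x, y, gbt_params(lambda = 0, eta = 1, n_rounds = 1,
#'                             max_depth = 2))
#' predict(fit, x)  # exactly y
gbt <- function(x, y, params = gbt_params()) {
  stopifnot(inherits(params, "qd_gbt_params"))
  x <- as.matrix(x); y <- as.numeric(y)
  if (!all(is.finite(y))) stop("targets must be finite", call. = FALSE)
  stopifnot(nrow(x) == length(y))
  base <- mean(y)
  pred <- rep(base, length(y))
  trees <- vector("list", params$n_rounds)
  rmse <- numeric(params$n_rounds)
  for (t in seq_len(params$n_rounds)) {
    gt <- pred - y          # d/dpred of 1/2 (y - pred)^2
    ht <- rep(1, length(y)) # second derivative
    trees[[t]] <- .grow_node(x, gt, ht, params, depth = 0L)
    pred <- pred + params$eta * .tree_predict(trees[[t]], x)
    rmse[t] <- sqrt(mean((pred - y)^2))
  }
  structure(list(base = base, trees = trees, params = params,
                 train_rmse = rmse, n_features = ncol(x)),
            class = "qd_gbt")
}

#' @export
predict.qd_gbt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature width mismatch: model expects ", object$n_features,
         call. = FALSE)
  pred <- rep(object$base, nrow(newdata))
  for (tree in object$trees)
    pred <- pred + object$params$eta * .tree_predict(tree, newdata)
  pred
}

#' @export
print.qd_gbt <- function(x, ...) {
  cat(sprintf(
    "Boosted tree ensemble: %d rounds, depth <= %d, eta = %g, lambda = %g, gamma = %g\n",
    length(x$trees), x$params$max_depth, x$params$eta, x$params$lambda,
    x$params$gamma))
  cat(sprintf("  final training RMSE = %.4g\n",
              x$train_rmse[length(x$train_rmse)]))
  invisible(x)
}

#' @export
summary.qd_gbt <- function(object, ...) {
  n_leaves <- function(node) if (node$leaf) 1L else
    n_leaves(node$left) + n_leaves(node$right)
  leaves <- vapply(object$trees, n_leaves, integer(1))
  cat(sprintf(
    "Boosted ensemble: %d trees, %d-%d leaves each, base = %.4g\n",
    length(object$trees), min(leaves), max(leaves), object$base))
  invisible(list(leaves = leaves, train_rmse = object$train_rmse))
}

#' Serialize / restore a boosted ensemble as JSON
#'
#' Predictions are bit-identical before and after a round trip (weights are
#' written at full precision).
#'
#' @param model a [gbt()] ensemble.
#' @param path JSON file path.
#' @return `path` (for `gbt_save`); a `qd_gbt` (for `gbt_load`).
#' @export
gbt_save <- function(model, path) {
  stopifnot(inherits(model, "qd_gbt"))
  jsonlite::write_json(
    list(format = "quantdesc-gbt", base = model$base,
         n_features = model$n_features, params = unclass(model$params),
         trees = model$trees),
    path, auto_unbox = TRUE, digits = I(17))  # 17 sig. digits: bit-exact
  invisible(path)
}

#' @rdname gbt_save
#' @export
gbt_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "quantdesc-gbt"))
    stop("not a boosted-ensemble archive", call. = FALSE)
  p <- doc$params
  structure(list(base = doc$base, trees = doc$trees,
                 params = gbt_params(p$lambda, p$gamma, p$eta, p$max_depth,
                                     p$n_rounds, p$min_child),
                 train_rmse = NA_real_, n_features = doc$n_features),
            class = "qd_gbt")
}
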