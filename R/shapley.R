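#' Exact interventional Shapley values for one sample
#'
#' Enumerates all `2^d` feature coalitions. The value of a coalition `S` is
#' the mean model prediction over the background rows with the features in
#' `S` replaced by the sample's values (interventional expectation). The
#' attribution of feature `j` is the Shapley-weighted average of its marginal
#' contributions:
#' `phi_j = sum over S not containing j of |S|! (d-|S|-1)! / d! (v(S+j) - v(S))`.
#' Satisfies local accuracy (`sum(phi) + baseline = f(x)`) and symmetry by
#' construction.
#'
#' @param predict_fun function taking a numeric matrix of rows and returning
#'   numeric predictions.
#' @param x the sample to explain (numeric vector of length `d <= 15`).
#' @param background matrix of background rows defining the reference
#'   distribution.
#' @return list with `phi` (length-d attribution vector), `baseline`
#'   (`v(empty) = mean prediction over the background`), and `fx`
#'   (`predict_fun(x)`).
#' @export
#' @examples
#' f <- function(m) 2 * m[, 1] + m[, 2]
#' bg <- matrix(rnorm(40), ncol = 2)
#' s <- exact_shapley(f, c(1, 1), bg)
#' abs(sum(s$phi) + s$baseline - s$fx) < 1e-12
exact_shapley <- function(predict_fun, x, background) {
  x <- as.numeric(x)
  d <- length(x)
  if (d > 15L)
    stop("exact enumeration is limited to d <= 15 features (2^d coalitions);",
         " explain a feature subset or use a model-specific explainer",
         call. = FALSE)
  background <- as.matrix(background)
  if (nrow(background) < 1L) stop("background must be non-empty",
                                  call. = FALSE)
  if (ncol(background) != d)
    stop("background width must equal length(x)", call. = FALSE)
  n_mask <- bitwShiftL(1L, d)
  nb <- nrow(background)
  # batch all coalition evaluations into one predict call
  big <- background[rep(seq_len(nb), n_mask), , drop = FALSE]
  for (j in seq_len(d)) {
    masks_with_j <- which(bitwAnd(seq_len(n_mask) - 1L,
                                  bitwShiftL(1L, j - 1L)) != 0L)
    rows <- as.vector(outer(seq_len(nb), (masks_with_j - 1L) * nb, "+"))
    big[rows, j] <- x[j]
  }
  preds <- predict_fun(big)
  v <- vapply(seq_len(n_mask), function(m)
    mean(preds[((m - 1L) * nb + 1L):(m * nb)]), numeric(1))
  sizes <- vapply(seq_len(n_mask) - 1L, function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) != 0L), integer(1))
  # weight |S|! (d-|S|-1)! / d!; the full coalition never enters a marginal
  w <- numeric(n_mask)
  ok <- sizes < d
  w[ok] <- exp(lfactorial(sizes[ok]) + lfactorial(d - sizes[ok] - 1L) -
                 lfactorial(d))
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    no_j <- which(bitwAnd(seq_len(n_mask) - 1L, bit) == 0L)
    phi[j] <- sum(w[no_j] * (v[no_j + bit] - v[no_j]))
  }
  if (!is.null(colnames(background))) names(phi) <- colnames(background)
  list(phi = phi, baseline = v[1], fx = v[n_mask])
}

#' Shapley attributions for several samples
#'
#' @param predict_fun prediction function over a matrix of rows.
#' @param x matrix of samples to explain.
#' @param background background rows.
#' @return list with `Phi` (samples x features attribution matrix),
#'   `baseline`, `fx` (per-sample predictions).
#' @export
shapley_matrix <- function(predict_fun, x, background) {
  x <- as.matrix(x)
  rows <- lapply(seq_len(nrow(x)), function(i)
    exact_shapley(predict_fun, x[i, ], background))
  list(Phi = do.call(rbind, lapply(rows, `[[`, "phi")),
       baseline = rows[[1]]$baseline,
       fx = vapply(rows, `[[`, numeric(1), "fx"))
}

#' Rank features and build a beeswarm export table
#'
#' Features are sorted by mean absolute attribution, descending, with ties
#' broken alphabetically by label. The long-format table pairs each feature
#' value with its attribution, ready for any plotting layer.
#'
#' @param Phi samples x features attribution matrix.
#' @param feature_values matrix of the corresponding feature values (same
#'   shape).
#' @param labels feature labels; defaults to `colnames(Phi)`.
#' @return list with `ranking` (data frame: feature, mean_abs_phi, rank) and
#'   `beeswarm` (data frame: feature, value, phi).
#' @export
shap_summary <- function(Phi, feature_values, labels = colnames(Phi)) {
  Phi <- as.matrix(Phi)
  feature_values <- as.matrix(feature_values)
  if (!all(is.finite(Phi))) stop("attributions must be finite", call. = FALSE)
  stopifnot(all(dim(Phi) == dim(feature_values)))
  if (is.null(labels)) labels <- paste0("f", seq_len(ncol(Phi)))
  imp <- colMeans(abs(Phi))
  ord <- order(-imp, labels)
  ranking <- data.frame(feature = labels[ord], mean_abs_phi = imp[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  beeswarm <- data.frame(
    feature = rep(labels, each = nrow(Phi)),
    value = as.vector(feature_values),
    phi = as.vector(Phi), stringsAsFactors = FALSE)
  list(ranking = ranking, beeswarm = beeswarm)
}
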