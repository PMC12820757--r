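#' Construct a descriptor block
#'
#' A named feature matrix: one row per molecule (in dataset order), one
#' labelled column per feature. All descriptor producers return blocks so
#' they can be concatenated, scaled and exported uniformly.
#'
#' @param name block name, used to prefix labels on concatenation.
#' @param matrix numeric n x d matrix, finite everywhere.
#' @param labels length-d unique feature labels; defaults to existing
#'   colnames.
#' @param row_ids optional molecule ids, one per row.
#' @return object of class `"qd_block"`.
#' @export
descriptor_block <- function(name, matrix, labels = colnames(matrix),
                             row_ids = rownames(matrix)) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (!all(is.finite(m)))
    stop("descriptor block ", name, " contains non-finite values",
         call. = FALSE)
  if (is.null(labels)) labels <- paste0(name, "_", seq_len(ncol(m)))
  labels <- as.character(labels)
  if (length(labels) != ncol(m) || anyDuplicated(labels))
    stop("labels must be unique and match the column count", call. = FALSE)
  colnames(m) <- labels
  rownames(m) <- row_ids
  structure(list(name = as.character(name), matrix = m, labels = labels),
            class = "qd_block")
}

#' @export
print.qd_block <- function(x, ...) {
  cat("<descriptor block ", x$name, "> ", nrow(x$matrix), " x ",
      ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' @export
dim.qd_block <- function(x) dim(x$matrix)

#' @export
as.matrix.qd_block <- function(x, ...) x$matrix

#' Column-wise concatenation of descriptor blocks
#'
#' Joins blocks side by side (e.g. a geometric block with the electronic
#' block), prefixing every label with its block name so the provenance of each
#' feature stays visible. All blocks must have the same number of rows in the
#' same molecule order.
#'
#' @param ... `qd_block`s, or a single list of them.
#' @param name name for the combined block; defaults to the names joined by
#'   `"+"`.
#' @return a [descriptor_block()].
#' @export
concat_blocks <- function(..., name = NULL) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1]], "qd_block"))
    blocks <- blocks[[1]]
  if (!length(blocks)) stop("no blocks to concatenate", call. = FALSE)
  stopifnot(all(vapply(blocks, inherits, logical(1), "qd_block")))
  n <- nrow(blocks[[1]]$matrix)
  if (!all(vapply(blocks, function(b) nrow(b$matrix), integer(1)) == n))
    stop("alignment error: blocks have differing row counts", call. = FALSE)
  mats <- lapply(blocks, function(b) {
    m <- b$matrix
    colnames(m) <- paste0(b$name, ".", b$labels)
    m
  })
  if (is.null(name))
    name <- paste(vapply(blocks, function(b) b$name, character(1)),
                  collapse = "+")
  descriptor_block(name, do.call(cbind, mats),
                   row_ids = rownames(blocks[[1]]$matrix))
}

#' Fit a per-feature z-score scaler on a block
#'
#' Location is the feature mean, scale the population standard deviation
#' (denominator n). Constant features are flagged and mapped to 0 by
#' [standardize_block()]. Fit on training rows only, then reuse the scaler on
#' validation/test blocks.
#'
#' @param block a [descriptor_block()] of training rows.
#' @return object of class `"qd_scaler"`.
#' @export
fit_block_scaler <- function(block) {
  stopifnot(inherits(block, "qd_block"))
  m <- block$matrix
  center <- colMeans(m)
  scale <- sqrt(colMeans(sweep(m, 2, center)^2))
  constant <- scale < 1e-12
  structure(list(labels = block$labels, center = center, scale = scale,
                 constant = constant),
            class = "qd_scaler")
}

#' Z-score a descriptor block
#'
#' @param block a [descriptor_block()].
#' @param scaler a [fit_block_scaler()]; when `NULL` the scaler is fitted on
#'   this block's rows.
#' @return the transformed block, with the scaler attached as attribute
#'   `"scaler"`.
#' @export
standardize_block <- function(block, scaler = NULL) {
  stopifnot(inherits(block, "qd_block"))
  if (is.null(scaler)) scaler <- fit_block_scaler(block)
  if (!identical(scaler$labels, block$labels))
    stop("label error: scaler was fitted on a differently-labelled block",
         call. = FALSE)
  m <- sweep(block$matrix, 2, scaler$center)
  sc <- ifelse(scaler$constant, 1, scaler$scale)
  m <- sweep(m, 2, sc, "/")
  m[, scaler$constant] <- 0
  out <- descriptor_block(block$name, m, block$labels,
                          row_ids = rownames(block$matrix))
  attr(out, "scaler") <- scaler
  out
}

#' Invert a z-score transform
#'
#' @param block a standardized [descriptor_block()].
#' @param scaler the [fit_block_scaler()] used to standardize it.
#' @return the block on the original scale (constant features restored to
#'   their fitted location).
#' @export
unstandardize_block <- function(block, scaler) {
  stopifnot(inherits(block, "qd_block"), inherits(scaler, "qd_scaler"))
  if (!identical(scaler$labels, block$labels))
    stop("label error: scaler was fitted on a differently-labelled block",
         call. = FALSE)
  sc <- ifelse(scaler$constant, 0, scaler$scale)
  m <- sweep(sweep(block$matrix, 2, sc, "*"), 2, scaler$center, "+")
  descriptor_block(block$name, m, block$labels,
                   row_ids = rownames(block$matrix))
}

#' Compute a geometric descriptor block over molecules
#'
#' @param molecules list of [molecule()]s or a [qd_dataset()].
#' @param spec a [fit_bag_spec()] or [slatm_spec()] deciding which descriptor
#'   is built.
#' @return a [descriptor_block()] named `"BOB"` or `"SLATM"`.
#' @export
geometry_block <- function(molecules, spec) {
  if (inherits(molecules, "qd_dataset")) molecules <- molecules$molecules
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (inherits(spec, "qd_bagspec")) {
    rows <- t(vapply(molecules, bob_vector, numeric(spec$length), spec))
    descriptor_block("BOB", rows, row_ids = ids)
  } else if (inherits(spec, "qd_slatmspec")) {
    rows <- t(vapply(molecules, slatm_vector, numeric(spec$length), spec))
    descriptor_block("SLATM", rows, row_ids = ids)
  } else stop("spec must be a bag spec or a SLATM spec", call. = FALSE)
}

#' Export a block as labelled CSV
#'
#' @param block a [descriptor_block()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_csv <- function(block, path) {
  stopifnot(inherits(block, "qd_block"))
  df <- as.data.frame(block$matrix)
  if (!is.null(rownames(block$matrix)))
    df <- cbind(molecule_id = rownames(block$matrix), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
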