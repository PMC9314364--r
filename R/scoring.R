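#' Fit column standardisation parameters
#'
#' Column means and standard deviations (denominator `n - 1`), fitted on the
#' training partition and later applied to held-out data so no holdout
#' statistics leak into the model.
#'
#' @param M Numeric matrix with at least 2 rows and no constant column.
#' @return A `standardizer`: list with `means` and `sds`.
#' @export
fit_standardizer <- function(M) {
  M <- check_matrix(M, "M", min_rows = 2L)
  means <- colMeans(M)
  sds <- apply(M, 2L, sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    nms <- colnames(M) %||% as.character(seq_len(ncol(M)))
    stop_rrscore(sprintf("Constant column(s): %s.", format_ids(nms[bad])),
                 "rrscore_constant_column_error")
  }
  structure(list(means = means, sds = sds), class = "standardizer")
}

#' Apply (or invert) a standardiser
#'
#' `apply_standardizer()` maps each column `x` to `(x - mean) / sd`;
#' `invert_standardizer()` is its exact inverse.
#'
#' @param M Numeric matrix with `length(params$means)` columns.
#' @param params A `standardizer` from [fit_standardizer()].
#' @return Matrix of the same shape.
#' @export
apply_standardizer <- function(M, params) {
  M <- check_matrix(M, "M")
  stopifnot(inherits(params, "standardizer"))
  if (ncol(M) != length(params$means)) {
    stop_rrscore("Column count does not match the standardizer.",
                 "rrscore_dim_error")
  }
  sweep(sweep(M, 2L, params$means, `-`), 2L, params$sds, `/`)
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(M, params) {
  M <- check_matrix(M, "M")
  stopifnot(inherits(params, "standardizer"))
  if (ncol(M) != length(params$means)) {
    stop_rrscore("Column count does not match the standardizer.",
                 "rrscore_dim_error")
  }
  sweep(sweep(M, 2L, params$sds, `*`), 2L, params$means, `+`)
}

#' Define a scale key for unit-weight scoring
#'
#' Maps each questionnaire item to one of a small number of factors and flags
#' negatively keyed items for reverse coding. This is the classical scoring
#' scheme for five-factor inventories: each factor score is the plain average
#' of its items after reverse coding.
#'
#' @param item Item identifiers (character) or indices, length `p`.
#' @param factor Factor name per item.
#' @param reversed Logical per item.
#' @param scale_min,scale_max Response bounds (defaults 1 and 5).
#' @return A `scale_key` tibble with attributes `scale_min`, `scale_max`.
#' @export
scale_key <- function(item, factor, reversed, scale_min = 1L, scale_max = 5L) {
  if (length(item) != length(factor) || length(item) != length(reversed)) {
    stop_rrscore("`item`, `factor` and `reversed` must have equal length.",
                 "rrscore_spec_error")
  }
  if (anyDuplicated(item)) {
    stop_rrscore("Each item may be assigned to exactly one factor.",
                 "rrscore_validation_error")
  }
  out <- tibble::tibble(item = as.character(item),
                        factor = as.character(factor),
                        reversed = as.logical(reversed))
  structure(out, scale_min = as.integer(scale_min),
            scale_max = as.integer(scale_max),
            class = c("scale_key", class(out)))
}

#' Default scale key for the synthetic questionnaire
#'
#' Matches the default generator design: consecutive blocks of items per
#' factor, with the negatively keyed items (the last 30% of each block)
#' flagged for reverse coding.
#'
#' @param n_items Number of items (default 100).
#' @param n_factors Number of factors (default 5).
#' @return A [scale_key()].
#' @export
default_scale_key <- function(n_items = 100L, n_factors = 5L) {
  L <- default_item_loadings(n_items, n_factors)
  fac <- apply(abs(L), 1L, which.max)
  rev <- L[cbind(seq_len(n_items), fac)] < 0
  scale_key(item = sprintf("item_%03d", seq_len(n_items)),
            factor = sprintf("F%d", fac),
            reversed = rev)
}

#' Reverse-code Likert responses
#'
#' Reflects a response about the scale midpoint: on a 1-5 scale, `x` maps to
#' `6 - x`. An involution: applying it twice returns the input.
#'
#' @param x Integer responses within the key's scale bounds.
#' @param key A [scale_key()] supplying the bounds.
#' @return Reverse-coded responses, same shape as `x`.
#' @export
reverse_code <- function(x, key) {
  lo <- attr(key, "scale_min"); hi <- attr(key, "scale_max")
  if (any(x < lo | x > hi, na.rm = TRUE)) {
    stop_rrscore(sprintf("Responses must lie in [%d, %d].", lo, hi),
                 "rrscore_validation_error")
  }
  lo + hi - x
}

#' Unit-weight factor scores
#'
#' For each participant and factor, the simple average of that factor's items
#' after reverse coding the flagged items — the classical scale-scoring
#' baseline.
#'
#' @param X `n x p` integer response matrix with columns named (or ordered) as
#'   in the key.
#' @param key A [scale_key()] covering exactly the `p` items.
#' @return `n x n_factors` matrix of factor scores.
#' @export
score_scales <- function(X, key) {
  X <- check_matrix(X, "X")
  stopifnot(inherits(key, "scale_key"))
  if (nrow(key) != ncol(X)) {
    stop_rrscore(sprintf("Key covers %d items but X has %d columns.",
                         nrow(key), ncol(X)),
                 "rrscore_dim_error")
  }
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), key$item)) {
      stop_rrscore("Key items do not match the columns of X.",
                   "rrscore_validation_error")
    }
    X <- X[, key$item, drop = FALSE]
  }
  lo <- attr(key, "scale_min"); hi <- attr(key, "scale_max")
  if (anyNA(X) || any(X < lo | X > hi)) {
    stop_rrscore(sprintf("Responses must be complete and in [%d, %d].", lo, hi),
                 "rrscore_validation_error")
  }
  Xr <- X
  if (any(key$reversed)) {
    Xr[, key$reversed] <- lo + hi - X[, key$reversed, drop = FALSE]
  }
  factors <- unique(key$factor)
  S <- vapply(factors,
              function(f) rowMeans(Xr[, key$factor == f, drop = FALSE]),
              numeric(nrow(X)))
  S <- matrix(S, nrow = nrow(X), dimnames = list(rownames(X), factors))
  S
}

#' Read / write a scale key as CSV
#'
#' CSV columns: `item`, `factor`, `reversed`.
#'
#' @param path File path.
#' @param key A [scale_key()].
#' @param scale_min,scale_max Response bounds used when reading.
#' @return `read_scale_key()` returns a [scale_key()]; `write_scale_key()`
#'   returns `path` invisibly.
#' @export
read_scale_key <- function(path, scale_min = 1L, scale_max = 5L) {
  df <- readr::read_csv(path, col_types = readr::cols(
    item = readr::col_character(),
    factor = readr::col_character(),
    reversed = readr::col_logical()))
  scale_key(df$item, df$factor, df$reversed, scale_min, scale_max)
}

#' @rdname read_scale_key
#' @export
write_scale_key <- function(key, path) {
  stopifnot(inherits(key, "scale_key"))
  readr::write_csv(tibble::as_tibble(key), path)
  invisible(path)
}
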