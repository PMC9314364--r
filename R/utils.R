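# internal helpers: validation, pseudoinverse, permutations

stop_rrscore <- function(msg, class) {
  rlang::abort(msg, class = c(class, "rrscore_error"))
}

check_matrix <- function(x, name, min_rows = 1L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_rrscore(sprintf("`%s` must be a numeric matrix.", name), "rrscore_type_error")
  }
  if (nrow(x) < min_rows) {
    stop_rrscore(sprintf("`%s` must have at least %d rows.", name, min_rows),
                 "rrscore_dim_error")
  }
  x
}

check_conformable <- function(a, b, name_a, name_b, dim_a = 2L, dim_b = 1L) {
  if (dim(a)[dim_a] != dim(b)[dim_b]) {
    stop_rrscore(sprintf("Dimension mismatch: %s has %d %s but %s has %d %s.",
                         name_a, dim(a)[dim_a], c("rows", "columns")[dim_a],
                         name_b, dim(b)[dim_b], c("rows", "columns")[dim_b]),
                 "rrscore_dim_error")
  }
  invisible(NULL)
}

# Moore-Penrose least-squares solve of min ||Y - X C|| via SVD.
# Singular values below tol * max(d) are dropped (logged by callers).
pinv_lstsq <- function(X, Y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  if (!any(keep)) {
    return(list(C = matrix(0, ncol(X), ncol(Y)), rank = 0L))
  }
  C <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep])
  list(C = C, rank = sum(keep))
}

# all r! permutations of 1..r, lexicographic, as a matrix (r! x r)
all_permutations <- function(r) {
  if (r == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(r - 1L)
  out <- vector("list", r)
  for (k in seq_len(r)) {
    rest <- seq_len(r)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), r - 1L))
  }
  do.call(rbind, out)
}

# all 2^r sign patterns as a (2^r x r) matrix of +/-1
all_sign_patterns <- function(r) {
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), r)))
  dimnames(grid) <- NULL
  grid
}

format_ids <- function(ids, max_show = 5L) {
  shown <- utils::head(ids, max_show)
  extra <- length(ids) - length(shown)
  paste0(paste(shown, collapse = ", "),
         if (extra > 0) sprintf(" (and %d more)", extra))
}
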