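#' Unconstrained multivariate least squares
#'
#' Minimises the Frobenius residual `||Y - X C||^2` over `C`. Inputs are
#' expected to be standardised already (no intercept column: centring makes
#' intercepts implicit). When `X'X` is singular the Moore-Penrose
#' pseudoinverse solution is returned and a warning is logged.
#'
#' @param X `n x p` standardised predictor matrix.
#' @param Y `n x q` standardised response matrix.
#' @param tol Relative singular-value tolerance for the numerical rank.
#' @return `p x q` coefficient matrix.
#' @export
fit_ols <- function(X, Y, tol = 1e-10) {
  X <- check_matrix(X, "X", min_rows = 2L)
  Y <- check_matrix(Y, "Y", min_rows = 2L)
  if (nrow(X) != nrow(Y)) {
    stop_rrscore("X and Y must have the same number of rows.", "rrscore_dim_error")
  }
  sol <- pinv_lstsq(X, Y, tol = tol)
  if (sol$rank < ncol(X)) {
    rlang::warn(sprintf(
      "X'X is rank deficient (rank %d < %d columns); pseudoinverse solution used.",
      sol$rank, ncol(X)), class = "rrscore_rank_deficient")
  }
  dimnames(sol$C) <- list(colnames(X), colnames(Y))
  sol$C
}

#' Fit a reduced-rank regression model
#'
#' Solves `argmin_C ||Y - X C||^2 subject to rank(C) = r` on internally
#' standardised copies of `X` and `Y` (standardisers fitted here and stored,
#' so held-out data are transformed with training statistics). The closed
#' form factorises `C = B A'`: `A` holds the top-`r` right singular vectors of
#' the unconstrained fitted values `X C_ols`, and `B = C_ols A`. The `n x r`
#' score matrix `X B` is the low-dimensional representation optimised for
#' predicting the outcome battery.
#'
#' Columns are ordered by decreasing singular value of the fitted-value
#' decomposition and each column's sign is fixed so its largest-magnitude
#' item loading is positive, making the factorisation reproducible (it is
#' otherwise only identified up to signed permutation).
#'
#' @param X `n x p` item matrix (integer Likert responses or numeric).
#' @param Y `n x q` outcome matrix.
#' @param r Rank, `1 <= r <= min(p, q)`.
#' @param tol Relative singular-value tolerance.
#' @return An `rrr_model`: `B` (`p x r`), `A` (`q x r`), `rank`,
#'   `singular_values`, the two standardisers, and the training loss
#'   (standardised scale).
#' @export
fit_rrr <- function(X, Y, r, tol = 1e-10) {
  X <- check_matrix(X, "X", min_rows = 2L)
  Y <- check_matrix(Y, "Y", min_rows = 2L)
  if (nrow(X) != nrow(Y)) {
    stop_rrscore("X and Y must have the same number of rows.", "rrscore_dim_error")
  }
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r > min(ncol(X), ncol(Y)) ||
      r != round(r)) {
    stop_rrscore(sprintf("`r` must be an integer in [1, %d].",
                         min(ncol(X), ncol(Y))), "rrscore_rank_error")
  }
  r <- as.integer(r)
  x_std <- fit_standardizer(X)
  y_std <- fit_standardizer(Y)
  Xs <- apply_standardizer(X, x_std)
  Ys <- apply_standardizer(Y, y_std)
  C_ols <- fit_ols(Xs, Ys, tol = tol)
  Fhat <- Xs %*% C_ols
  sv <- svd(Fhat, nu = 0L, nv = r)
  A <- sv$v
  B <- C_ols %*% A
  # sign convention: dominant item loading positive per dimension
  for (k in seq_len(r)) {
    s <- sign(B[which.max(abs(B[, k])), k])
    if (s < 0) {
      B[, k] <- -B[, k]
      A[, k] <- -A[, k]
    }
  }
  dims <- sprintf("dim_%d", seq_len(r))
  dimnames(B) <- list(colnames(X), dims)
  dimnames(A) <- list(colnames(Y), dims)
  loss <- sum((Ys - Xs %*% tcrossprod(B, A))^2)
  structure(list(B = B, A = A, rank = r,
                 singular_values = sv$d[seq_len(r)],
                 x_standardizer = x_std, y_standardizer = y_std,
                 training_loss = loss,
                 n_train = nrow(X)),
            class = "rrr_model")
}

#' Project new responses onto a fitted representation
#'
#' Standardises `X_new` with the model's stored training standardiser and
#' maps it into the model's low-dimensional space. For a reduced-rank model
#' the result is the supervised score matrix `X B`; for a principal-component
#' model it is the component scores; for a [scale_key()] it is the
#' unit-weight factor scores.
#'
#' @param object A fitted `rrr_model`, `pcr_model`, or a [scale_key()].
#' @param X_new `m x p` response matrix.
#' @param ... Unused.
#' @return `m x r` score matrix.
#' @export
project <- function(object, X_new, ...) UseMethod("project")

#' @rdname project
#' @export
project.rrr_model <- function(object, X_new, ...) {
  X_new <- check_matrix(X_new, "X_new")
  apply_standardizer(X_new, object$x_standardizer) %*% object$B
}

#' @rdname project
#' @export
project.pcr_model <- function(object, X_new, ...) {
  X_new <- check_matrix(X_new, "X_new")
  apply_standardizer(X_new, object$x_standardizer) %*% object$loadings
}

#' @rdname project
#' @export
project.scale_key <- function(object, X_new, ...) {
  score_scales(X_new, object)
}

#' Predict outcomes from a reduced-rank model
#'
#' Projects the responses, multiplies by the outcome coefficients, and maps
#' back to the training outcome scale.
#'
#' @param object A fitted `rrr_model`.
#' @param newdata `m x p` response matrix.
#' @param ... Unused.
#' @return `m x q` predicted outcome matrix.
#' @export
predict.rrr_model <- function(object, newdata, ...) {
  S <- project(object, newdata)
  invert_standardizer(tcrossprod(S, object$A), object$y_standardizer)
}

#' Fit a principal-component regression model
#'
#' The unsupervised benchmark: reduce standardised items to their leading
#' `r` principal axes (learned on the training data only), then regress each
#' standardised outcome on the component scores.
#'
#' @param X `n x p` item matrix.
#' @param Y `n x q` outcome matrix.
#' @param r Number of components, `1 <= r <= p`.
#' @return A `pcr_model` with orthonormal `loadings` (`p x r`), outcome
#'   `coefficients` (`q x r`) and the standardisers.
#' @export
fit_pcr <- function(X, Y, r) {
  X <- check_matrix(X, "X", min_rows = 2L)
  Y <- check_matrix(Y, "Y", min_rows = 2L)
  if (nrow(X) != nrow(Y)) {
    stop_rrscore("X and Y must have the same number of rows.", "rrscore_dim_error")
  }
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r > ncol(X) || r != round(r)) {
    stop_rrscore(sprintf("`r` must be an integer in [1, %d].", ncol(X)),
                 "rrscore_rank_error")
  }
  r <- as.integer(r)
  x_std <- fit_standardizer(X)
  y_std <- fit_standardizer(Y)
  Xs <- apply_standardizer(X, x_std)
  Ys <- apply_standardizer(Y, y_std)
  sv <- svd(Xs, nu = 0L, nv = r)
  V <- sv$v
  for (k in seq_len(r)) {
    s <- sign(V[which.max(abs(V[, k])), k])
    if (s < 0) V[, k] <- -V[, k]
  }
  S <- Xs %*% V
  coef <- t(fit_ols(S, Ys))
  dims <- sprintf("pc_%d", seq_len(r))
  dimnames(V) <- list(colnames(X), dims)
  dimnames(coef) <- list(colnames(Y), dims)
  structure(list(loadings = V, coefficients = coef,
                 singular_values = sv$d[seq_len(r)],
                 x_standardizer = x_std, y_standardizer = y_std,
                 rank = r, n_train = nrow(X)),
            class = "pcr_model")
}

#' @rdname fit_pcr
#' @param object A fitted `pcr_model`.
#' @param newdata `m x p` response matrix.
#' @param ... Unused.
#' @export
predict.pcr_model <- function(object, newdata, ...) {
  S <- project(object, newdata)
  invert_standardizer(tcrossprod(S, object$coefficients), object$y_standardizer)
}

#' Multi-start alternating-least-squares check for reduced-rank fits
#'
#' An independent, iterative solver for the rank-constrained least-squares
#' problem, intended for verifying the closed-form [fit_rrr()] solution on
#' small instances (`p, q <= 12`). Alternates exact minimisation over the two
#' factors from several random starts and keeps the best coefficient matrix.
#'
#' @param X,Y Data matrices (standardised internally with the same
#'   conventions as [fit_rrr()]).
#' @param r Rank.
#' @param restarts Number of random starts.
#' @param seed Integer seed.
#' @param max_iter,rel_tol Convergence controls.
#' @return List with the best `C` (`p x q`, standardised scale), its `loss`,
#'   and the vector of per-start losses.
#' @export
rrr_brute_oracle <- function(X, Y, r, restarts = 10L, seed = 1L,
                             max_iter = 500L, rel_tol = 1e-12) {
  X <- check_matrix(X, "X", min_rows = 2L)
  Y <- check_matrix(Y, "Y", min_rows = 2L)
  if (ncol(X) > 12L || ncol(Y) > 12L) {
    stop_rrscore("Oracle is for small instances only (p, q <= 12).",
                 "rrscore_dim_error")
  }
  x_std <- fit_standardizer(X)
  y_std <- fit_standardizer(Y)
  Xs <- apply_standardizer(X, x_std)
  Ys <- apply_standardizer(Y, y_std)
  best <- list(loss = Inf, C = NULL)
  losses <- numeric(restarts)
  withr::with_seed(seed, {
    for (s in seq_len(restarts)) {
      A <- qr.Q(qr(matrix(rnorm(ncol(Ys) * r), ncol(Ys), r)))
      loss_prev <- Inf
      loss <- Inf
      C <- NULL
      for (it in seq_len(max_iter)) {
        # B-step: exact for fixed orthonormal A
        B <- pinv_lstsq(Xs, Ys %*% A)$C
        C <- tcrossprod(B, A)
        loss <- sum((Ys - Xs %*% C)^2)
        if (is.finite(loss_prev) && abs(loss_prev - loss) <=
            rel_tol * max(1, abs(loss_prev))) break
        loss_prev <- loss
        # A-step: exact for fixed scores Xs B, then re-orthonormalised
        S <- Xs %*% B
        A <- qr.Q(qr(t(pinv_lstsq(S, Ys)$C)))
      }
      losses[s] <- loss
      if (loss < best$loss) best <- list(loss = loss, C = C)
    }
  })
  list(C = best$C, loss = best$loss, losses = losses)
}

#' Residual loss of a coefficient matrix on standardised data
#'
#' `||Y_s - X_s C||^2` where the standardisation is fitted on `X`, `Y`
#' themselves; the scale on which [fit_rrr()] training losses and
#' [rrr_brute_oracle()] losses are comparable.
#'
#' @param X,Y Data matrices.
#' @param C `p x q` coefficient matrix on the standardised scale.
#' @return Scalar loss.
#' @export
rrr_loss <- function(X, Y, C) {
  Xs <- apply_standardizer(X, fit_standardizer(X))
  Ys <- apply_standardizer(Y, fit_standardizer(Y))
  sum((Ys - Xs %*% C)^2)
}

#' @export
print.rrr_model <- function(x, ...) {
  cat(sprintf("<rrr_model> rank %d: %d items -> %d dimensions -> %d outcomes (n = %d)\n",
              x$rank, nrow(x$B), x$rank, nrow(x$A), x$n_train))
  cat("  singular values:", paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model> %d leading components of %d items -> %d outcomes (n = %d)\n",
              x$rank, nrow(x$loadings), nrow(x$coefficients), x$n_train))
  invisible(x)
}

#' Tidy a reduced-rank model
#'
#' Item loadings (`B`) and outcome coefficients (`A`) in long format.
#'
#' @param x An `rrr_model`.
#' @param matrix Which factor to tidy: `"B"` (item loadings) or `"A"`
#'   (outcome coefficients).
#' @param ... Unused.
#' @return A tibble with columns `term`, `dimension`, `value`.
#' @method tidy rrr_model
#' @export
tidy.rrr_model <- function(x, matrix = c("B", "A"), ...) {
  matrix <- match.arg(matrix)
  M <- x[[matrix]]
  tibble::tibble(term = rep(rownames(M), ncol(M)),
                 dimension = rep(colnames(M), each = nrow(M)),
                 value = as.vector(M))
}

#' @rdname tidy.rrr_model
#' @method glance rrr_model
#' @export
glance.rrr_model <- function(x, ...) {
  tibble::tibble(rank = x$rank,
                 n_items = nrow(x$B),
                 n_outcomes = nrow(x$A),
                 n_train = x$n_train,
                 training_loss = x$training_loss,
                 leading_singular_value = x$singular_values[1])
}
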