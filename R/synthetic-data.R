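#' Discretise continuous scores onto a 1-5 Likert scale
#'
#' Values below the first cutpoint map to 1; values in `[t_j, t_{j+1})` map to
#' `j + 1`; values at or above the last cutpoint map to 5.
#'
#' @param continuous Numeric matrix (or vector) of continuous item scores.
#' @param thresholds Strictly increasing numeric vector of length 4.
#' @return Integer matrix of the same shape with entries in 1..5.
#' @export
latent_to_likert <- function(continuous, thresholds) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop_rrscore("`thresholds` must be 4 strictly increasing values.",
                 "rrscore_spec_error")
  }
  was_matrix <- is.matrix(continuous)
  out <- findInterval(continuous, thresholds) + 1L
  if (was_matrix) {
    out <- matrix(out, nrow(continuous), ncol(continuous),
                  dimnames = dimnames(continuous))
  }
  out
}

#' Generate outcomes linear in latent traits
#'
#' `Y = Z %*% t(weights) + noise`, with independent Gaussian noise per
#' outcome. With unit-variance latents the population R-squared of outcome `j`
#' is `rowSS(weights)[j] / (rowSS(weights)[j] + noise_sd[j]^2)`.
#'
#' @param Z `n x k` latent matrix.
#' @param weights `q x k` outcome weight matrix.
#' @param noise_sd Nonnegative noise sd(s), recycled to `q`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return `n x q` outcome matrix.
#' @export
generate_outcomes <- function(Z, weights, noise_sd, seed = NULL) {
  Z <- check_matrix(Z, "Z")
  weights <- check_matrix(weights, "weights")
  check_conformable(Z, t(weights), "Z", "weights")
  q <- nrow(weights)
  noise_sd <- rep_len(noise_sd, q)
  if (any(noise_sd < 0)) {
    stop_rrscore("`noise_sd` must be nonnegative.", "rrscore_spec_error")
  }
  gen <- function() {
    E <- matrix(rnorm(nrow(Z) * q), nrow(Z), q)
    Z %*% t(weights) + sweep(E, 2L, noise_sd, `*`)
  }
  Y <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  colnames(Y) <- sprintf("outcome_%02d", seq_len(q))
  rownames(Y) <- rownames(Z)
  Y
}

#' Generate a synthetic cohort
#'
#' Draws latent traits per participant (standard normal, optionally correlated
#' via the spec's `latent_corr` Cholesky factor), forms continuous item scores
#' `loadings %*% latent + noise`, discretises them with [latent_to_likert()],
#' and generates outcomes with [generate_outcomes()]. Deterministic given the
#' spec's seed.
#'
#' @param spec A [generator_spec()].
#' @param id_prefix Prefix for generated participant identifiers.
#' @return A `cohort`: list with `participant_ids`, integer item matrix `X`
#'   (`n x p`, entries 1..5), outcome matrix `Y` (`n x q`), `X_retest`
#'   (`NULL` until [generate_retest()]), and the true latents `Z_true`
#'   (kept for diagnostics/tests only; no fitting function reads it).
#' @export
generate_cohort <- function(spec, id_prefix = "P") {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_participants
  withr::with_seed(spec$seed, {
    Z <- matrix(rnorm(n * spec$n_latent), n, spec$n_latent)
    if (!is.null(spec$latent_corr)) {
      Z <- Z %*% chol(spec$latent_corr)
    }
    U <- Z %*% t(spec$item_loadings) +
      spec$item_noise_sd * matrix(rnorm(n * spec$n_items), n, spec$n_items)
    X <- latent_to_likert(U, spec$likert_thresholds)
    ids <- sprintf("%s%06d", id_prefix, seq_len(n))
    dimnames(X) <- list(ids, sprintf("item_%03d", seq_len(spec$n_items)))
    rownames(Z) <- ids
    Y <- generate_outcomes(Z, spec$outcome_weights, spec$outcome_noise_sd)
    new_cohort(ids, X, Y, Z_true = Z)
  })
}

new_cohort <- function(participant_ids, X, Y, X_retest = NULL, Z_true = NULL,
                       Z_retest = NULL) {
  structure(list(participant_ids = participant_ids,
                 X = X, Y = Y,
                 X_retest = X_retest,
                 Z_true = Z_true,
                 Z_retest = Z_retest),
            class = "cohort")
}

validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  X <- cohort$X; Y <- cohort$Y
  if (anyNA(X) || anyNA(Y)) {
    stop_rrscore("Cohort contains missing values; complete responses required.",
                 "rrscore_validation_error")
  }
  if (any(X < 1 | X > 5) || any(X != round(X))) {
    stop_rrscore("Item responses must be integers in 1..5.",
                 "rrscore_validation_error")
  }
  if (anyDuplicated(cohort$participant_ids)) {
    stop_rrscore("Duplicate participant identifiers.", "rrscore_validation_error")
  }
  invisible(cohort)
}

#' Attach a retest administration to a cohort
#'
#' For a random subset of participants, a second latent vector is drawn as
#' `Z2 = s * Z1 + sqrt(1 - s^2) * fresh noise` (per-latent stability `s`), and
#' items are regenerated through the same loadings, item noise and cutpoints.
#' With `s = 1` and zero item noise the retest responses reproduce the first
#' administration exactly; with `s = 0` the two administrations are
#' independent.
#'
#' @param cohort A cohort carrying `Z_true`.
#' @param spec The [generator_spec()] used to build the cohort.
#' @param fraction Fraction of participants retested, in `(0, 1]`.
#' @param seed Integer seed for subset choice and fresh noise.
#' @return The cohort with `X_retest` (rownames identify the retested subset)
#'   and `Z_retest` attached.
#' @export
generate_retest <- function(cohort, spec, fraction = 1, seed = spec$seed + 1L) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "generator_spec"))
  if (is.null(cohort$Z_true)) {
    stop_rrscore("Cohort lacks `Z_true`; retest requires the generating latents.",
                 "rrscore_validation_error")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop_rrscore("`fraction` must lie in (0, 1].", "rrscore_spec_error")
  }
  n <- nrow(cohort$X)
  withr::with_seed(seed, {
    n_rt <- max(1L, round(fraction * n))
    idx <- sort(sample.int(n, n_rt))
    Z1 <- cohort$Z_true[idx, , drop = FALSE]
    s <- rep_len(spec$retest_stability, spec$n_latent)
    E <- matrix(rnorm(n_rt * spec$n_latent), n_rt, spec$n_latent)
    Z2 <- sweep(Z1, 2L, s, `*`) + sweep(E, 2L, sqrt(1 - s^2), `*`)
    U2 <- Z2 %*% t(spec$item_loadings) +
      spec$item_noise_sd * matrix(rnorm(n_rt * spec$n_items), n_rt, spec$n_items)
    X2 <- latent_to_likert(U2, spec$likert_thresholds)
    dimnames(X2) <- list(rownames(cohort$X)[idx], colnames(cohort$X))
    rownames(Z2) <- rownames(X2)
    cohort$X_retest <- X2
    cohort$Z_retest <- Z2
  })
  cohort
}

#' Split a cohort into disjoint subcohorts by row index
#'
#' @param cohort A cohort.
#' @param idx Integer row indices for the first part.
#' @return List of two cohorts, `$a` (rows `idx`) and `$b` (the rest).
#' @export
split_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$X)
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1 | idx > n)) {
    stop_rrscore("`idx` out of range.", "rrscore_dim_error")
  }
  take <- function(rows) {
    ids <- cohort$participant_ids[rows]
    sub <- new_cohort(ids,
                      cohort$X[rows, , drop = FALSE],
                      cohort$Y[rows, , drop = FALSE],
                      Z_true = if (!is.null(cohort$Z_true))
                        cohort$Z_true[rows, , drop = FALSE])
    if (!is.null(cohort$X_retest)) {
      keep <- rownames(cohort$X_retest) %in% ids
      if (any(keep)) {
        sub$X_retest <- cohort$X_retest[keep, , drop = FALSE]
        if (!is.null(cohort$Z_retest))
          sub$Z_retest <- cohort$Z_retest[keep, , drop = FALSE]
      }
    }
    sub
  }
  list(a = take(idx), b = take(setdiff(seq_len(n), idx)))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d items, %d outcomes%s%s\n",
              nrow(x$X), ncol(x$X), ncol(x$Y),
              if (!is.null(x$X_retest))
                sprintf(", retest n = %d", nrow(x$X_retest)) else "",
              if (!is.null(x$Z_true)) ", latents retained" else ""))
  invisible(x)
}

#' @method as_tibble cohort
#' @export
as_tibble.cohort <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(participant_id = x$participant_ids),
                   tibble::as_tibble(x$X), tibble::as_tibble(x$Y))
}
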