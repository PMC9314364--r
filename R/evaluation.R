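#' Out-of-sample R-squared
#'
#' `1 - SSE/SST` with `SST` taken about the mean of the observed holdout
#' values (the stricter convention; set `center` to use an external mean,
#' e.g. the training mean). Can be negative when predictions are worse than
#' the holdout mean.
#'
#' @param y Observed values (length >= 2, not constant).
#' @param y_hat Predicted values, same length.
#' @param center Optional mean to use in `SST`; default `mean(y)`.
#' @return Scalar R-squared.
#' @export
r_squared <- function(y, y_hat, center = NULL) {
  if (length(y) != length(y_hat)) {
    stop_rrscore("`y` and `y_hat` must have equal length.", "rrscore_dim_error")
  }
  if (length(y) < 2L) {
    stop_rrscore("Need at least 2 observations.", "rrscore_dim_error")
  }
  mu <- center %||% mean(y)
  sst <- sum((y - mu)^2)
  if (sst == 0) {
    stop_rrscore("`y` is constant; R-squared undefined.",
                 "rrscore_constant_column_error")
  }
  1 - sum((y - y_hat)^2) / sst
}

#' Mean absolute error
#'
#' @param y Observed values (nonempty).
#' @param y_hat Predicted values, same length.
#' @return Scalar MAE.
#' @export
mean_abs_error <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop_rrscore("`y` and `y_hat` must have equal length.", "rrscore_dim_error")
  }
  if (length(y) == 0L) {
    stop_rrscore("Empty input.", "rrscore_dim_error")
  }
  mean(abs(y - y_hat))
}

#' Paired t-test on per-participant absolute errors
#'
#' Predictions of two models for the same participants are paired; comparing
#' the models collapses to a one-sample two-sided t-test of the differences
#' `d_i = |e1_i| - |e2_i|` against zero mean. Degenerate inputs follow
#' documented conventions: all differences exactly zero returns `t = 0, p = 1`;
#' zero variance with nonzero mean returns `t = +/-Inf, p = 0`.
#'
#' @param abs_err_model1,abs_err_model2 Absolute errors of the two models for
#'   the same participants (equal length >= 3).
#' @return List with `t`, `p`, `mean_diff`.
#' @export
paired_error_ttest <- function(abs_err_model1, abs_err_model2) {
  if (length(abs_err_model1) != length(abs_err_model2)) {
    stop_rrscore("Error vectors must be paired (equal length).", "rrscore_dim_error")
  }
  if (length(abs_err_model1) < 3L) {
    stop_rrscore("Need at least 3 pairs.", "rrscore_dim_error")
  }
  d <- abs_err_model1 - abs_err_model2
  m <- mean(d)
  # degenerate-variance conventions (tolerance guards float cancellation in d)
  if (sd(d) <= 1e-12 * max(abs(m), max(abs(d)), 1)) {
    if (abs(m) <= 1e-12 * max(abs(d), 1)) return(list(t = 0, p = 1, mean_diff = m))
    return(list(t = sign(m) * Inf, p = 0, mean_diff = m))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = m)
}

#' Benjamini-Hochberg step-up decisions
#'
#' Rejects the hypotheses whose BH-adjusted p-value is at most `alpha`,
#' equivalent to the step-up rule rejecting the `k` smallest p-values where
#' `k = max{ i : p_(i) <= i * alpha / m }`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target false-discovery rate, in `(0, 1)`.
#' @return Logical rejection vector, same order as `p_values`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_rrscore("`alpha` must lie in (0, 1).", "rrscore_spec_error")
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_rrscore("p-values must lie in [0, 1].", "rrscore_validation_error")
  }
  p.adjust(p_values, method = "BH") <= alpha
}

#' Cross-validation scheme for the two-stage evaluation
#'
#' @param n_folds Number of folds over the evaluation cohort (default 4).
#' @param seed Integer seed for fold assignment.
#' @param models Representations to compare: any of `"rrr"` (supervised
#'   reduced-rank scores), `"scales"` (unit-weight factor scores), `"pcr"`
#'   (leading principal components), `"external"` (a pre-fitted projection
#'   passed via `prefit`, the transfer design where the item-to-dimension map
#'   is carried over from an earlier study).
#' @param prefit Optional pre-fitted `rrr_model`/`pcr_model` for
#'   `"external"`.
#' @param scale_key Optional [scale_key()] for `"scales"`; defaults to the
#'   synthetic questionnaire key.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(n_folds = 4L, seed = 1L,
                      models = c("rrr", "scales", "pcr"),
                      prefit = NULL, scale_key = NULL) {
  if (!is.numeric(n_folds) || n_folds < 2L) {
    stop_rrscore("`n_folds` must be at least 2.", "rrscore_spec_error")
  }
  models <- match.arg(models, c("rrr", "scales", "pcr", "external"),
                      several.ok = TRUE)
  if ("external" %in% models && is.null(prefit)) {
    stop_rrscore("`models` includes \"external\" but no `prefit` projection given.",
                 "rrscore_spec_error")
  }
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 models = models, prefit = prefit, scale_key = scale_key),
            class = "cv_scheme")
}

#' Two-stage cross-validated model comparison
#'
#' Stage 1 learns each representation on the training cohort only: the
#' reduced-rank item-to-dimension map for `"rrr"`, the leading principal axes
#' for `"pcr"`, the unit-weight scale key for `"scales"` (no training data
#' needed), or a pre-fitted projection for `"external"`. Stage 2 evaluates on
#' an independent test cohort with `n_folds`-fold cross-validation: outcome
#' coefficients are re-learned per fold on the in-fold part (e.g. 600 of 800
#' participants under the default fourfold scheme) by ordinary regression of
#' each outcome on the `r` representation scores, and R-squared / MAE are
#' measured on the held-out quarter (200 of 800). Every test participant is
#' held out exactly once, so per-participant absolute errors are paired
#' across models.
#'
#' @param train Training cohort (may be `NULL` if no requested model needs
#'   one).
#' @param test Evaluation cohort, disjoint from `train` by participant id.
#' @param scheme A [cv_scheme()].
#' @param r Representation dimension (default 5).
#' @return An `evaluation_report` with tibbles `folds` (outcome x model x
#'   fold R-squared and MAE), `errors` (per-participant absolute errors),
#'   `summary` (per outcome x model: mean R-squared across folds, pooled
#'   MAE), `comparisons` (pairwise paired t-tests with BH-FDR decisions and
#'   percent R-squared / MAE changes), and `aggregate` (mean R-squared per
#'   model).
#' @export
two_stage_cv <- function(train, test, scheme, r = 5L) {
  stopifnot(inherits(scheme, "cv_scheme"))
  validate_cohort(test)
  needs_train <- any(scheme$models %in% c("rrr", "pcr"))
  if (needs_train) {
    if (is.null(train)) {
      stop_rrscore("Requested models need a training cohort.", "rrscore_spec_error")
    }
    validate_cohort(train)
    overlap <- intersect(train$participant_ids, test$participant_ids)
    if (length(overlap)) {
      stop_rrscore(sprintf("Train and test cohorts overlap: %s.",
                           format_ids(overlap)), "rrscore_validation_error")
    }
  }
  n <- nrow(test$X)
  k <- scheme$n_folds
  if (k > n) {
    stop_rrscore("`n_folds` exceeds the test-cohort size.", "rrscore_spec_error")
  }

  projectors <- lapply(stats::setNames(scheme$models, scheme$models), function(m) {
    switch(m,
      rrr = fit_rrr(train$X, train$Y, r),
      pcr = fit_pcr(train$X, train$Y, r),
      scales = scheme$scale_key %||% default_scale_key(ncol(test$X)),
      external = scheme$prefit)
  })
  scores <- lapply(projectors, project, X_new = test$X)

  # seeded shuffle, then folds of near-equal size (remainder spread one each)
  fold <- integer(n)
  withr::with_seed(scheme$seed, {
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  })

  outcomes <- colnames(test$Y) %||% sprintf("outcome_%02d", seq_len(ncol(test$Y)))
  fold_rows <- list()
  err_rows <- list()
  for (m in scheme$models) {
    S <- scores[[m]]
    for (f in seq_len(k)) {
      hold <- fold == f
      Sin <- cbind(1, S[!hold, , drop = FALSE])
      fit <- lm.fit(Sin, test$Y[!hold, , drop = FALSE])
      coef <- fit$coefficients
      coef[is.na(coef)] <- 0
      pred <- cbind(1, S[hold, , drop = FALSE]) %*% coef
      yh <- test$Y[hold, , drop = FALSE]
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        outcome = outcomes, model = m, fold = f,
        r2 = vapply(seq_along(outcomes),
                    function(j) r_squared(yh[, j], pred[, j]), numeric(1)),
        mae = vapply(seq_along(outcomes),
                     function(j) mean_abs_error(yh[, j], pred[, j]), numeric(1)),
        n_holdout = sum(hold))
      err_rows[[length(err_rows) + 1L]] <- tibble::tibble(
        participant_id = rep(test$participant_ids[hold], length(outcomes)),
        outcome = rep(outcomes, each = sum(hold)),
        model = m, fold = f,
        abs_error = as.vector(abs(yh - pred)))
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  errors <- dplyr::bind_rows(err_rows)

  summary <- folds |>
    dplyr::group_by(.data$outcome, .data$model) |>
    dplyr::summarise(r2 = mean(.data$r2),
                     mae = stats::weighted.mean(.data$mae, .data$n_holdout),
                     .groups = "drop")

  comparisons <- cv_comparisons(summary, errors, scheme$models)

  aggregate <- summary |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), mean_mae = mean(.data$mae),
                     .groups = "drop")

  structure(list(folds = folds, errors = errors, summary = summary,
                 comparisons = comparisons, aggregate = aggregate,
                 models = scheme$models, n_folds = k, r = r,
                 seed = scheme$seed, n_test = n),
            class = "evaluation_report")
}

# pairwise paired-error t-tests (errors pooled over folds: each participant
# contributes one holdout error) with BH-FDR within each model pair
cv_comparisons <- function(summary, errors, models) {
  if (length(models) < 2L) {
    return(tibble::tibble(outcome = character(), model_1 = character(),
                          model_2 = character(), mean_abs_err_diff = numeric(),
                          t = numeric(), p = numeric(), fdr_reject = logical(),
                          pct_r2_change = numeric(), pct_mae_change = numeric()))
  }
  pairs <- utils::combn(models, 2L, simplify = FALSE)
  wide <- errors |>
    dplyr::select("participant_id", "outcome", "model", "abs_error") |>
    tidyr::pivot_wider(names_from = "model", values_from = "abs_error")
  perf <- summary |>
    tidyr::pivot_wider(names_from = "model", values_from = c("r2", "mae"))
  out <- purrr::map_dfr(pairs, function(pr) {
    res <- wide |>
      dplyr::group_by(.data$outcome) |>
      dplyr::group_modify(function(df, key) {
        tt <- paired_error_ttest(df[[pr[1]]], df[[pr[2]]])
        tibble::tibble(mean_abs_err_diff = tt$mean_diff, t = tt$t, p = tt$p)
      }) |>
      dplyr::ungroup()
    res$fdr_reject <- bh_fdr(res$p, 0.05)
    res$model_1 <- pr[1]
    res$model_2 <- pr[2]
    res |>
      dplyr::left_join(perf, by = "outcome") |>
      dplyr::mutate(
        pct_r2_change = 100 * (.data[[paste0("r2_", pr[1])]] -
                                 .data[[paste0("r2_", pr[2])]]) /
          abs(.data[[paste0("r2_", pr[2])]]),
        pct_mae_change = 100 * (.data[[paste0("mae_", pr[1])]] -
                                  .data[[paste0("mae_", pr[2])]]) /
          .data[[paste0("mae_", pr[2])]]) |>
      dplyr::select("outcome", "model_1", "model_2", "mean_abs_err_diff",
                    "t", "p", "fdr_reject", "pct_r2_change", "pct_mae_change")
  })
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d outcomes x %s, %d-fold CV on n = %d\n",
              length(unique(x$summary$outcome)),
              paste(x$models, collapse = "/"), x$n_folds, x$n_test))
  print(x$aggregate)
  invisible(x)
}

#' Tidy / glance an evaluation report
#'
#' `tidy()` returns the per-fold results; `glance()` the per-model aggregate
#' out-of-sample performance.
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$folds

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) x$aggregate

#' Write an evaluation report to tidy CSV files
#'
#' Writes `folds.csv` (outcome, model, fold, r2, mae) and `summary.csv`
#' (per-outcome performance per model plus the pairwise comparison columns).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$folds, file.path(dir, "folds.csv"))
  wide <- report$summary |>
    tidyr::pivot_wider(names_from = "model", values_from = c("r2", "mae"))
  readr::write_csv(wide, file.path(dir, "summary.csv"))
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  invisible(dir)
}
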