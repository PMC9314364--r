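#' Configure an end-to-end study run
#'
#' Exactly one input source must be given: a [generator_spec()] (synthetic
#' cohort) or CSV file paths. Two designs are supported. `"study1"` splits
#' the cohort into a training part (where the representation is learned) and
#' an independent test part evaluated by [two_stage_cv()], then runs the
#' reproducibility / reliability / divergence diagnostics. `"transfer"`
#' evaluates a previously fitted projection on a new sample with new
#' outcomes: the item-to-dimension map is frozen and only the per-fold
#' outcome coefficients are learned on the new data.
#'
#' @param generator Optional [generator_spec()].
#' @param items_csv,outcomes_csv,retest_csv Optional file inputs.
#' @param n_test Size of the held-out evaluation cohort (default 800).
#' @param r Representation dimension (default 5).
#' @param n_folds Folds of the evaluation stage (default 4).
#' @param seed Integer seed for splitting and fold assignment.
#' @param models Representations to compare (see [cv_scheme()]).
#' @param study_mode `"study1"` or `"transfer"`.
#' @param prefit A fitted `rrr_model` or a directory written by
#'   [write_rrr_model()]; required in transfer mode.
#' @param scale_key Optional [scale_key()]; defaults to the synthetic key.
#' @param retest_fraction Fraction of test participants given a second
#'   administration when generating synthetically (default 0.5).
#' @param output_dir Optional directory; when given, all result tables, the
#'   fitted model and a manifest are written there.
#' @return A `study_config`.
#' @export
study_config <- function(generator = NULL,
                         items_csv = NULL, outcomes_csv = NULL, retest_csv = NULL,
                         n_test = 800L, r = 5L, n_folds = 4L, seed = 1L,
                         models = c("rrr", "scales", "pcr"),
                         study_mode = c("study1", "transfer"),
                         prefit = NULL, scale_key = NULL,
                         retest_fraction = 0.5,
                         output_dir = NULL) {
  study_mode <- match.arg(study_mode)
  has_gen <- !is.null(generator)
  has_files <- !is.null(items_csv) || !is.null(outcomes_csv)
  if (has_gen == has_files) {
    stop_rrscore("Provide exactly one of: a generator spec, or item/outcome files.",
                 "rrscore_spec_error")
  }
  if (has_files && (is.null(items_csv) || is.null(outcomes_csv))) {
    stop_rrscore("File input needs both `items_csv` and `outcomes_csv`.",
                 "rrscore_spec_error")
  }
  if (study_mode == "transfer" && is.null(prefit)) {
    stop_rrscore("Transfer mode requires a pre-fitted model (`prefit`).",
                 "rrscore_spec_error")
  }
  structure(list(generator = generator, items_csv = items_csv,
                 outcomes_csv = outcomes_csv, retest_csv = retest_csv,
                 n_test = as.integer(n_test), r = as.integer(r),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 models = models, study_mode = study_mode, prefit = prefit,
                 scale_key = scale_key, retest_fraction = retest_fraction,
                 output_dir = output_dir),
            class = "study_config")
}

#' Run a configured study end to end
#'
#' In `"study1"` mode: load or generate the cohort, split off `n_test`
#' participants as the independent evaluation cohort, learn each requested
#' representation on the remainder, run the two-stage cross-validated
#' comparison, and compute diagnostics (split-half reproducibility of the
#' projection; and, when a retest administration exists, test-retest
#' reliability plus the convergence/divergence analysis against the
#' unit-weight scale scores). In `"transfer"` mode the whole sample is the
#' evaluation cohort and the frozen `prefit` projection is compared against
#' the scale-score baseline.
#'
#' All results are returned as tibble-valued components and, when
#' `output_dir` is set, written as CSVs with a `manifest.json` capturing the
#' seed, configuration hash and package version; a rerun with the same
#' configuration and seed reproduces the outputs byte for byte.
#'
#' @param config A [study_config()].
#' @return A `study_result` list: `evaluation` (an `evaluation_report`),
#'   `model` (the fitted or transferred `rrr_model`), `reliability`,
#'   `reproducibility`, `divergence`, and `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  prefit <- config$prefit
  if (is.character(prefit)) prefit <- read_rrr_model(prefit)

  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator)
  } else {
    cohort <- read_cohort(config$items_csv, config$outcomes_csv, config$retest_csv)
  }

  n <- nrow(cohort$X)
  if (config$study_mode == "study1") {
    if (config$n_test >= n) {
      stop_rrscore("`n_test` must be smaller than the cohort.", "rrscore_spec_error")
    }
    test_idx <- withr::with_seed(config$seed, sample.int(n, config$n_test))
    parts <- split_cohort(cohort, test_idx)
    test <- parts$a
    train <- parts$b
    if (!is.null(config$generator) && config$retest_fraction > 0 &&
        !is.null(test$Z_true)) {
      test <- generate_retest(test, config$generator,
                              fraction = config$retest_fraction,
                              seed = config$seed + 211L)
    }
    scheme <- cv_scheme(config$n_folds, config$seed, config$models,
                        scale_key = config$scale_key)
  } else {
    test <- cohort
    train <- NULL
    models <- unique(c("external", setdiff(config$models, c("rrr", "pcr"))))
    scheme <- cv_scheme(config$n_folds, config$seed, models,
                        prefit = prefit, scale_key = config$scale_key)
  }

  evaluation <- two_stage_cv(train, test, scheme, config$r)

  model <- if (config$study_mode == "study1") {
    fit_rrr(train$X, train$Y, config$r)
  } else {
    prefit
  }

  reliability <- NULL
  divergence <- NULL
  reproducibility <- NULL
  key <- config$scale_key %||% default_scale_key(ncol(test$X))

  if (config$study_mode == "study1") {
    n_tr <- nrow(train$X)
    half_idx <- withr::with_seed(config$seed + 97L, sample.int(n_tr, n_tr %/% 2))
    halves <- split_cohort(train, half_idx)
    reproducibility <- split_half_reproducibility(halves$a, halves$b,
                                                  test$X, config$r)
    retest_source <- if (!is.null(test$X_retest)) test else cohort
    if (!is.null(retest_source$X_retest)) {
      rt_ids <- rownames(retest_source$X_retest)
      X_t1 <- retest_source$X[rt_ids, , drop = FALSE]
      X_t2 <- retest_source$X_retest
      pf_rel <- test_retest_reliability(model, X_t1, X_t2)
      ffm_rel <- test_retest_reliability(key, X_t1, X_t2)
      reliability <- tibble::tibble(
        dimension = seq_along(pf_rel),
        rrr = unname(pf_rel),
        scales = unname(ffm_rel))
      divergence <- divergence_analysis(
        score_scales(X_t1, key), score_scales(X_t2, key),
        project(model, X_t1), project(model, X_t2))
    }
  }

  manifest <- list(
    package = "rrscore",
    version = as.character(utils::packageVersion("rrscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    study_mode = config$study_mode,
    models = evaluation$models,
    rank = config$r,
    n_folds = config$n_folds,
    n_train = if (!is.null(train)) nrow(train$X) else 0L,
    n_test = nrow(test$X),
    config_hash = config_hash(config))

  result <- structure(list(evaluation = evaluation, model = model,
                           reliability = reliability,
                           reproducibility = reproducibility,
                           divergence = divergence,
                           manifest = manifest),
                      class = "study_result")
  if (!is.null(config$output_dir)) write_study_result(result, config$output_dir)
  result
}

# stable md5 of the configuration (file-based; tools::md5sum has no string API)
config_hash <- function(config) {
  slim <- config[!vapply(config, is.function, logical(1))]
  slim$prefit <- if (is.null(slim$prefit)) NULL else "prefit-model"
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a study result bundle
#'
#' @param result A `study_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_evaluation_report(result$evaluation, dir)
  if (inherits(result$model, "rrr_model")) {
    write_rrr_model(result$model, file.path(dir, "model"))
  }
  if (!is.null(result$reliability)) {
    readr::write_csv(result$reliability, file.path(dir, "reliability.csv"))
  }
  if (!is.null(result$reproducibility)) {
    readr::write_csv(tibble::tibble(
      dimension = names(result$reproducibility$correlations),
      correlation = unname(result$reproducibility$correlations)),
      file.path(dir, "reproducibility.csv"))
  }
  if (!is.null(result$divergence)) {
    readr::write_csv(tidy(result$divergence), file.path(dir, "divergence.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s mode (seed %d)\n",
              x$manifest$study_mode, x$manifest$seed))
  print(x$evaluation)
  if (!is.null(x$reproducibility)) {
    cat(sprintf("  split-half reproducibility (mean r): %.3f\n",
                x$reproducibility$mean_correlation))
  }
  if (!is.null(x$reliability)) {
    cat(sprintf("  test-retest reliability (mean r): rrr %.3f, scales %.3f\n",
                mean(x$reliability$rrr), mean(x$reliability$scales)))
  }
  if (!is.null(x$divergence)) {
    cat(sprintf("  divergence Hedges' g: %.3f\n", x$divergence$hedges_g))
  }
  invisible(x)
}
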