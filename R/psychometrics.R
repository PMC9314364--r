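#' Cosine similarity between two vectors
#'
#' `u . v / (||u|| ||v||)`, in `[-1, 1]`; the cosine of the angle between two
#' points in score space.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop_rrscore("`u` and `v` must have equal length.", "rrscore_dim_error")
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_rrscore("Cosine similarity is undefined for zero vectors.",
                 "rrscore_validation_error")
  }
  sum(u * v) / (nu * nv)
}

# row-wise cosines between two n x r matrices; zero rows -> NA
row_cosines <- function(M1, M2) {
  n1 <- sqrt(rowSums(M1^2))
  n2 <- sqrt(rowSums(M2^2))
  out <- rowSums(M1 * M2) / (n1 * n2)
  out[n1 == 0 | n2 == 0] <- NA_real_
  out
}

#' Align two score spaces by signed column permutation
#'
#' Rank-constrained fits identify their dimensions only up to column order
#' and sign. This searches all `2^r * r!` signed permutations of the columns
#' of `S2` (3,840 candidates for `r = 5`) and returns the one maximising the
#' chosen objective against `S1` — exhaustive, hence globally optimal, and
#' the most conservative basis for comparing two spaces.
#'
#' Objectives: `"mean_cosine"` is the mean over participants of the cosine
#' between their `S1` row and transformed `S2` row; `"mean_abs_correlation"`
#' is the mean over dimensions of `|cor(S1[, k], S2_aligned[, k])|`.
#'
#' @param S1,S2 `n x r` score matrices, `r <= 6`.
#' @param objective Alignment objective.
#' @return An `alignment_result`: `permutation` (aligned column `k` of `S2`
#'   is its original column `permutation[k]`), `signs`, `objective` (the
#'   achieved value) and `objective_name`.
#' @seealso [apply_alignment()], [align_greedy()]
#' @export
align_signed_permutation <- function(S1, S2,
                                     objective = c("mean_cosine",
                                                   "mean_abs_correlation")) {
  objective <- match.arg(objective)
  S1 <- check_matrix(S1, "S1"); S2 <- check_matrix(S2, "S2")
  if (nrow(S1) != nrow(S2) || ncol(S1) != ncol(S2)) {
    stop_rrscore("`S1` and `S2` must have identical dimensions.",
                 "rrscore_dim_error")
  }
  r <- ncol(S1)
  if (r > 6L) {
    stop_rrscore(paste0("Exhaustive search supports r <= 6 (", 2^r,
                        " * ", factorial(r), " candidates at r = ", r,
                        "); use align_greedy() for larger spaces."),
                 "rrscore_rank_error")
  }
  # The objective decomposes over columns: precompute the r x r match matrix
  # M[k, l], then each signed permutation scores sum_k signs[k] * M[k, perm[k]]
  # with the optimal sign being sign(M[k, perm[k]]).
  if (objective == "mean_cosine") {
    n1 <- sqrt(rowSums(S1^2)); n2 <- sqrt(rowSums(S2^2))
    ok <- n1 > 0 & n2 > 0
    M <- crossprod(S1[ok, , drop = FALSE] / n1[ok],
                   S2[ok, , drop = FALSE] / n2[ok]) / sum(ok)
  } else {
    M <- suppressWarnings(cor(S1, S2))
    M[is.na(M)] <- 0
  }
  perms <- all_permutations(r)
  scores <- apply(perms, 1L, function(p) sum(abs(M[cbind(seq_len(r), p)])))
  best <- which.max(scores)
  perm <- perms[best, ]
  signs <- sign(M[cbind(seq_len(r), perm)])
  signs[signs == 0] <- 1
  obj <- if (objective == "mean_abs_correlation") scores[best] / r else scores[best]
  structure(list(permutation = as.integer(perm), signs = signs,
                 objective = obj, objective_name = objective),
            class = "alignment_result")
}

#' Greedy fallback alignment for large spaces
#'
#' Repeatedly matches the strongest remaining `|M[k, l]|` entry. Not
#' guaranteed optimal; intended for `r > 6` where the exhaustive search in
#' [align_signed_permutation()] is infeasible.
#'
#' @inheritParams align_signed_permutation
#' @return An `alignment_result`.
#' @export
align_greedy <- function(S1, S2, objective = c("mean_cosine",
                                               "mean_abs_correlation")) {
  objective <- match.arg(objective)
  r <- ncol(S1)
  if (objective == "mean_cosine") {
    n1 <- sqrt(rowSums(S1^2)); n2 <- sqrt(rowSums(S2^2))
    ok <- n1 > 0 & n2 > 0
    M <- crossprod(S1[ok, , drop = FALSE] / n1[ok],
                   S2[ok, , drop = FALSE] / n2[ok]) / sum(ok)
  } else {
    M <- suppressWarnings(cor(S1, S2))
    M[is.na(M)] <- 0
  }
  perm <- integer(r); signs <- numeric(r)
  A <- abs(M)
  for (step in seq_len(r)) {
    idx <- arrayInd(which.max(A), dim(A))
    k <- idx[1]; l <- idx[2]
    perm[k] <- l
    signs[k] <- if (M[k, l] < 0) -1 else 1
    A[k, ] <- -Inf; A[, l] <- -Inf
  }
  obj <- sum(abs(M[cbind(seq_len(r), perm)]))
  if (objective == "mean_abs_correlation") obj <- obj / r
  structure(list(permutation = perm, signs = signs, objective = obj,
                 objective_name = objective),
            class = "alignment_result")
}

#' Apply an alignment to a score matrix
#'
#' @param S `n x r` score matrix (the `S2` side of the alignment).
#' @param alignment An `alignment_result`.
#' @return `S` with columns permuted and sign-flipped: aligned column `k` is
#'   `signs[k] * S[, permutation[k]]`.
#' @export
apply_alignment <- function(S, alignment) {
  stopifnot(inherits(alignment, "alignment_result"))
  S <- check_matrix(S, "S")
  out <- sweep(S[, alignment$permutation, drop = FALSE], 2L,
               alignment$signs, `*`)
  colnames(out) <- colnames(S)
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s = %.4f\n  permutation: %s\n  signs: %s\n",
              x$objective_name, x$objective,
              paste(x$permutation, collapse = " "),
              paste(ifelse(x$signs > 0, "+", "-"), collapse = " ")))
  invisible(x)
}

#' Split-half reproducibility of the learned representation
#'
#' Fits the reduced-rank projection independently on two disjoint cohorts,
#' projects a common held-out evaluation set with both, aligns the second
#' solution to the first by signed permutation, and reports the
#' per-dimension Pearson correlation over participants. High correlations
#' mean the discovered dimensional structure replicates across samples.
#'
#' @param cohort_a,cohort_b Disjoint training cohorts.
#' @param eval_X Item matrix of held-out participants (in neither cohort).
#' @param r Representation dimension.
#' @return List with `correlations` (length `r`), `mean_correlation`, and
#'   the `alignment` used.
#' @export
split_half_reproducibility <- function(cohort_a, cohort_b, eval_X, r = 5L) {
  validate_cohort(cohort_a); validate_cohort(cohort_b)
  overlap <- intersect(cohort_a$participant_ids, cohort_b$participant_ids)
  if (length(overlap)) {
    stop_rrscore(sprintf("Cohorts overlap: %s.", format_ids(overlap)),
                 "rrscore_validation_error")
  }
  eval_X <- check_matrix(eval_X, "eval_X", min_rows = 3L)
  m_a <- fit_rrr(cohort_a$X, cohort_a$Y, r)
  m_b <- fit_rrr(cohort_b$X, cohort_b$Y, r)
  S_a <- project(m_a, eval_X)
  S_b <- project(m_b, eval_X)
  if (any(apply(S_a, 2L, sd) == 0) || any(apply(S_b, 2L, sd) == 0)) {
    stop_rrscore("Degenerate projection: zero-variance score column.",
                 "rrscore_constant_column_error")
  }
  al <- align_signed_permutation(S_a, S_b, "mean_abs_correlation")
  S_b_aligned <- apply_alignment(S_b, al)
  cors <- vapply(seq_len(r), function(k) cor(S_a[, k], S_b_aligned[, k]),
                 numeric(1))
  names(cors) <- colnames(S_a) %||% sprintf("dim_%d", seq_len(r))
  list(correlations = cors, mean_correlation = mean(cors), alignment = al)
}

#' Test-retest reliability of representation scores
#'
#' Projects two administrations of the questionnaire (same participants,
#' rows aligned) with the same fitted model and reports the per-dimension
#' Pearson correlation between the two score sets.
#'
#' @param model A fitted `rrr_model` (or anything with a [project()] method,
#'   e.g. a [scale_key()]).
#' @param X_t1,X_t2 Item matrices for the first and second administration,
#'   row-aligned by participant.
#' @return Named numeric vector of per-dimension correlations.
#' @export
test_retest_reliability <- function(model, X_t1, X_t2) {
  X_t1 <- check_matrix(X_t1, "X_t1", min_rows = 3L)
  X_t2 <- check_matrix(X_t2, "X_t2", min_rows = 3L)
  if (nrow(X_t1) != nrow(X_t2)) {
    stop_rrscore("Administrations must cover the same participants.",
                 "rrscore_dim_error")
  }
  if (!is.null(rownames(X_t1)) && !is.null(rownames(X_t2)) &&
      !identical(rownames(X_t1), rownames(X_t2))) {
    stop_rrscore("Participant identifiers differ between administrations.",
                 "rrscore_validation_error")
  }
  S1 <- project(model, X_t1)
  S2 <- project(model, X_t2)
  cors <- vapply(seq_len(ncol(S1)), function(k) cor(S1[, k], S2[, k]),
                 numeric(1))
  names(cors) <- colnames(S1) %||% sprintf("dim_%d", seq_len(ncol(S1)))
  cors
}

#' Hedges' g standardised mean difference
#'
#' Cohen's d with pooled standard deviation, multiplied by the small-sample
#' correction `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @return Scalar effect size (positive when `sample1` has the larger mean).
#' @export
hedges_g <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2L || n2 < 2L) {
    stop_rrscore("Each sample needs at least 2 observations.", "rrscore_dim_error")
  }
  sp2 <- ((n1 - 1) * var(sample1) + (n2 - 1) * var(sample2)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    stop_rrscore("Zero pooled standard deviation.", "rrscore_constant_column_error")
  }
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  J * (mean(sample1) - mean(sample2)) / sqrt(sp2)
}

#' Convergence/divergence analysis of two multidimensional representations
#'
#' The multitrait-multimethod logic applied to score spaces: for each
#' participant, the cosine similarity of their scores across two
#' administrations *within* each representation (convergence; near 1 when
#' the representation is stable) is contrasted with the similarity *between*
#' the two representations at each time point (divergence). If the
#' between-measure similarity is clearly below both within-measure
#' similarities, the two representations span genuinely different spaces.
#' The headline effect size is Hedges' g of the smallest within-vs-between
#' contrast — the most conservative gap.
#'
#' Score matrices are standardised per dimension before the cosine is taken
#' (switchable) so that bounded 1-5 scale scores and unbounded projection
#' scores contribute comparable geometry, and the second representation is
#' aligned to the first by signed permutation (on the first administration)
#' unless `align = FALSE`.
#'
#' The between-measure comparison can be taken across administrations
#' (`between_occasion = "cross"`, the default: first measure at one occasion
#' against the second measure at the other) or within the same
#' administration (`"same"`). The cross-occasion form is calibrated: when
#' the two representations are identical, between and within similarities
#' have exactly the same distribution and the effect size is zero, whereas
#' same-occasion comparisons share occasion-specific variance (same latent
#' state, same response noise) and are inflated even under identity. Both
#' pooled means are reported; `between_occasion` selects which one feeds the
#' headline contrast.
#'
#' @param ffm_t1,ffm_t2 First representation's `n x r` scores at times 1
#'   and 2 (e.g. unit-weight factor scores).
#' @param pf_t1,pf_t2 Second representation's scores, same participants.
#' @param align Align `pf` to `ffm` by signed permutation first?
#' @param standardize Standardise each score matrix per dimension first?
#' @param between_occasion Between-measure comparison design; see Details.
#' @return A `divergence_report`: per-participant similarity draws
#'   (`similarities` tibble), summary means/sds for within-first,
#'   within-second and pooled between similarities, same- and cross-occasion
#'   between means, `hedges_g` of the smallest within-vs-between contrast,
#'   and the count of values excluded for zero score vectors.
#' @export
divergence_analysis <- function(ffm_t1, ffm_t2, pf_t1, pf_t2,
                                align = TRUE, standardize = TRUE,
                                between_occasion = c("cross", "same")) {
  between_occasion <- match.arg(between_occasion)
  mats <- list(ffm_t1 = check_matrix(ffm_t1, "ffm_t1"),
               ffm_t2 = check_matrix(ffm_t2, "ffm_t2"),
               pf_t1 = check_matrix(pf_t1, "pf_t1"),
               pf_t2 = check_matrix(pf_t2, "pf_t2"))
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L) {
    stop_rrscore("All score matrices must cover the same participants.",
                 "rrscore_dim_error")
  }
  if (standardize) {
    mats <- lapply(mats, function(M) apply_standardizer(M, fit_standardizer(M)))
  }
  alignment <- NULL
  if (align) {
    alignment <- align_signed_permutation(mats$ffm_t1, mats$pf_t1, "mean_cosine")
    mats$pf_t1 <- apply_alignment(mats$pf_t1, alignment)
    mats$pf_t2 <- apply_alignment(mats$pf_t2, alignment)
  }
  within_first <- row_cosines(mats$ffm_t1, mats$ffm_t2)
  within_second <- row_cosines(mats$pf_t1, mats$pf_t2)
  between_same_t1 <- row_cosines(mats$ffm_t1, mats$pf_t1)
  between_same_t2 <- row_cosines(mats$ffm_t2, mats$pf_t2)
  between_cross_12 <- row_cosines(mats$ffm_t1, mats$pf_t2)
  between_cross_21 <- row_cosines(mats$ffm_t2, mats$pf_t1)
  sims <- tibble::tibble(
    component = rep(c("within_first", "within_second",
                      "between_same_t1", "between_same_t2",
                      "between_cross_12", "between_cross_21"), each = n),
    similarity = c(within_first, within_second,
                   between_same_t1, between_same_t2,
                   between_cross_12, between_cross_21))
  n_excluded <- sum(is.na(sims$similarity))
  if (n_excluded > 0) {
    rlang::inform(sprintf("Excluded %d zero-vector similarity values.", n_excluded))
    sims <- sims[!is.na(sims$similarity), ]
  }
  between_components <- if (between_occasion == "cross") {
    c("between_cross_12", "between_cross_21")
  } else {
    c("between_same_t1", "between_same_t2")
  }
  between <- sims$similarity[sims$component %in% between_components]
  wf <- sims$similarity[sims$component == "within_first"]
  ws <- sims$similarity[sims$component == "within_second"]
  # the smallest convergence-vs-divergence contrast
  weaker_within <- if (mean(wf) <= mean(ws)) wf else ws
  g <- hedges_g(weaker_within, between)
  structure(list(
    similarities = sims,
    within_first = c(mean = mean(wf), sd = sd(wf)),
    within_second = c(mean = mean(ws), sd = sd(ws)),
    between = c(mean = mean(between), sd = sd(between)),
    between_same = c(
      t1 = mean(sims$similarity[sims$component == "between_same_t1"]),
      t2 = mean(sims$similarity[sims$component == "between_same_t2"])),
    between_occasion = between_occasion,
    hedges_g = g,
    n = n, n_excluded = n_excluded,
    alignment = alignment),
    class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("<divergence_report> n = %d participants\n", x$n))
  cat(sprintf("  within first:  M = %.3f, SD = %.3f\n",
              x$within_first["mean"], x$within_first["sd"]))
  cat(sprintf("  within second: M = %.3f, SD = %.3f\n",
              x$within_second["mean"], x$within_second["sd"]))
  cat(sprintf("  between:       M = %.3f, SD = %.3f\n",
              x$between["mean"], x$between["sd"]))
  cat(sprintf("  Hedges' g (smallest within-vs-between contrast): %.3f\n",
              x$hedges_g))
  invisible(x)
}

#' @method tidy divergence_report
#' @export
tidy.divergence_report <- function(x, ...) {
  x$similarities |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(mean = mean(.data$similarity),
                     sd = sd(.data$similarity),
                     n = dplyr::n(), .groups = "drop")
}

#' Cross-correlation report between two score blocks
#'
#' Pearson correlations between the columns of two row-aligned matrices
#' (e.g. outcome variables against representation scores), optionally
#' appending the leading principal components of the first block. Constant
#' columns yield `NA` cells.
#'
#' @param scores_a,scores_b Row-aligned numeric matrices.
#' @param include_pcs Number of leading principal components of `scores_a`
#'   to append to it (0 for none).
#' @return A correlation matrix (class `correlation_report`) with rows for
#'   `scores_a` (plus PCs) and columns for `scores_b`.
#' @export
correlation_report <- function(scores_a, scores_b, include_pcs = 0L) {
  A <- check_matrix(scores_a, "scores_a", min_rows = 3L)
  B <- check_matrix(scores_b, "scores_b", min_rows = 3L)
  if (nrow(A) != nrow(B)) {
    stop_rrscore("Score blocks must be row-aligned.", "rrscore_dim_error")
  }
  if (is.null(colnames(A))) colnames(A) <- sprintf("a_%d", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- sprintf("b_%d", seq_len(ncol(B)))
  if (include_pcs > 0L) {
    ok <- apply(A, 2L, sd) > 0
    pc <- stats::prcomp(A[, ok, drop = FALSE], center = TRUE, scale. = TRUE)
    k <- min(include_pcs, ncol(pc$x))
    P <- pc$x[, seq_len(k), drop = FALSE]
    colnames(P) <- sprintf("PC%d", seq_len(k))
    A <- cbind(A, P)
  }
  M <- suppressWarnings(cor(A, B))
  structure(M, class = c("correlation_report", class(M)))
}
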