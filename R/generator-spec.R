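#' Specify a synthetic questionnaire cohort
#'
#' A `generator_spec` fully describes a simulated study population: latent
#' traits per participant, a loading matrix mapping latents to continuous item
#' scores, Gaussian item noise, fixed cutpoints discretising the continuous
#' score into a 1-5 Likert response, outcomes that are linear in the latents
#' plus noise, and a stability coefficient for a second (retest)
#' administration.
#'
#' Defaults emulate a 100-item five-factor inventory: five blocks of 20 items,
#' each loading on one latent with |loading| = 1 (the last 6 items of each
#' block negatively keyed, mirroring reverse-coded items in real inventories),
#' item noise sd 1, and cutpoints at the 20/40/60/80% quantiles of the
#' continuous item score so the five categories are balanced. Default outcome
#' weights give population R-squared values spread evenly from 1% to 9% across
#' the outcomes, the range typical of single personality-outcome associations.
#'
#' @param n_participants Number of participants.
#' @param n_items Number of Likert items (default 100).
#' @param n_outcomes Number of outcome variables (default 10).
#' @param n_latent Number of latent traits (default 5).
#' @param item_loadings `n_items x n_latent` matrix; `NULL` uses the block
#'   default described above.
#' @param item_noise_sd Nonnegative sd of Gaussian item noise.
#' @param likert_thresholds Strictly increasing length-4 cutpoints; `NULL`
#'   places them at the 20/40/60/80% quantiles implied by the loadings and
#'   item noise.
#' @param outcome_weights `n_outcomes x n_latent` matrix; `NULL` uses the
#'   1-9% R-squared default.
#' @param outcome_noise_sd Nonnegative sd(s) of outcome noise, recycled to
#'   `n_outcomes`.
#' @param retest_stability Latent stability in `[0, 1]` between the two
#'   administrations, recycled to `n_latent`.
#' @param latent_corr Optional `n_latent x n_latent` correlation matrix for
#'   correlated latents (applied via its Cholesky factor); `NULL` for i.i.d.
#'   standard-normal latents.
#' @param seed Integer seed; cohorts are bit-identical given the same spec.
#'
#' @return An object of class `generator_spec`.
#' @seealso [generate_cohort()], [pop_outcome_r2()], [spec_supervised_advantage()]
#' @export
generator_spec <- function(n_participants,
                           n_items = 100L,
                           n_outcomes = 10L,
                           n_latent = 5L,
                           item_loadings = NULL,
                           item_noise_sd = 1,
                           likert_thresholds = NULL,
                           outcome_weights = NULL,
                           outcome_noise_sd = 1,
                           retest_stability = 0.8,
                           latent_corr = NULL,
                           seed = 1L) {
  for (v in c("n_participants", "n_items", "n_outcomes", "n_latent")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1L || val < 1 || val != round(val)) {
      stop_rrscore(sprintf("`%s` must be a positive integer.", v),
                   "rrscore_spec_error")
    }
  }
  if (is.null(item_loadings)) {
    item_loadings <- default_item_loadings(n_items, n_latent)
  }
  item_loadings <- check_matrix(item_loadings, "item_loadings")
  if (nrow(item_loadings) != n_items || ncol(item_loadings) != n_latent) {
    stop_rrscore("`item_loadings` must be n_items x n_latent.", "rrscore_dim_error")
  }
  if (!is.numeric(item_noise_sd) || length(item_noise_sd) != 1L || item_noise_sd < 0) {
    stop_rrscore("`item_noise_sd` must be a nonnegative scalar.", "rrscore_spec_error")
  }
  if (is.null(likert_thresholds)) {
    # balanced categories: quantiles of the typical continuous item score
    s <- sqrt(mean(rowSums(item_loadings^2)) + item_noise_sd^2)
    likert_thresholds <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8)) * s
  }
  if (length(likert_thresholds) != 4L || any(diff(likert_thresholds) <= 0)) {
    stop_rrscore("`likert_thresholds` must be 4 strictly increasing cutpoints.",
                 "rrscore_spec_error")
  }
  if (is.null(outcome_weights)) {
    outcome_weights <- default_outcome_weights(n_outcomes, n_latent,
                                               rep_len(outcome_noise_sd, n_outcomes))
  }
  outcome_weights <- check_matrix(outcome_weights, "outcome_weights")
  if (nrow(outcome_weights) != n_outcomes || ncol(outcome_weights) != n_latent) {
    stop_rrscore("`outcome_weights` must be n_outcomes x n_latent.", "rrscore_dim_error")
  }
  outcome_noise_sd <- rep_len(outcome_noise_sd, n_outcomes)
  if (any(outcome_noise_sd < 0)) {
    stop_rrscore("`outcome_noise_sd` must be nonnegative.", "rrscore_spec_error")
  }
  retest_stability <- rep_len(retest_stability, n_latent)
  if (any(retest_stability < 0 | retest_stability > 1)) {
    stop_rrscore("`retest_stability` must lie in [0, 1].", "rrscore_spec_error")
  }
  if (!is.null(latent_corr)) {
    latent_corr <- check_matrix(latent_corr, "latent_corr")
    if (nrow(latent_corr) != n_latent || ncol(latent_corr) != n_latent) {
      stop_rrscore("`latent_corr` must be n_latent x n_latent.", "rrscore_dim_error")
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_items = as.integer(n_items),
         n_outcomes = as.integer(n_outcomes),
         n_latent = as.integer(n_latent),
         item_loadings = item_loadings,
         item_noise_sd = item_noise_sd,
         likert_thresholds = likert_thresholds,
         outcome_weights = outcome_weights,
         outcome_noise_sd = outcome_noise_sd,
         retest_stability = retest_stability,
         latent_corr = latent_corr,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# blocks of items per latent; last 30% of each block negatively keyed
default_item_loadings <- function(n_items, n_latent) {
  block <- rep(seq_len(n_latent), length.out = n_items)
  block <- sort(block)
  L <- matrix(0, n_items, n_latent)
  for (k in seq_len(n_latent)) {
    idx <- which(block == k)
    signs <- rep(1, length(idx))
    n_rev <- floor(0.3 * length(idx))
    if (n_rev > 0) signs[seq(length(idx) - n_rev + 1L, length(idx))] <- -1
    L[cbind(idx, k)] <- signs
  }
  L
}

# one dominant latent per outcome; row norms set so population R2 spans 1-9%
default_outcome_weights <- function(n_outcomes, n_latent, noise_sd) {
  r2 <- if (n_outcomes == 1L) 0.05 else seq(0.01, 0.09, length.out = n_outcomes)
  W <- matrix(0, n_outcomes, n_latent)
  for (j in seq_len(n_outcomes)) {
    k <- ((j - 1L) %% n_latent) + 1L
    W[j, k] <- sqrt(r2[j] / (1 - r2[j])) * noise_sd[j]
  }
  W
}

#' Population outcome R-squared implied by a generator spec
#'
#' With unit-variance independent latents, the proportion of variance of each
#' outcome explained by the latent traits is
#' `rowSS(weights) / (rowSS(weights) + noise_sd^2)`.
#'
#' @param spec A [generator_spec()].
#' @return Numeric vector of length `n_outcomes`.
#' @export
pop_outcome_r2 <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  ss <- rowSums(spec$outcome_weights^2)
  unname(ss / (ss + spec$outcome_noise_sd^2))
}

#' Scenario where the predictive latent has the smallest item-variance share
#'
#' Builds a spec with six latents: five high-variance "nuisance" blocks of 18
#' items each (|loading| 1) and one low-variance latent measured by only 10
#' items with loading 0.4. All outcomes are driven by the low-variance latent.
#' Unsupervised reduction (leading principal components) spends its dimensions
#' on the nuisance blocks; supervised reduced-rank regression targets the
#' predictive latent directly, so this scenario separates the two approaches.
#'
#' @param n_participants Number of participants.
#' @param n_outcomes Number of outcomes (default 10).
#' @param outcome_r2 Population R-squared of each outcome on the predictive
#'   latent (default 0.3).
#' @param seed Integer seed.
#' @return A [generator_spec()].
#' @export
spec_supervised_advantage <- function(n_participants, n_outcomes = 10L,
                                      outcome_r2 = 0.3, seed = 1L) {
  n_latent <- 6L
  n_items <- 100L
  L <- matrix(0, n_items, n_latent)
  for (k in 1:5) {
    idx <- ((k - 1L) * 18L + 1L):(k * 18L)
    signs <- rep(1, 18L); signs[14:18] <- -1
    L[cbind(idx, k)] <- signs
  }
  L[91:100, 6L] <- 0.4
  W <- matrix(0, n_outcomes, n_latent)
  W[, 6L] <- sqrt(outcome_r2 / (1 - outcome_r2))
  generator_spec(n_participants,
                 n_items = n_items, n_outcomes = n_outcomes, n_latent = n_latent,
                 item_loadings = L, item_noise_sd = 1,
                 outcome_weights = W, outcome_noise_sd = 1,
                 seed = seed)
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> %d participants, %d items, %d outcomes, %d latents (seed %d)\n",
              x$n_participants, x$n_items, x$n_outcomes, x$n_latent, x$seed))
  r2 <- pop_outcome_r2(x)
  cat(sprintf("  population outcome R2: %.3f - %.3f\n", min(r2), max(r2)))
  invisible(x)
}
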