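#' Corridor-of-stability coverage by simulation
#'
#' Simulates sequential sampling of bivariate-normal pairs with true
#' correlation `rho`. A trajectory succeeds if its running Pearson
#' correlation stays inside the corridor `[rho - w, rho + w]` at every sample
#' size from `n_start` through `n_max`. The returned success fraction is the
#' confidence that, having collected `n_start` observations, the correlation
#' estimate has stabilised to within `w` of the truth — the standard
#' sample-size justification for correlational studies (e.g. 470 observations
#' give roughly 95% confidence for a small effect `rho = 0.1` with corridor
#' half-width `w = 0.1`).
#'
#' @param rho True correlation, in `(-1, 1)`.
#' @param w Corridor half-width, positive.
#' @param n_start First sample size that must lie in the corridor (>= 3).
#' @param n_max Largest sample size simulated.
#' @param n_sims Number of independent trajectories.
#' @param seed Integer seed.
#' @param chunk_size Trajectories simulated per block (memory control).
#' @return Success fraction in `[0, 1]`.
#' @export
corridor_coverage <- function(rho, w, n_start, n_max, n_sims = 10000L,
                              seed = 1L, chunk_size = 1000L) {
  if (!is.numeric(rho) || abs(rho) >= 1) {
    stop_rrscore("`rho` must lie in (-1, 1).", "rrscore_spec_error")
  }
  if (!is.numeric(w) || length(w) != 1L || w <= 0) {
    stop_rrscore("`w` must be positive.", "rrscore_spec_error")
  }
  if (n_start < 3L || n_start > n_max) {
    stop_rrscore("Require 3 <= n_start <= n_max.", "rrscore_spec_error")
  }
  lo <- rho - w
  hi <- rho + w
  ns <- seq_len(n_max)
  check <- ns >= n_start
  successes <- 0L
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_sims) {
      m <- min(chunk_size, n_sims - done)
      X <- matrix(rnorm(n_max * m), n_max, m)
      Y <- rho * X + sqrt(1 - rho^2) * matrix(rnorm(n_max * m), n_max, m)
      sx <- apply(X, 2L, cumsum)
      sy <- apply(Y, 2L, cumsum)
      sxx <- apply(X * X, 2L, cumsum)
      syy <- apply(Y * Y, 2L, cumsum)
      sxy <- apply(X * Y, 2L, cumsum)
      num <- ns * sxy - sx * sy
      den2 <- (ns * sxx - sx^2) * (ns * syy - sy^2)
      r_run <- num / sqrt(pmax(den2, 0))
      inside <- r_run >= lo & r_run <= hi
      inside[!is.finite(r_run)] <- FALSE
      ok <- colSums(inside[check, , drop = FALSE]) == sum(check)
      successes <- successes + sum(ok)
      done <- done + m
    }
  })
  successes / n_sims
}
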