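test_that("R-squared and MAE follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # hand computation: SSE = 4 * 0.25 = 1, SST = 5
  expect_equal(r_squared(y, c(1.5, 1.5, 3.5, 3.5)), 1 - 1 / 5)
  expect_error(r_squared(rep(2, 4), y), class = "rrscore_constant_column_error")
  expect_error(r_squared(y, y[1:3]), class = "rrscore_dim_error")

  expect_equal(mean_abs_error(y, y), 0)
  expect_equal(mean_abs_error(c(0, 0), c(1, -1)), 1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mean_abs_error(a, b), sum(abs(a - b)) / 50)
  expect_error(mean_abs_error(numeric(0), numeric(0)), class = "rrscore_dim_error")
})

test_that("paired error t-test matches the hand formula and handles degeneracy", {
  e <- c(0.5, 0.7, 0.9, 1.1, 1.3)
  expect_equal(paired_error_ttest(e, e), list(t = 0, p = 1, mean_diff = 0))

  res <- paired_error_ttest(e + 1, e)
  expect_identical(res$t, Inf)
  expect_identical(res$p, 0)

  d <- c(0.2, -0.1, 0.3, 0.1, 0.0)
  res2 <- paired_error_ttest(d, rep(0, 5))
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res2$t, t_hand, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(res2$mean_diff, 0.1)
  expect_error(paired_error_ttest(1:2, 1:2), class = "rrscore_dim_error")
})

test_that("BH step-up reproduces the hand-worked rule and nests correctly", {
  expect_false(any(bh_fdr(rep(1, 5), 0.05)))
  # thresholds i * alpha / m = 0.0125, 0.025, 0.0375, 0.05
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_true(bh_fdr(0.04, 0.05))
  expect_error(bh_fdr(c(0.1, 0.2), alpha = 1.5), class = "rrscore_spec_error")
  expect_error(bh_fdr(c(0.1, 2)), class = "rrscore_validation_error")

  withr::with_seed(31, {
    for (i in 1:20) {
      p <- runif(12)^2
      bh <- bh_fdr(p, 0.05)
      bonf <- p <= 0.05 / length(p)
      raw <- p <= 0.05
      expect_true(all(bh[bonf]))     # BH rejects everything Bonferroni does
      expect_true(all(raw[bh]))      # and nothing the raw threshold keeps
    }
  })
})

test_that("two-stage CV uses 600/200 splits on an 800-participant test cohort", {
  co <- make_cohort(1600, seed = 41, n_items = 20)
  parts <- split_cohort(co, 1:800)
  rep <- two_stage_cv(parts$b, parts$a, cv_scheme(4, seed = 1), r = 5)
  expect_true(all(rep$folds$n_holdout == 200))
  # partition property: each test participant scored exactly once per model/outcome
  counts <- table(rep$errors$participant_id, rep$errors$model)
  expect_true(all(counts == ncol(co$Y)))
  # shape: outcomes x models x folds
  expect_equal(nrow(rep$folds), 10 * 3 * 4)
  # determinism
  rep2 <- two_stage_cv(parts$b, parts$a, cv_scheme(4, seed = 1), r = 5)
  expect_equal(rep$summary, rep2$summary, tolerance = 0)
  # overlapping cohorts are rejected
  expect_error(two_stage_cv(co, parts$a, cv_scheme(4, seed = 1), 5),
               class = "rrscore_validation_error")
})

test_that("realisable outcomes give holdout R2 of one; null outcomes give none", {
  co <- make_realizable_cohort(n = 1400, p = 20, q = 5, r = 5, seed = 42)
  parts <- split_cohort(co, 1:400)
  rep <- two_stage_cv(parts$b, parts$a,
                      cv_scheme(4, seed = 2, models = "rrr"), r = 5)
  expect_equal(mean(rep$summary$r2), 1, tolerance = 1e-6)

  # outcomes independent of items: out-of-sample R2 hovers at/below zero
  mean_r2 <- vapply(1:20, function(s) {
    sp <- generator_spec(600, n_items = 20, n_outcomes = 4, n_latent = 2,
                         outcome_weights = matrix(0, 4, 2), seed = 100 + s)
    con <- generate_cohort(sp)
    pp <- split_cohort(con, 1:200)
    r <- two_stage_cv(pp$b, pp$a, cv_scheme(4, seed = s, models = "rrr"), r = 2)
    mean(r$summary$r2)
  }, numeric(1))
  expect_lt(mean(mean_r2), 0.02)
})

test_that("transfer evaluation uses a frozen projection on new outcomes", {
  co <- make_cohort(1200, seed = 43)
  parts <- split_cohort(co, 1:400)
  m <- fit_rrr(parts$b$X, parts$b$Y, 5)
  # new cohort with q = 6 fresh outcomes
  new_co <- make_cohort(530, seed = 44, n_outcomes = 6)
  sch <- cv_scheme(4, seed = 3, models = c("external", "scales"), prefit = m)
  rep <- two_stage_cv(NULL, new_co, sch, r = 5)
  expect_setequal(unique(rep$summary$outcome), sprintf("outcome_%02d", 1:6))
  expect_equal(nrow(rep$folds), 6 * 2 * 4)
  expect_error(cv_scheme(4, models = "external"), class = "rrscore_spec_error")
})

test_that("corridor coverage matches closed-form checks", {
  # corridor wider than the whole correlation range: certain success
  expect_equal(corridor_coverage(0, 1.01, 10, 20, n_sims = 200, seed = 1), 1)
  # pointwise (n_start = n_max) coverage agrees with the Fisher-z approximation
  cov <- corridor_coverage(0.2, 0.1, 200, 200, n_sims = 4000, seed = 2)
  z_se <- 1 / sqrt(200 - 3)
  approx <- pnorm((atanh(0.3) - atanh(0.2)) / z_se) -
    pnorm((atanh(0.1) - atanh(0.2)) / z_se)
  expect_lt(abs(cov - approx), 0.03)
  expect_error(corridor_coverage(0.1, -1, 10, 20), class = "rrscore_spec_error")
  expect_error(corridor_coverage(1.2, 0.1, 10, 20), class = "rrscore_spec_error")
})
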