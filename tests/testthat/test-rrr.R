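test_that("unconstrained least squares matches the normal-equation oracle", {
  X <- std(rand_matrix(50, 6, seed = 1))
  Y <- std(rand_matrix(50, 3, seed = 2))
  C <- fit_ols(X, Y)
  oracle <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(C), unname(oracle), tolerance = 1e-10)

  # Y = X recovers the identity
  expect_equal(unname(fit_ols(X, X)), diag(6), tolerance = 1e-10)

  # responses orthogonal to the column space give zero coefficients
  R <- rand_matrix(50, 2, seed = 3)
  Yperp <- R - X %*% solve(crossprod(X), crossprod(X, R))
  expect_lt(max(abs(fit_ols(X, Yperp))), 1e-10)

  # rank-deficient design falls back to the pseudoinverse with a warning
  Xd <- cbind(X, X[, 1])
  expect_warning(fit_ols(Xd, Y), class = "rrscore_rank_deficient")
})

test_that("reduced-rank fit equals OLS at full rank and zero loss when realisable", {
  co <- make_realizable_cohort(n = 300, p = 10, q = 4, r = 4, seed = 4)
  m <- fit_rrr(co$X, co$Y, r = 4)     # r = q: unconstrained limit
  Xs <- std(co$X); Ys <- std(co$Y)
  C_ols <- fit_ols(Xs, Ys)
  expect_equal(tcrossprod(m$B, m$A), C_ols, tolerance = 1e-8,
               ignore_attr = TRUE)

  co2 <- make_realizable_cohort(n = 300, p = 10, q = 5, r = 2, seed = 5)
  m2 <- fit_rrr(co2$X, co2$Y, r = 2)
  expect_lt(m2$training_loss, 1e-16 * nrow(co2$X))

  expect_error(fit_rrr(co$X, co$Y, r = 20), class = "rrscore_rank_error")
  expect_error(fit_rrr(co$X, co$Y, r = 0), class = "rrscore_rank_error")
})

test_that("closed-form solution attains the ALS-oracle optimum", {
  X <- rand_matrix(200, 8, seed = 6)
  Y <- rand_matrix(200, 4, seed = 7)
  m <- fit_rrr(X, Y, r = 2)
  o <- rrr_brute_oracle(X, Y, r = 2, restarts = 8, seed = 8)
  expect_lt(abs(m$training_loss - o$loss), 1e-6)
  # and the oracle C achieves the same residual through rrr_loss
  expect_equal(rrr_loss(X, Y, o$C), o$loss, tolerance = 1e-8)
})

test_that("training loss is nonincreasing in rank and C has numerical rank <= r", {
  X <- rand_matrix(150, 8, seed = 9)
  Y <- rand_matrix(150, 5, seed = 10)
  losses <- vapply(1:5, function(r) fit_rrr(X, Y, r)$training_loss, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
  m <- fit_rrr(X, Y, 2)
  d <- svd(tcrossprod(m$B, m$A))$d
  expect_lt(d[3] / d[1], 1e-10)
  # columns ordered by decreasing singular value, dominant loading positive
  expect_true(all(diff(m$singular_values) <= 1e-12))
  expect_true(all(vapply(1:2, function(k) m$B[which.max(abs(m$B[, k])), k] > 0,
                         logical(1))))
})

test_that("projection and prediction recompose as matrix products", {
  # hand-built 2x3 responses, 3x2 map, identity standardisers
  B <- matrix(c(1, 0, 2,
                0, 1, -1), 3, 2)
  model <- structure(list(
    B = B, A = matrix(c(1, 0, 0, 1), 2, 2), rank = 2L,
    x_standardizer = structure(list(means = rep(0, 3), sds = rep(1, 3)),
                               class = "standardizer"),
    y_standardizer = structure(list(means = c(0, 0), sds = c(1, 1)),
                               class = "standardizer"),
    singular_values = c(1, 1), n_train = 2L), class = "rrr_model")
  Xn <- matrix(c(1, 2, 3,
                 4, 5, 6), 2, 3, byrow = TRUE)
  expect_equal(project(model, Xn),
               matrix(c(1 + 6, 2 - 3, 4 + 12, 5 - 6), 2, 2, byrow = TRUE))
  # identical item responses give identical scores
  expect_equal(project(model, Xn[c(1, 1), ])[1, ],
               project(model, Xn[c(1, 1), ])[2, ])

  # fitted model: projecting the training data reproduces the training scores
  co <- make_cohort(100, seed = 11, n_items = 12)
  m <- fit_rrr(co$X, co$Y, 3)
  expect_equal(project(m, co$X), std(co$X) %*% m$B, ignore_attr = TRUE)

  # predictions equal scores times A', destandardised (independent recompose)
  P <- predict(m, co$X)
  S <- project(m, co$X)
  manual <- sweep(sweep(tcrossprod(S, m$A), 2, m$y_standardizer$sds, `*`),
                  2, m$y_standardizer$means, `+`)
  expect_equal(P, manual, ignore_attr = TRUE)

  # noiseless realisable data are predicted exactly
  co2 <- make_realizable_cohort(n = 300, p = 10, q = 4, r = 2, seed = 12)
  m2 <- fit_rrr(co2$X, co2$Y, 2)
  expect_equal(predict(m2, co2$X), co2$Y, tolerance = 1e-8, ignore_attr = TRUE)

  # zero outcome map predicts the training means
  m0 <- m
  m0$A[] <- 0
  expect_equal(unname(predict(m0, co$X)[3, ]), unname(m$y_standardizer$means))
  expect_error(project(m, co$X[, 1:5]), class = "rrscore_dim_error")
})

test_that("predictions are invariant under signed permutation of the factors", {
  co <- make_cohort(120, seed = 13, n_items = 10)
  m <- fit_rrr(co$X, co$Y, 3)
  perm <- c(3, 1, 2); signs <- c(-1, 1, -1)
  m2 <- m
  m2$B <- sweep(m$B[, perm], 2, signs, `*`)
  m2$A <- sweep(m$A[, perm], 2, signs, `*`)
  expect_equal(predict(m, co$X), predict(m2, co$X))
})

test_that("principal-component regression matches its spectral oracle", {
  co <- make_cohort(400, seed = 14, n_items = 6)
  # r = p: rotation of the full basis reproduces OLS predictions
  pm <- fit_pcr(co$X, co$Y, 6)
  Xs <- std(co$X); Ys <- std(co$Y)
  pred_pcr <- predict(pm, co$X)
  C_ols <- fit_ols(Xs, Ys)
  pred_ols <- invert_standardizer(Xs %*% C_ols, pm$y_standardizer)
  expect_equal(pred_pcr, pred_ols, tolerance = 1e-8, ignore_attr = TRUE)

  # component scores are uncorrelated
  pm2 <- fit_pcr(co$X, co$Y, 3)
  S <- project(pm2, co$X)
  cv <- crossprod(S) / (nrow(S) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)

  # loadings match an eigendecomposition of the sample correlation matrix
  ev <- eigen(cor(co$X), symmetric = TRUE)$vectors[, 1:3]
  for (k in 1:3) {
    expect_equal(abs(sum(pm2$loadings[, k] * ev[, k])), 1, tolerance = 1e-8)
  }
  expect_error(fit_pcr(co$X, co$Y, 7), class = "rrscore_rank_error")
})

test_that("model serialisation round-trips losslessly", {
  co <- make_cohort(200, seed = 15, n_items = 15)
  m <- fit_rrr(co$X, co$Y, 4)
  dir <- withr::local_tempdir()
  write_rrr_model(m, dir)
  m2 <- read_rrr_model(dir)
  expect_equal(m2$B, m$B, tolerance = 0)
  expect_equal(m2$A, m$A, tolerance = 0)
  expect_equal(m2$x_standardizer$means, m$x_standardizer$means, tolerance = 0)
  expect_equal(m2$y_standardizer$sds, m$y_standardizer$sds, tolerance = 0)
  expect_identical(m2$rank, m$rank)
  # the restored model projects and predicts identically
  expect_equal(predict(m2, co$X), predict(m, co$X), tolerance = 0)
})

test_that("tidy and glance expose loadings and fit summaries", {
  co <- make_cohort(100, seed = 16, n_items = 8)
  m <- fit_rrr(co$X, co$Y, 2)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8 * 2)
  expect_equal(tidy(m, matrix = "A")$value, as.vector(m$A))
  gl <- glance(m)
  expect_equal(gl$rank, 2L)
  expect_equal(gl$training_loss, m$training_loss)
})
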