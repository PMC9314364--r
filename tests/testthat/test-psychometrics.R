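test_that("cosine similarity follows the dot-product formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "rrscore_validation_error")
  expect_error(cosine_similarity(1:3, 1:4), class = "rrscore_dim_error")
})

test_that("signed-permutation alignment recovers constructed transformations", {
  S1 <- rand_matrix(200, 4, seed = 51)
  al0 <- align_signed_permutation(S1, S1)
  expect_identical(al0$permutation, 1:4)
  expect_true(all(al0$signs == 1))
  expect_equal(al0$objective, 1, tolerance = 1e-12)

  perm <- c(2, 4, 1, 3); signs <- c(1, -1, -1, 1)
  S2 <- sweep(S1[, perm], 2, signs, `*`)
  # to align S2 back onto S1 we need the inverse transformation
  al <- align_signed_permutation(S1, S2)
  expect_equal(apply_alignment(S2, al), S1, ignore_attr = TRUE)
  expect_equal(al$objective, 1, tolerance = 1e-12)

  expect_error(align_signed_permutation(rand_matrix(10, 7), rand_matrix(10, 7)),
               class = "rrscore_rank_error")
})

test_that("alignment is globally optimal against a brute-force enumeration", {
  r <- 3
  S1 <- rand_matrix(150, r, seed = 52)
  mix <- matrix(rnorm(r * r), r, r)
  S2 <- S1 %*% mix + 0.3 * rand_matrix(150, r, seed = 53)
  for (obj in c("mean_cosine", "mean_abs_correlation")) {
    al <- align_signed_permutation(S1, S2, obj)
    # dumb enumeration over all 2^r * r! candidates, recomputing from scratch
    best <- -Inf
    perms <- rrscore:::all_permutations(r)
    signs <- rrscore:::all_sign_patterns(r)
    for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(signs))) {
      T2 <- sweep(S2[, perms[i, ]], 2, signs[j, ], `*`)
      val <- if (obj == "mean_cosine") {
        mean(rowSums(S1 * T2) / (sqrt(rowSums(S1^2)) * sqrt(rowSums(T2^2))))
      } else {
        mean(abs(diag(cor(S1, T2))))
      }
      best <- max(best, val)
    }
    expect_equal(al$objective, best, tolerance = 1e-10)
    # aligned objective is at least the unaligned one; idempotent afterwards
    S2a <- apply_alignment(S2, al)
    al2 <- align_signed_permutation(S1, S2a, obj)
    expect_identical(al2$permutation, 1:r)
    expect_true(all(al2$signs == 1))
  }
})

test_that("split-half reproducibility is exact for identical data and grows with n", {
  co <- make_cohort(700, seed = 54)
  parts <- split_cohort(co, 1:200)
  half <- parts$b
  clone <- half
  clone$participant_ids <- paste0("C", half$participant_ids)
  rownames(clone$X) <- rownames(clone$Y) <- clone$participant_ids
  res <- split_half_reproducibility(half, clone, parts$a$X, 3)
  expect_equal(unname(res$correlations), rep(1, 3), tolerance = 1e-12)

  # disjointness enforced
  expect_error(split_half_reproducibility(half, half, parts$a$X, 3),
               class = "rrscore_validation_error")

  # large halves replicate well; small halves strictly worse
  big <- generate_cohort(generator_spec(201000, seed = 55))
  eval_part <- split_cohort(big, 1:1000)
  halves <- split_cohort(eval_part$b, 1:100000)
  rep_big <- split_half_reproducibility(halves$a, halves$b, eval_part$a$X, 5)
  expect_gt(rep_big$mean_correlation, 0.9)

  small <- split_cohort(eval_part$b, 1:500)
  small2 <- split_cohort(small$b, 1:500)
  rep_small <- split_half_reproducibility(small$a, small2$a, eval_part$a$X, 5)
  expect_lt(rep_small$mean_correlation, rep_big$mean_correlation)
})

test_that("test-retest reliability tracks the latent stability", {
  sp <- generator_spec(2000, seed = 56)
  co <- generate_retest(generate_cohort(sp), sp, fraction = 1)
  m <- fit_rrr(co$X, co$Y, 5)
  expect_equal(unname(test_retest_reliability(m, co$X, co$X)), rep(1, 5))

  sp0 <- generator_spec(4000, retest_stability = 0, seed = 57)
  co0 <- generate_retest(generate_cohort(sp0), sp0, fraction = 1)
  m0 <- fit_rrr(co0$X, co0$Y, 5)
  expect_lt(max(abs(test_retest_reliability(m0, co0$X, co0$X_retest))), 0.06)

  # stability 0.8 at scale: agrees with an independent Monte-Carlo replication
  spb <- generator_spec(50000, retest_stability = 0.8, seed = 58)
  cob <- generate_retest(generate_cohort(spb), spb, fraction = 1)
  mb <- fit_rrr(cob$X, cob$Y, 5)
  rel <- test_retest_reliability(mb, cob$X, cob$X_retest)
  spc <- generator_spec(50000, retest_stability = 0.8, seed = 59)
  coc <- generate_retest(generate_cohort(spc), spc, fraction = 1, seed = 600)
  rel_oracle <- test_retest_reliability(mb, coc$X, coc$X_retest)
  expect_lt(max(abs(rel - rel_oracle)), 0.02)
  # attenuation: observed reliabilities sit below the latent stability
  expect_true(all(rel < 0.8))

  expect_error(test_retest_reliability(mb, cob$X[1:10, ], cob$X[1:9, ]),
               class = "rrscore_dim_error")
})

test_that("Hedges' g applies the pooled-SD small-sample correction", {
  x <- c(1, 2, 3, 4)
  expect_equal(hedges_g(x, x), 0)
  # hand computation: d = -1/sqrt(0.5), J = 1 - 3/7
  expect_equal(hedges_g(c(0, 1), c(1, 2)), (1 - 3 / 7) * (-1 / sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2), c(0, 1)), -hedges_g(c(0, 1), c(1, 2)))
  a <- rnorm(30); b <- rnorm(25, 1)
  expect_equal(hedges_g(a + 5, b + 5), hedges_g(a, b), tolerance = 1e-10)
  # equals Cohen's d times J
  n1 <- 30; n2 <- 25
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  d <- (mean(a) - mean(b)) / sp
  expect_equal(hedges_g(a, b), d * (1 - 3 / (4 * (n1 + n2 - 2) - 1)))
  expect_error(hedges_g(c(1, 1), c(1, 1)),
               class = "rrscore_constant_column_error")
})

test_that("divergence analysis separates identical from orthogonal spaces", {
  n <- 400
  F1 <- rand_matrix(n, 5, seed = 60)
  F2 <- F1 + 0.2 * rand_matrix(n, 5, seed = 61)
  # identical representations: within and between distributions coincide
  rep_same <- divergence_analysis(F1, F2, F1, F2)
  expect_equal(rep_same$hedges_g, 0, tolerance = 1e-10)
  expect_equal(rep_same$within_first[["mean"]], rep_same$between[["mean"]],
               tolerance = 1e-12)

  # scores in orthogonal subspaces: between-measure similarity collapses
  withr::with_seed(62, {
    basis <- qr.Q(qr(matrix(rnorm(10 * 10), 10, 10)))
    Z <- matrix(rnorm(n * 10), n, 10)
  })
  P1 <- Z %*% basis[, 1:5]   # first representation lives in span 1-5
  P2 <- Z %*% basis[, 6:10]  # second in the complementary span
  rep_orth <- divergence_analysis(P1, P1, P2, P2, standardize = FALSE,
                                  align = FALSE)
  expect_equal(rep_orth$within_first[["mean"]], 1)
  expect_equal(rep_orth$within_second[["mean"]], 1)
  expect_lt(abs(rep_orth$between[["mean"]]), 0.2)
  expect_gt(rep_orth$hedges_g, 2)

  # similarity summaries are bounded by the cosine range
  sims <- tidy(rep_orth)
  expect_true(all(sims$mean >= -1 & sims$mean <= 1))
})

test_that("correlation reports cross-correlate score blocks", {
  A <- rand_matrix(5000, 3, seed = 63)
  M <- correlation_report(A, A)
  expect_equal(unname(diag(M)), rep(1, 3))

  B <- rand_matrix(5000, 4, seed = 64)
  M2 <- correlation_report(A, B)
  expect_lt(max(abs(M2)), 0.05)

  # hand example
  a <- matrix(c(1, 2, 3), 3, 1)
  b <- matrix(c(2, 1, 3), 3, 1)
  expect_equal(correlation_report(a, b)[1, 1], cor(a, b)[1, 1])

  # leading principal components can be appended to the first block
  M3 <- correlation_report(A, B, include_pcs = 2)
  expect_equal(nrow(M3), 5)
  expect_true(all(c("PC1", "PC2") %in% rownames(M3)))

  # constant columns flag undefined cells rather than failing
  Ac <- cbind(A, const = 1)
  M4 <- correlation_report(Ac, B)
  expect_true(all(is.na(M4)["const", ]))
})
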