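# Shared fixtures: small cohorts and random matrices built in code.

rand_matrix <- function(n, p, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * p), n, p))
}

# a standardised copy (for functions that expect centred/scaled input)
std <- function(M) apply_standardizer(M, fit_standardizer(M))

make_cohort <- function(n = 400, seed = 1, ...) {
  generate_cohort(generator_spec(n, seed = seed, ...))
}

# cohort whose outcomes are EXACTLY rank-r linear in the standardised items
# (realisable reduced-rank model, zero outcome noise)
make_realizable_cohort <- function(n = 600, p = 20, q = 6, r = 2, seed = 1,
                                   noise_sd = 0) {
  co <- generate_cohort(generator_spec(n, n_items = p, n_outcomes = q,
                                       n_latent = min(5, p), seed = seed))
  withr::with_seed(seed + 1000, {
    B0 <- matrix(rnorm(p * r), p, r)
    A0 <- matrix(rnorm(q * r), q, r)
    E <- matrix(rnorm(n * q), n, q)
  })
  Y <- std(co$X) %*% tcrossprod(B0, A0) + noise_sd * E
  dimnames(Y) <- dimnames(co$Y)
  co$Y <- Y
  attr(co, "B0") <- B0
  attr(co, "A0") <- A0
  co
}

# largest principal angle between column spans, in degrees
largest_principal_angle <- function(A, B) {
  Qa <- qr.Q(qr(A))
  Qb <- qr.Q(qr(B))
  d <- svd(crossprod(Qa, Qb))$d
  acos(min(1, min(d))) * 180 / pi
}
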