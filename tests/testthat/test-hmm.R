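test_that("single-cluster model has closed-form fit and deterministic emission", {
  set.seed(1)
  H <- matrix(rbinom(200 * 8, 1, 0.4), 200, 8)
  fit <- fit_hmm_em(H, K = 1)
  expect_equal(as.vector(fit$theta), colMeans(H), tolerance = 1e-10)
  expect_true(all(fit$alpha == 1))
  # theta == 1 emits ones with probability one
  m1 <- haplotype_hmm(matrix(1, 4, 1), matrix(1, 4, 1), c(1, 0, 0, 0))
  expect_equal(as.numeric(haplotype_loglik(m1, matrix(1L, 1, 4))), 0)
})

test_that("forward log-likelihood matches path enumeration and normalizes", {
  for (K in 2:3) {
    m <- tiny_hmm(3, K, seed = 10 + K)
    haps <- all_haps(3)
    ll <- haplotype_loglik(m, haps)
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
    brute <- apply(haps, 1, function(h) brute_hap_prob(m, h))
    expect_equal(exp(ll), brute, tolerance = 1e-10)
  }
  # larger instance still normalizes
  m <- tiny_hmm(4, 3, seed = 99)
  expect_equal(sum(exp(haplotype_loglik(m, all_haps(4)))), 1, tolerance = 1e-10)
})

test_that("EM log-likelihood is non-decreasing and recovers parameters", {
  p <- 20
  truth <- haplotype_hmm(matrix(0.5, p, 2),
                         matrix(rep(c(0.15, 0.85), each = p), p, 2),
                         c(1, rep(0.1, p - 1)))
  H <- sample_haplotypes(truth, 2000, seed = 3)$H
  fit <- fit_hmm_em(H, K = 2, max_iter = 60, tol = 1e-5, n_restarts = 3,
                    seed = 4)
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) > -1e-6))
  mae <- min(mean(abs(fit$theta - truth$theta)),
             mean(abs(fit$theta[, 2:1] - truth$theta)))
  expect_lt(mae, 0.05)
})

test_that("sampled haplotypes match the model's closed-form marginals", {
  m <- tiny_hmm(10, 3, seed = 21)
  n <- 10000
  sm <- sample_haplotypes(m, n, seed = 22)
  # closed-form allele frequency: propagate the latent marginal through the
  # jump mixture, then apply the emission frequencies
  zmarg <- m$alpha[1, ]
  marg <- numeric(10)
  marg[1] <- sum(zmarg * m$theta[1, ])
  for (j in 2:10) {
    zmarg <- (1 - m$r[j]) * zmarg + m$r[j] * m$alpha[j, ]
    marg[j] <- sum(zmarg * m$theta[j, ])
  }
  se <- sqrt(marg * (1 - marg) / n)
  expect_true(all(abs(colMeans(sm$H) - marg) < 3 * se))
  # reproducible under the same seed
  sm2 <- sample_haplotypes(m, n, seed = 22)
  expect_identical(sm$H, sm2$H)
  expect_identical(sm$Z, sm2$Z)
})

test_that("with jump probability one the latent states are independent", {
  p <- 4
  K <- 3
  set.seed(31)
  alpha <- matrix(runif(p * K, 0.2, 1), p, K)
  alpha <- alpha / rowSums(alpha)
  m <- haplotype_hmm(alpha, matrix(0.5, p, K), rep(1, p))
  Z <- sample_haplotypes(m, 10000, seed = 32)$Z
  for (j in 2:p) {
    pv <- suppressWarnings(chisq.test(table(Z[, j - 1], Z[, j]))$p.value)
    expect_gt(pv, 0.001)
  }
})

test_that("posterior path sampling matches the enumerated posterior", {
  K <- 2
  m <- tiny_hmm(2, K, seed = 41)
  h <- c(1L, 0L)
  # enumerate P(z | h) directly
  paths <- as.matrix(expand.grid(z1 = 1:K, z2 = 1:K))
  pr <- apply(paths, 1, function(z) {
    m$alpha[1, z[1]] * m$theta[1, z[1]] *
      ((1 - m$r[2]) * (z[2] == z[1]) + m$r[2] * m$alpha[2, z[2]]) *
      (1 - m$theta[2, z[2]])
  })
  pr <- pr / sum(pr)
  n <- 1e5
  Z <- posterior_latent_sample(m, matrix(rep(h, each = n), n, 2), seed = 42)
  emp <- as.vector(table(factor(paste(Z[, 1], Z[, 2]),
                                levels = paste(paths[, 1], paths[, 2])))) / n
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(emp - pr) < 3 * se + 1e-4))
  # single cluster: constant path
  m1 <- haplotype_hmm(matrix(1, 3, 1), matrix(0.5, 3, 1), c(1, 0.3, 0.3))
  expect_true(all(posterior_latent_sample(m1, matrix(0L, 2, 3), seed = 1) == 1L))
})

test_that("near-deterministic emissions pin the posterior to the true path", {
  # one-hot emissions identify the state at every site
  p <- 3
  theta <- matrix(c(0.999, 0.001), p, 2, byrow = TRUE)
  m <- haplotype_hmm(matrix(0.5, p, 2), theta, c(1, 0.5, 0.5))
  h <- c(1L, 0L, 1L)
  Z <- posterior_latent_sample(m, matrix(rep(h, each = 500), 500, p), seed = 7)
  expect_gt(mean(Z[, 1] == 1 & Z[, 2] == 2 & Z[, 3] == 1), 0.95)
})

test_that("model serialization round-trips bit-exactly", {
  m <- tiny_hmm(7, 3, seed = 51)
  f <- tempfile(fileext = ".txt")
  write_hmm(m, f)
  m2 <- read_hmm(f)
  expect_identical(m$alpha, m2$alpha)
  expect_identical(m$theta, m2$theta)
  expect_identical(m$r, m2$r)
  expect_identical(m$positions, m2$positions)
  unlink(f)
})

test_that("invalid inputs are rejected", {
  expect_error(fit_hmm_em(matrix(c(0, 2), 2, 1), K = 1), "binary")
  expect_error(fit_hmm_em(matrix(0L, 2, 3), K = 5), "degenerate")
  m <- tiny_hmm(4, 2)
  expect_error(haplotype_loglik(m, matrix(0L, 2, 3)), "mismatch")
  expect_error(haplotype_hmm(matrix(1, 2, 1), matrix(0.5, 2, 1), c(0.5, 0.5)),
               "r\\[1\\]")
  # impossible observation under a degenerate model
  m0 <- haplotype_hmm(matrix(1, 2, 1), matrix(0, 2, 1), c(1, 0.5))
  expect_error(posterior_latent_sample(m0, matrix(1L, 1, 2)), "impossible")
})
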