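test_that("conditional probabilities are a symmetric softmax at zero parameters", {
  P <- conditional_prob_matrix(matrix(0, 3, 2), matrix(0, 4, 2))
  expect_equal(dim(P), c(4L, 3L))
  expect_true(all(abs(P - 0.25) < 1e-15))
})

test_that("conditional probability columns are normalized and match hand softmax", {
  # one taxon, two metabolites, L = 1: column = softmax(1, -1)
  P <- conditional_prob_matrix(matrix(1, 1, 1), matrix(c(1, -1), 2, 1))
  expect_equal(P[, 1], exp(c(1, -1)) / sum(exp(c(1, -1))), tolerance = 1e-12)
  expect_equal(P[1, 1], 0.8808, tolerance = 1e-4)

  # normalization holds across random parameterizations
  set.seed(42)
  for (i in 1:100) {
    N <- sample(2:8, 1); M <- sample(2:9, 1); L <- sample(1:4, 1)
    P <- conditional_prob_matrix(matrix(rnorm(N * L, 0, 3), N, L),
                                 matrix(rnorm(M * L, 0, 3), M, L),
                                 v_bias = rnorm(M, 0, 2),
                                 u_bias = rnorm(N, 0, 2))
    expect_lt(max(abs(colSums(P) - 1)), 1e-10)
  }
})

test_that("conditional probabilities survive extreme logits and reject bad input", {
  P <- conditional_prob_matrix(matrix(400, 1, 1), matrix(c(2, -2), 2, 1))
  expect_true(all(is.finite(P)))
  expect_equal(colSums(P), 1, ignore_attr = TRUE)
  expect_error(conditional_prob_matrix(matrix(0, 2, 2), matrix(0, 3, 1)),
               "latent dimensions differ")
  expect_error(conditional_prob_matrix(matrix(NaN, 2, 1), matrix(0, 3, 1)),
               "non-finite")
})

test_that("taxon bias cancels out of the conditional distribution", {
  set.seed(5)
  U <- matrix(rnorm(6), 3, 2); V <- matrix(rnorm(8), 4, 2)
  P1 <- conditional_prob_matrix(U, V, u_bias = rnorm(3, 0, 5))
  P2 <- conditional_prob_matrix(U, V)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("multinomial log-likelihood follows the weighted cross-entropy form", {
  expect_equal(multinomial_loglik(c(2, 1), c(0.5, 0.5)), 3 * log(0.5))
  expect_equal(multinomial_loglik(c(7, 0, 0), c(1, 0, 0)), 0)  # certain outcome
  expect_equal(multinomial_loglik(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  # non-integer abundances are accepted
  expect_equal(multinomial_loglik(c(1.5, 2.5), c(0.4, 0.6)),
               1.5 * log(0.4) + 2.5 * log(0.6))
  expect_warning(ll <- multinomial_loglik(c(1, 1), c(1, 0)), "-Inf")
  expect_identical(ll, -Inf)
  expect_error(multinomial_loglik(c(-1, 2), c(0.5, 0.5)), "negative")
  expect_error(multinomial_loglik(c(1, 1), c(0.9, 0.4)), "probability")
})

test_that("Gaussian KL has its closed form and vanishes at the prior", {
  expect_equal(gaussian_kl(0, 1, 1), 0)
  expect_equal(gaussian_kl(1, 1, 1), 0.5)
  expect_equal(gaussian_kl(0.3, 0.7, 2),
               log(2 / 0.7) + (0.49 + 0.09) / 8 - 0.5)
  expect_error(gaussian_kl(0, -1, 1), "positive")
  set.seed(1)
  kl <- gaussian_kl(rnorm(1000), exp(rnorm(1000)), exp(rnorm(1000)))
  expect_true(all(kl >= 0))
})

test_that("Bernoulli KL has its closed form, symmetry and non-negativity", {
  expect_equal(bernoulli_kl(0.3, 0.3), 0)
  expect_equal(bernoulli_kl(0.5, 0.1),
               0.5 * log(0.5 / 0.1) + 0.5 * log(0.5 / 0.9))
  expect_equal(bernoulli_kl(0.5, 0.1), 0.5108, tolerance = 1e-4)
  set.seed(2)
  xi <- runif(1000, 0.01, 0.99); lam <- runif(1000, 0.01, 0.99)
  expect_true(all(bernoulli_kl(xi, lam) >= 0))
  expect_equal(bernoulli_kl(xi, lam), bernoulli_kl(1 - xi, 1 - lam))
  expect_warning(b <- bernoulli_kl(1, 0.5), "clipped")
  expect_true(is.finite(b))
})

test_that("closed-form KLs agree with Monte Carlo estimates", {
  # independent oracle: KL = E_q[log q - log p] under draws from q
  set.seed(99)
  n <- 1e6
  for (rep in 1:20) {
    a <- rnorm(1); b <- exp(rnorm(1, 0, 0.5)); b0 <- exp(rnorm(1, 0, 0.5))
    x <- rnorm(n, a, b)
    terms <- dnorm(x, a, b, log = TRUE) - dnorm(x, 0, b0, log = TRUE)
    se <- sd(terms) / sqrt(n)
    expect_lt(abs(mean(terms) - gaussian_kl(a, b, b0)), 3 * se + 1e-12)

    xi <- runif(1, 0.05, 0.95); lam <- runif(1, 0.05, 0.95)
    z <- rbinom(n, 1, xi)
    bt <- z * log(xi / lam) + (1 - z) * log((1 - xi) / (1 - lam))
    bse <- sd(bt) / sqrt(n)
    expect_lt(abs(mean(bt) - bernoulli_kl(xi, lam)), 3 * bse + 1e-12)
  }
})

test_that("spike-and-slab KL vanishes at the prior and sums its two parts", {
  N <- 4; L <- 2
  at_prior <- spike_slab_posterior(matrix(0, N, L), matrix(1, N, L),
                                   matrix(0.1, N, L), rep(0, N), rep(1, N),
                                   prior_beta0_u = 1, prior_lambda = 0.1)
  expect_equal(spike_slab_kl_total(at_prior), 0, tolerance = 1e-12)

  single <- spike_slab_posterior(matrix(1), matrix(1), matrix(0.5),
                                 0, 1, prior_beta0_u = 1, prior_lambda = 0.1)
  expect_equal(spike_slab_kl_total(single),
               bernoulli_kl(0.5, 0.1) + 0.5 * gaussian_kl(1, 1, 1))
  expect_equal(spike_slab_kl_total(single), 0.7608, tolerance = 1e-4)

  set.seed(3)
  for (i in 1:20) {
    p <- random_posteriors(5, 3, 2, seed = i)
    expect_gte(spike_slab_kl_total(p$ss), 0)
  }
})

test_that("Gumbel-softmax relaxation is symmetric, monotone and sharpens", {
  # symmetry point: zeta = 0 for any temperature
  for (iota in c(0.5, 1, 3)) {
    expect_equal(gumbel_softmax_relax(0.5, iota, 0.5), 0.5)
  }
  # strictly increasing in xi at fixed kappa
  xi <- seq(0.05, 0.95, by = 0.05)
  g <- gumbel_softmax_relax(xi, 0.5, kappa = 0.3)
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0 & g < 1))
  # low-temperature limit approaches the indicator 1{zeta > 0}
  set.seed(4)
  xi <- runif(200, 0.01, 0.99); kap <- runif(200, 0.01, 0.99)
  hard <- as.numeric(qlogis(xi) + qlogis(kap) > 0)
  soft <- gumbel_softmax_relax(xi, 1e-4, kap)
  expect_lt(max(abs(soft - hard)), 1e-6)
  expect_error(gumbel_softmax_relax(0.5, -1, 0.5), "positive")
})

test_that("relaxed inclusion draws average to a value monotone in xi", {
  set.seed(8)
  kap <- runif(20000)
  means <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(x) mean(gumbel_softmax_relax(x, 0.5, kap)),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("default prior inclusion rate matches its closed form", {
  # printed worked example for a 4702-taxon, 92-sample, L = 3 analysis
  expect_equal(default_lambda(4702, 92, 3), 4.48e-6, tolerance = 0.02)
  # direct evaluation at small dimensions
  expect_equal(default_lambda(10, 4, 3),
               exp(-(log(33) + 0.1 * (2 * log(10) + log(20)))))
  expect_equal(default_lambda(10, 4, 3), 0.01417, tolerance = 1e-3)
  # strictly decreasing in N
  lams <- vapply(c(10, 50, 200, 1000, 5000), default_lambda,
                 numeric(1), K = 50, L = 3)
  expect_true(all(diff(lams) < 0))
  expect_error(default_lambda(0, 10, 3), ">= 1")
})
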