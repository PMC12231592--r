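# shared fixtures, generated in code

# tiny deterministic dataset for contract tests
tiny_dataset <- function(K = 5, N = 6, M = 4, seed = 11) {
  set.seed(seed)
  X <- matrix(rpois(K * N, 8) + 1L, K, N)
  Y <- matrix(rpois(K * M, 20) + 1L, K, M)
  paired_omics_dataset(X, Y)
}

# random valid posteriors for property tests
random_posteriors <- function(N, M, L, seed = 1, lambda = 0.1) {
  set.seed(seed)
  ss <- spike_slab_posterior(
    alpha_U = matrix(rnorm(N * L, 0, 0.5), N, L),
    beta_U = matrix(exp(rnorm(N * L, -1, 0.3)), N, L),
    xi = matrix(runif(N * L, 0.05, 0.95), N, L),
    u_bias_alpha = rnorm(N, 0, 0.3),
    u_bias_beta = exp(rnorm(N, -1, 0.3)),
    prior_lambda = lambda
  )
  g <- gaussian_posterior(
    alpha_V = matrix(rnorm(M * L, 0, 0.5), M, L),
    beta_V = matrix(exp(rnorm(M * L, -1, 0.3)), M, L),
    v_bias_alpha = rnorm(M, 0, 0.3),
    v_bias_beta = exp(rnorm(M, -1, 0.3))
  )
  list(ss = ss, g = g)
}

# small, quick fit configuration for pipeline tests
quick_config <- function(...) {
  model_config(epochs = 300L, batch_size = 200L, seed = 1L, ...)
}
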