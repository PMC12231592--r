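#' Model and optimizer configuration
#'
#' Collects every tunable of the model and its stochastic optimizer. Defaults
#' follow the published settings of the method family: latent dimension 3,
#' Adam with learning rate 0.1 and decay rates 0.8 / 0.9, Gumbel-softmax
#' temperature 0.5 (the stability floor; values below it are clamped with a
#' warning), and the network-size-aware default inclusion rate
#' ([default_lambda()]) when `lambda = "auto"`.
#'
#' @param latent_dim latent dimension `L` (positive integer).
#' @param temperature Gumbel-softmax temperature; clamped to >= 0.5.
#' @param lambda `"auto"` or an explicit prior inclusion rate in (0, 1).
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2 Adam exponential decay rates in (0, 1).
#' @param batch_size number of (sample, taxon) pairs per stochastic gradient
#'   step.
#' @param epochs number of stochastic gradient steps (one minibatch of
#'   `batch_size` pairs per step).
#' @param mc_samples Monte Carlo draws per gradient step; 1 is standard
#'   stochastic variational practice.
#' @param seed integer seed controlling initialization, minibatches and noise.
#' @param spike_slab_enabled if `FALSE`, the taxon embeddings get a plain
#'   Gaussian posterior (no selection); inclusion probabilities are then
#'   reported as 1.
#' @param mode `"vb"` for variational inference, `"map"` for the maximum a
#'   posteriori point-estimate baseline.
#' @param prior_beta0_u,prior_beta0_v prior scales of the Gaussian slab for
#'   taxa and of the metabolite prior (standard normal by default).
#' @param anchor_reference fix the first metabolite's embedding row and bias
#'   at zero as the softmax reference cell, removing the translation
#'   degeneracy of the decoder.
#' @param eval_every compute training/validation MAE every this many steps.
#' @return object of class `spikemm_config` (a validated list).
#' @export
model_config <- function(latent_dim = 3L, temperature = 0.5, lambda = "auto",
                         learning_rate = 0.1, adam_beta1 = 0.8,
                         adam_beta2 = 0.9, batch_size = 500L, epochs = 5000L,
                         mc_samples = 1L, seed = 1L, spike_slab_enabled = TRUE,
                         mode = c("vb", "map"), prior_beta0_u = 1,
                         prior_beta0_v = 1, anchor_reference = TRUE,
                         eval_every = 10L) {
  mode <- match.arg(mode)
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  if (temperature < 0.5) {
    warning("temperature below the 0.5 stability floor; clamped to 0.5")
    temperature <- 0.5
  }
  if (!identical(lambda, "auto")) {
    lambda <- as.numeric(lambda)
    if (lambda <= 0 || lambda >= 1) stop("lambda must be 'auto' or in (0, 1)")
  }
  for (r in c(adam_beta1, adam_beta2)) {
    if (r <= 0 || r >= 1) stop("Adam decay rates must lie in (0, 1)")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (mc_samples < 1L) stop("mc_samples must be >= 1")
  if (prior_beta0_u <= 0 || prior_beta0_v <= 0) stop("prior scales must be positive")
  structure(list(latent_dim = latent_dim, temperature = temperature,
                 lambda = lambda, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 mc_samples = as.integer(mc_samples), seed = as.integer(seed),
                 spike_slab_enabled = isTRUE(spike_slab_enabled), mode = mode,
                 prior_beta0_u = prior_beta0_u, prior_beta0_v = prior_beta0_v,
                 anchor_reference = isTRUE(anchor_reference),
                 eval_every = as.integer(eval_every)),
            class = "spikemm_config")
}

# resolve "auto" lambda against dataset dimensions
resolve_lambda <- function(cfg, N, K) {
  if (identical(cfg$lambda, "auto")) default_lambda(N, K, cfg$latent_dim)
  else cfg$lambda
}
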