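#' Conditional metabolite probabilities given each taxon
#'
#' Computes the column-stochastic matrix `P` with `P[j, i]` the probability of
#' observing metabolite `j` given a read of taxon `i`, from the softmax of the
#' inner products of the latent embeddings plus biases:
#' `P[j, i] = exp(v_j . u_i + v_j0 + u_i0) / sum_m exp(v_m . u_i + v_m0 + u_i0)`.
#' The per-taxon bias enters numerator and denominator alike, so it cancels;
#' it is accepted for interface completeness. Logits are max-subtracted per
#' column before exponentiation for overflow safety.
#'
#' @param U numeric matrix, `N x L`: taxon embeddings (posterior means or draws).
#' @param V numeric matrix, `M x L`: metabolite embeddings.
#' @param v_bias numeric length-`M` metabolite bias (default zeros).
#' @param u_bias numeric length-`N` taxon bias (default zeros); has no effect
#'   on the result but is validated for finiteness.
#' @return `M x N` matrix with non-negative entries; every column sums to 1.
#' @examples
#' P <- conditional_prob_matrix(matrix(0, 2, 1), matrix(0, 4, 1))
#' colSums(P)  # each exactly 1
#' @export
conditional_prob_matrix <- function(U, V, v_bias = NULL, u_bias = NULL) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) != ncol(V)) {
    stop("latent dimensions differ: U has ", ncol(U), ", V has ", ncol(V))
  }
  if (is.null(v_bias)) v_bias <- numeric(nrow(V))
  if (is.null(u_bias)) u_bias <- numeric(nrow(U))
  if (length(v_bias) != nrow(V)) stop("v_bias length must equal nrow(V)")
  if (length(u_bias) != nrow(U)) stop("u_bias length must equal nrow(U)")
  if (!all(is.finite(U)) || !all(is.finite(V)) ||
      !all(is.finite(v_bias)) || !all(is.finite(u_bias))) {
    stop("non-finite embedding or bias values")
  }
  logits <- tcrossprod(V, U) + v_bias        # M x N; bias recycles down columns
  logits <- sweep(logits, 2L, apply(logits, 2L, max))
  num <- exp(logits)
  sweep(num, 2L, colSums(num), "/")
}

#' Multinomial log-likelihood up to the multinomial coefficient
#'
#' Returns `sum_j y_j * log(p_j)`. The multinomial coefficient is dropped: it
#' is constant in the model parameters, so objective values are comparable
#' only within this convention. Non-integer `y` (e.g. mass-spectrometry
#' intensities) are accepted; the quantity is then a weighted cross-entropy.
#' Terms with `y_j = 0` contribute zero even when `p_j = 0`.
#'
#' @param y non-negative numeric vector of observed abundances.
#' @param p probability vector of the same length.
#' @return scalar; `-Inf` (with a warning) if some `p_j = 0` where `y_j > 0`.
#' @export
multinomial_loglik <- function(y, p) {
  if (length(y) != length(p)) stop("y and p lengths differ")
  if (any(y < 0)) stop("negative abundances in y")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) stop("p is not a probability vector")
  pos <- y > 0
  if (any(p[pos] == 0)) {
    warning("p_j = 0 where y_j > 0: log-likelihood is -Inf")
    return(-Inf)
  }
  sum(y[pos] * log(p[pos]))
}

#' KL divergence between two univariate Gaussians with zero-mean reference
#'
#' `KL[N(alpha, beta^2) || N(0, beta0^2)]`, elementwise-broadcastable:
#' `log(beta0/beta) + (beta^2 + alpha^2) / (2 beta0^2) - 1/2`.
#'
#' @param alpha mean(s) of the variational Gaussian.
#' @param beta positive scale(s) of the variational Gaussian.
#' @param beta0 positive prior scale(s).
#' @return non-negative value(s), same shape as the broadcast arguments.
#' @export
gaussian_kl <- function(alpha, beta, beta0) {
  if (any(beta <= 0) || any(beta0 <= 0)) stop("scales must be positive")
  log(beta0 / beta) + (beta^2 + alpha^2) / (2 * beta0^2) - 0.5
}

#' KL divergence between two Bernoulli distributions
#'
#' `xi log(xi/lam) + (1 - xi) log((1 - xi)/(1 - lam))`. Arguments at or
#' beyond the open-interval boundary are clipped to `[1e-8, 1 - 1e-8]` with a
#' warning.
#'
#' @param xi variational inclusion probability/probabilities in (0, 1).
#' @param lam prior inclusion probability/probabilities in (0, 1).
#' @return non-negative value(s).
#' @export
bernoulli_kl <- function(xi, lam) {
  if (any(xi <= 0 | xi >= 1) || any(lam <= 0 | lam >= 1)) {
    warning("Bernoulli parameters at the boundary clipped to [1e-8, 1 - 1e-8]")
    xi <- clip01(xi); lam <- clip01(lam)
  }
  xi * log(xi / lam) + (1 - xi) * log((1 - xi) / (1 - lam))
}

#' Total spike-and-slab KL penalty of a taxon posterior
#'
#' Sums, over all `N x L` embedding elements, the Bernoulli KL between the
#' variational inclusion probability and the prior inclusion rate plus the
#' inclusion-weighted Gaussian slab KL:
#' `sum_il [ KL_Bern(xi_il, lambda) + xi_il * KL_Gauss(alpha_il, beta_il, beta0) ]`.
#' Bias terms are not part of this penalty (biases carry a plain Gaussian
#' posterior; see [fit_spikemm()]).
#'
#' @param ss a [spike_slab_posterior()] object.
#' @return non-negative scalar.
#' @export
spike_slab_kl_total <- function(ss) {
  stopifnot(inherits(ss, "spike_slab_posterior"))
  sum(bernoulli_kl(ss$xi, ss$prior_lambda) +
        ss$xi * gaussian_kl(ss$alpha_U, ss$beta_U, ss$prior_beta0_u))
}

#' Gumbel-softmax relaxation of a Bernoulli draw
#'
#' Continuous, differentiable surrogate for sampling `Bernoulli(xi)`:
#' `zeta = logit(xi) + logit(kappa)` with `kappa ~ U(0,1)`, and
#' `gamma_bar = (1 + exp(-zeta / iota))^-1`. As the temperature `iota`
#' approaches 0 the output sharpens to the indicator `1{zeta > 0}`, which
#' equals 1 with probability `xi`.
#'
#' @param xi inclusion probability/probabilities in (0, 1); boundary values
#'   are clipped to `[1e-8, 1 - 1e-8]`.
#' @param iota positive temperature; the model default is 0.5.
#' @param kappa uniform noise draw(s) in (0, 1), clipped like `xi`.
#' @return relaxed inclusion value(s) in (0, 1).
#' @export
gumbel_softmax_relax <- function(xi, iota, kappa) {
  if (any(iota <= 0)) stop("temperature must be positive")
  xi <- clip01(xi); kappa <- clip01(kappa)
  zeta <- qlogis(xi) + qlogis(kappa)
  plogis(zeta / iota)
}

#' Default prior inclusion rate for the spike-and-slab prior
#'
#' The network-size-aware default for the Bernoulli prior rate `lambda`:
#' `log(1/lambda) = log((N + 1) L) + 0.1 (2 log N + log(sqrt(K) N))`
#' (natural logarithms). Larger taxon counts give smaller `lambda`, i.e.
#' stronger sparsity, preventing overfitting when features are numerous.
#'
#' @param N number of taxa (>= 1).
#' @param K number of samples (>= 1).
#' @param L latent dimension (>= 1).
#' @return scalar in (0, 1).
#' @examples
#' default_lambda(N = 4702, K = 92, L = 3)  # ~4.47e-6
#' @export
default_lambda <- function(N, K, L) {
  if (N < 1 || K < 1 || L < 1) stop("N, K and L must be >= 1")
  exp(-(log((N + 1) * L) + 0.1 * (2 * log(N) + log(sqrt(K) * N))))
}
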