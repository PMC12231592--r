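#' Spike-and-slab variational posterior over taxon embeddings
#'
#' Container for the variational family of the taxon side of the model: each
#' embedding element `U[i, l]` has posterior
#' `q(U_il) = xi_il N(alpha_il, beta_il^2) + (1 - xi_il) delta_0`, and each
#' taxon bias has a plain Gaussian posterior. The sparsifying mixture applies
#' to the embedding matrix only; biases always carry the slab.
#'
#' @param alpha_U `N x L` matrix of slab means.
#' @param beta_U `N x L` matrix of positive slab scales (may be `NA` for
#'   point-estimate fits, flagged via `point_estimate`).
#' @param xi `N x L` matrix of inclusion probabilities in (0, 1).
#' @param u_bias_alpha,u_bias_beta length-`N` bias posterior mean and scale.
#' @param prior_beta0_u positive prior scale of the slab.
#' @param prior_lambda prior inclusion rate in (0, 1).
#' @param point_estimate logical; `TRUE` for MAP fits whose "posterior" is a
#'   point mass (scales are then `NA` and not validated).
#' @return object of class `spike_slab_posterior`.
#' @export
spike_slab_posterior <- function(alpha_U, beta_U, xi, u_bias_alpha, u_bias_beta,
                                 prior_beta0_u = 1, prior_lambda = 0.1,
                                 point_estimate = FALSE) {
  alpha_U <- as.matrix(alpha_U); beta_U <- as.matrix(beta_U); xi <- as.matrix(xi)
  stopifnot(all(dim(alpha_U) == dim(beta_U)), all(dim(alpha_U) == dim(xi)),
            length(u_bias_alpha) == nrow(alpha_U),
            length(u_bias_beta) == nrow(alpha_U))
  if (!point_estimate && (any(beta_U <= 0) || any(u_bias_beta <= 0))) {
    stop("posterior scales must be positive")
  }
  if (any(xi <= 0 | xi >= 1)) stop("xi must lie strictly in (0, 1)")
  if (prior_beta0_u <= 0) stop("prior_beta0_u must be positive")
  if (prior_lambda <= 0 || prior_lambda >= 1) {
    stop("prior_lambda must lie strictly in (0, 1)")
  }
  structure(list(alpha_U = alpha_U, beta_U = beta_U, xi = xi,
                 u_bias_alpha = as.numeric(u_bias_alpha),
                 u_bias_beta = as.numeric(u_bias_beta),
                 prior_beta0_u = prior_beta0_u, prior_lambda = prior_lambda,
                 point_estimate = point_estimate),
            class = "spike_slab_posterior")
}

#' Gaussian variational posterior over metabolite embeddings
#'
#' Each metabolite embedding element and bias has posterior
#' `N(alpha, beta^2)`. When the model anchors a reference metabolite (see
#' [fit_spikemm()]), `reference` records its row index: that row's embedding
#' and bias are fixed at zero to pin the softmax translation degeneracy.
#'
#' @param alpha_V `M x L` matrix of means.
#' @param beta_V `M x L` matrix of positive scales (`NA` allowed when
#'   `point_estimate`).
#' @param v_bias_alpha,v_bias_beta length-`M` bias posterior mean and scale.
#' @param prior_beta0_v positive prior scale.
#' @param reference integer row index of the anchored reference metabolite,
#'   or `NA` when no anchoring is used.
#' @param point_estimate logical, as in [spike_slab_posterior()].
#' @return object of class `gaussian_posterior`.
#' @export
gaussian_posterior <- function(alpha_V, beta_V, v_bias_alpha, v_bias_beta,
                               prior_beta0_v = 1, reference = NA_integer_,
                               point_estimate = FALSE) {
  alpha_V <- as.matrix(alpha_V); beta_V <- as.matrix(beta_V)
  stopifnot(all(dim(alpha_V) == dim(beta_V)),
            length(v_bias_alpha) == nrow(alpha_V),
            length(v_bias_beta) == nrow(alpha_V))
  if (!point_estimate && (any(beta_V <= 0) || any(v_bias_beta <= 0))) {
    stop("posterior scales must be positive")
  }
  if (prior_beta0_v <= 0) stop("prior_beta0_v must be positive")
  structure(list(alpha_V = alpha_V, beta_V = beta_V,
                 v_bias_alpha = as.numeric(v_bias_alpha),
                 v_bias_beta = as.numeric(v_bias_beta),
                 prior_beta0_v = prior_beta0_v, reference = reference,
                 point_estimate = point_estimate),
            class = "gaussian_posterior")
}

#' Posterior-mean embeddings
#'
#' The expected taxon embedding under the spike-and-slab family is
#' `E_q[gamma * u] = xi * alpha` (the spike contributes zero); the metabolite
#' embedding mean is `alpha_V`. For point-estimate (MAP) fits the stored
#' points are returned unchanged.
#'
#' @param ss a [spike_slab_posterior()].
#' @param g a [gaussian_posterior()].
#' @return list with `U`, `V`, `u_bias`, `v_bias`.
#' @export
posterior_mean_embeddings <- function(ss, g) {
  U <- if (ss$point_estimate) ss$alpha_U else ss$xi * ss$alpha_U
  list(U = U, V = g$alpha_V, u_bias = ss$u_bias_alpha, v_bias = g$v_bias_alpha)
}
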