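# Internal numerical engine.
#
# All optimization runs in unconstrained coordinates:
#   alpha (means)            -- unconstrained
#   rho   (scales)           -- beta = softplus(rho) > 0
#   phi   (inclusion logits) -- xi = plogis(phi) in (0, 1)
# The Gumbel-softmax relaxation makes the Bernoulli inclusion draws
# differentiable, so a single reparameterized Monte Carlo draw per step gives
# an unbiased, low-cost ELBO gradient.

# --- parameter blocks -------------------------------------------------------

init_vb_params <- function(N, M, L, init_scale = 0.1) {
  rho0 <- softplus_inv(init_scale)
  list(
    aU = matrix(rnorm(N * L, 0, init_scale), N, L),
    rU = matrix(rho0, N, L),
    phi = matrix(qlogis(clip01(runif(N * L))), N, L),
    aV = matrix(rnorm(M * L, 0, init_scale), M, L),
    rV = matrix(rho0, M, L),
    au0 = rnorm(N, 0, init_scale),
    ru0 = rep(rho0, N),
    av0 = rnorm(M, 0, init_scale),
    rv0 = rep(rho0, M)
  )
}

init_map_params <- function(N, M, L, init_scale = 0.1) {
  list(
    aU = matrix(rnorm(N * L, 0, init_scale), N, L),
    aV = matrix(rnorm(M * L, 0, init_scale), M, L),
    au0 = rnorm(N, 0, init_scale),
    av0 = rnorm(M, 0, init_scale)
  )
}

# one fresh noise draw per parameter element (kappa for inclusions, epsilon
# for Gaussians); the taxon bias needs no draw because it cancels in the
# decoder softmax and its posterior is driven by its KL term alone.
draw_noise <- function(N, M, L, spike = TRUE) {
  list(
    epsU = matrix(rnorm(N * L), N, L),
    epsV = matrix(rnorm(M * L), M, L),
    epsv0 = rnorm(M),
    kappa = if (spike) matrix(clip01(runif(N * L)), N, L) else NULL
  )
}

# --- data-term statistics ---------------------------------------------------

# Weighted softmax cross-entropy statistics. The data term of the objective is
#   sum_{k,i} w_ki * sum_j Y_kj log P[j, i]
# which only needs Cyx[j, i] = sum_k w_ki Y_kj and D[i] = sum_k w_ki W_k
# (W_k = total metabolite abundance of sample k). `cols` restricts the
# computation to taxa with nonzero weight.
full_data_stats <- function(X, Y) {
  list(Cyx = crossprod(Y, X), D = as.vector(crossprod(X, rowSums(Y))),
       cols = seq_len(ncol(X)))
}

minibatch_data_stats <- function(ks, is, Y, Wk, w, K, N) {
  cols <- sort(unique(is))
  Wt <- Matrix::sparseMatrix(i = ks, j = match(is, cols), x = rep(w, length(ks)),
                             dims = c(K, length(cols)))
  list(Cyx = as.matrix(Matrix::crossprod(Wt, Y)) |> t(),
       D = as.vector(Matrix::crossprod(Wt, Wk)), cols = cols)
}

# value and gradients of the data term w.r.t. the sampled embeddings;
# stats$Cyx and stats$D are already restricted to (and aligned with)
# stats$cols
data_term <- function(Us, Vs, v0s, stats) {
  Uc <- Us[stats$cols, , drop = FALSE]
  lg <- tcrossprod(Vs, Uc) + v0s                       # M x nc
  lg <- sweep(lg, 2L, apply(lg, 2L, max))
  lse <- log(colSums(exp(lg)))
  logP <- sweep(lg, 2L, lse)
  P <- exp(logP)
  R <- stats$Cyx - sweep(P, 2L, stats$D, "*")
  list(value = sum(stats$Cyx * logP),
       gVs = R %*% Uc, gv0s = rowSums(R),
       gUs_cols = crossprod(R, Vs), cols = stats$cols)
}

# --- VB objective: stochastic ELBO value + gradient -------------------------

# Single-draw reparameterized ELBO estimate and its exact gradient in
# unconstrained coordinates. `stats` carries the (possibly minibatch-weighted)
# data statistics; KL terms are always full.
vb_value_grad <- function(th, stats, noise, opts) {
  N <- nrow(th$aU); M <- nrow(th$aV); L <- ncol(th$aU)
  bU <- softplus(th$rU); bV <- softplus(th$rV)
  bu0 <- softplus(th$ru0); bv0 <- softplus(th$rv0)
  b0u <- opts$prior_beta0_u; b0v <- opts$prior_beta0_v

  if (opts$spike) {
    xi <- clip01(plogis(th$phi))
    zeta <- qlogis(xi) + qlogis(noise$kappa)
    gbar <- plogis(zeta / opts$iota)
    Us <- gbar * (th$aU + bU * noise$epsU)
  } else {
    Us <- th$aU + bU * noise$epsU
  }
  Vs <- th$aV + bV * noise$epsV
  v0s <- th$av0 + bv0 * noise$epsv0
  if (!is.na(opts$anchor)) {
    Vs[opts$anchor, ] <- 0
    v0s[opts$anchor] <- 0
  }

  dt <- data_term(Us, Vs, v0s, stats)
  gUs <- matrix(0, N, L); gUs[dt$cols, ] <- dt$gUs_cols
  gVs <- dt$gVs; gv0s <- dt$gv0s

  sigrU <- plogis(th$rU); sigrV <- plogis(th$rV)
  sigru0 <- plogis(th$ru0); sigrv0 <- plogis(th$rv0)

  # chain through the reparameterization
  if (opts$spike) {
    g_aU <- gbar * gUs
    g_rU <- gbar * noise$epsU * gUs * sigrU
    g_phi <- gUs * (th$aU + bU * noise$epsU) * gbar * (1 - gbar) / opts$iota
  } else {
    g_aU <- gUs
    g_rU <- noise$epsU * gUs * sigrU
    g_phi <- NULL
  }
  g_aV <- gVs
  g_rV <- gVs * noise$epsV * sigrV
  g_av0 <- gv0s
  g_rv0 <- gv0s * noise$epsv0 * sigrv0
  g_au0 <- numeric(N)   # taxon bias cancels in the softmax
  g_ru0 <- numeric(N)

  # KL penalties (closed form, noise-free)
  gklU <- gaussian_kl(th$aU, bU, b0u)
  if (opts$spike) {
    klU <- sum(xi * log(xi / opts$lambda) +
                 (1 - xi) * log((1 - xi) / (1 - opts$lambda)) + xi * gklU)
    g_aU <- g_aU - xi * th$aU / b0u^2
    g_rU <- g_rU - xi * (bU / b0u^2 - 1 / bU) * sigrU
    g_phi <- g_phi - (qlogis(xi) - qlogis(opts$lambda) + gklU) * xi * (1 - xi)
  } else {
    klU <- sum(gklU)
    g_aU <- g_aU - th$aU / b0u^2
    g_rU <- g_rU - (bU / b0u^2 - 1 / bU) * sigrU
  }
  klu0 <- sum(gaussian_kl(th$au0, bu0, b0u))
  g_au0 <- g_au0 - th$au0 / b0u^2
  g_ru0 <- g_ru0 - (bu0 / b0u^2 - 1 / bu0) * sigru0

  klVm <- gaussian_kl(th$aV, bV, b0v)
  klv0 <- gaussian_kl(th$av0, bv0, b0v)
  g_aV <- g_aV - th$aV / b0v^2
  g_rV <- g_rV - (bV / b0v^2 - 1 / bV) * sigrV
  g_av0 <- g_av0 - th$av0 / b0v^2
  g_rv0 <- g_rv0 - (bv0 / b0v^2 - 1 / bv0) * sigrv0
  if (!is.na(opts$anchor)) {
    a <- opts$anchor
    klVm[a, ] <- 0; klv0[a] <- 0
    g_aV[a, ] <- 0; g_rV[a, ] <- 0; g_av0[a] <- 0; g_rv0[a] <- 0
  }

  grad <- list(aU = g_aU, rU = g_rU, aV = g_aV, rV = g_rV,
               au0 = g_au0, ru0 = g_ru0, av0 = g_av0, rv0 = g_rv0)
  if (opts$spike) grad$phi <- g_phi
  list(value = dt$value - klU - klu0 - sum(klVm) - sum(klv0), grad = grad)
}

# --- MAP objective: penalized log-likelihood value + gradient ---------------

# Gaussian log-prior (up to additive constants) plus the multinomial data
# term, evaluated at point parameters.
map_value_grad <- function(th, stats, opts) {
  N <- nrow(th$aU); L <- ncol(th$aU)
  Vs <- th$aV; v0s <- th$av0
  if (!is.na(opts$anchor)) {
    Vs[opts$anchor, ] <- 0
    v0s[opts$anchor] <- 0
  }
  dt <- data_term(th$aU, Vs, v0s, stats)
  gUs <- matrix(0, N, L); gUs[dt$cols, ] <- dt$gUs_cols
  b0u2 <- opts$prior_beta0_u^2; b0v2 <- opts$prior_beta0_v^2
  logprior <- -(sum(th$aU^2) + sum(th$au0^2)) / (2 * b0u2) -
    (sum(th$aV^2) + sum(th$av0^2)) / (2 * b0v2)
  grad <- list(aU = gUs - th$aU / b0u2,
               aV = dt$gVs - th$aV / b0v2,
               au0 = -th$au0 / b0u2,
               av0 = dt$gv0s - th$av0 / b0v2)
  if (!is.na(opts$anchor)) {
    grad$aV[opts$anchor, ] <- 0
    grad$av0[opts$anchor] <- 0
  }
  list(value = dt$value + logprior, grad = grad)
}

# --- Adam ascent ------------------------------------------------------------

adam_state <- function(th) {
  list(m = lapply(th, function(z) z * 0), v = lapply(th, function(z) z * 0),
       t = 0L)
}

adam_step <- function(th, grad, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grad)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    th[[nm]] <- th[[nm]] + lr * mhat / (sqrt(vhat) + eps)
  }
  list(th = th, state = state)
}

# engine options resolved from a config + dataset
engine_opts <- function(cfg, N, K, M) {
  list(iota = cfg$temperature,
       lambda = resolve_lambda(cfg, N, K),
       prior_beta0_u = cfg$prior_beta0_u,
       prior_beta0_v = cfg$prior_beta0_v,
       spike = cfg$spike_slab_enabled,
       anchor = if (cfg$anchor_reference) 1L else NA_integer_)
}

# posterior objects from unconstrained parameter blocks
params_to_posteriors <- function(th, opts, cfg, mode = "vb") {
  if (mode == "map") {
    N <- nrow(th$aU); M <- nrow(th$aV); L <- ncol(th$aU)
    ss <- spike_slab_posterior(th$aU, matrix(NA_real_, N, L),
                               matrix(1 - .EPS, N, L),
                               th$au0, rep(NA_real_, N),
                               prior_beta0_u = opts$prior_beta0_u,
                               prior_lambda = opts$lambda,
                               point_estimate = TRUE)
    g <- gaussian_posterior(th$aV, matrix(NA_real_, M, L),
                            th$av0, rep(NA_real_, M),
                            prior_beta0_v = opts$prior_beta0_v,
                            reference = opts$anchor, point_estimate = TRUE)
  } else {
    xi <- if (opts$spike) clip01(plogis(th$phi)) else
      matrix(1 - .EPS, nrow(th$aU), ncol(th$aU))
    ss <- spike_slab_posterior(th$aU, softplus(th$rU), xi,
                               th$au0, softplus(th$ru0),
                               prior_beta0_u = opts$prior_beta0_u,
                               prior_lambda = opts$lambda)
    g <- gaussian_posterior(th$aV, softplus(th$rV), th$av0, softplus(th$rv0),
                            prior_beta0_v = opts$prior_beta0_v,
                            reference = opts$anchor)
  }
  list(ss = ss, g = g)
}

# unconstrained parameter blocks from posterior objects (vb only)
posteriors_to_params <- function(ss, g) {
  list(aU = ss$alpha_U, rU = softplus_inv(ss$beta_U),
       phi = qlogis(clip01(ss$xi)),
       aV = g$alpha_V, rV = softplus_inv(g$beta_V),
       au0 = ss$u_bias_alpha, ru0 = softplus_inv(ss$u_bias_beta),
       av0 = g$v_bias_alpha, rv0 = softplus_inv(g$v_bias_beta))
}
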