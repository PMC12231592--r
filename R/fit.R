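#' Minibatch sampler over (sample, taxon) read pairs
#'
#' Returns a draw function that yields `batch_size` (sample, taxon) index
#' pairs per call. Samples are drawn proportional to their sequencing depth
#' and, within a sample, taxa proportional to their counts, so the empirical
#' pair frequencies converge to the proportions of the count matrix `X` and
#' the rescaled minibatch data term is an unbiased estimate of the full one.
#' All-zero sample rows are excluded with a warning. Draws consume the
#' current R random number stream, so a fixed seed gives a reproducible
#' stream.
#'
#' @param ds a [paired_omics_dataset()].
#' @param batch_size number of pairs per draw (>= 1).
#' @return function() returning a `batch_size x 2` integer matrix with
#'   columns `sample` and `taxon`.
#' @export
minibatch_sampler <- function(ds, batch_size) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  X <- ds$X
  depths <- rowSums(X)
  live <- which(depths > 0)
  if (length(live) < nrow(X)) {
    warning(nrow(X) - length(live), " all-zero sample row(s) excluded")
  }
  if (length(live) == 0L) stop("no samples with positive taxon totals")
  pk <- depths[live] / sum(depths[live])
  N <- ncol(X)
  function() {
    ks <- live[sample.int(length(live), batch_size, replace = TRUE, prob = pk)]
    is <- integer(batch_size)
    for (k in unique(ks)) {
      sel <- which(ks == k)
      is[sel] <- sample.int(N, length(sel), replace = TRUE, prob = X[k, ])
    }
    cbind(sample = ks, taxon = is)
  }
}

#' Fit the spike-and-slab variational model
#'
#' Maximizes the evidence lower bound by stochastic gradient ascent with Adam.
#' Each step draws a minibatch of (sample, taxon) pairs, one reparameterized
#' Gaussian noise draw per parameter and one Gumbel-softmax draw per inclusion
#' element, rescales the minibatch data term to full-data magnitude, and
#' updates means, scales and inclusion logits. With
#' `cfg$spike_slab_enabled = FALSE` the taxon posterior degenerates to a plain
#' Gaussian family and all Bernoulli terms drop from the objective.
#'
#' The fit is deterministic given `(ds, cfg)`: `cfg$seed` controls
#' initialization, minibatches and all noise.
#'
#' @param ds a [paired_omics_dataset()].
#' @param cfg a [model_config()] with `mode = "vb"`.
#' @param validation optional held-out [paired_omics_dataset()]; when given,
#'   validation MAE is recorded every `cfg$eval_every` steps.
#' @return object of class `spikemm_fit`: the final posteriors, per-taxon
#'   inclusion probabilities `gamma_tilde`, the co-occurrence
#'   log-probability matrix, the per-step ELBO trace, MAE traces, and the
#'   configuration used.
#' @export
fit_spikemm <- function(ds, cfg = model_config(), validation = NULL) {
  stopifnot(inherits(ds, "paired_omics"), inherits(cfg, "spikemm_config"))
  if (cfg$mode != "vb") stop("fit_spikemm requires cfg$mode = 'vb'; see fit_map()")
  K <- nrow(ds$X); N <- ncol(ds$X); M <- ncol(ds$Y)
  opts <- engine_opts(cfg, N = N, K = K, M = M)

  set.seed(cfg$seed)
  th <- init_vb_params(N, M, L = cfg$latent_dim)
  if (!opts$spike) th$phi <- NULL
  if (!is.na(opts$anchor)) {
    th$aV[opts$anchor, ] <- 0
    th$av0[opts$anchor] <- 0
  }
  state <- adam_state(th)
  draw_batch <- minibatch_sampler(ds, cfg$batch_size)
  Wk <- rowSums(ds$Y)
  w_scale <- sum(ds$X) / cfg$batch_size

  elbo_trace <- numeric(cfg$epochs)
  mae_iter <- integer(0); train_mae <- numeric(0); val_mae <- numeric(0)
  diverged <- FALSE

  for (it in seq_len(cfg$epochs)) {
    pairs <- draw_batch()
    stats <- minibatch_data_stats(pairs[, 1L], pairs[, 2L], ds$Y, Wk,
                                  w = w_scale, K = K, N = N)
    val <- 0; grad <- NULL
    for (s in seq_len(cfg$mc_samples)) {
      noise <- draw_noise(N, M, cfg$latent_dim, spike = opts$spike)
      vg <- vb_value_grad(th, stats, noise, opts)
      val <- val + vg$value / cfg$mc_samples
      grad <- if (is.null(grad)) vg$grad else Map(`+`, grad, vg$grad)
    }
    if (cfg$mc_samples > 1L) grad <- lapply(grad, function(z) z / cfg$mc_samples)
    if (!is.finite(val) || !all(vapply(grad, function(z) all(is.finite(z)), TRUE))) {
      warning("non-finite ELBO at step ", it, "; aborting with last finite state")
      elbo_trace <- elbo_trace[seq_len(it - 1L)]
      diverged <- TRUE
      break
    }
    elbo_trace[it] <- val
    upd <- adam_step(th, grad, state, cfg$learning_rate,
                     cfg$adam_beta1, cfg$adam_beta2)
    th <- upd$th; state <- upd$state
    if (!is.na(opts$anchor)) {
      th$aV[opts$anchor, ] <- 0
      th$av0[opts$anchor] <- 0
    }
    if (it %% cfg$eval_every == 0L || it == cfg$epochs) {
      post <- params_to_posteriors(th, opts, cfg)
      mae_iter <- c(mae_iter, it)
      prop <- predict_from_posteriors(post$ss, post$g, ds$X)
      train_mae <- c(train_mae, mae(ds$Y, prop * rowSums(ds$Y)))
      if (!is.null(validation)) {
        vprop <- predict_from_posteriors(post$ss, post$g, validation$X)
        val_mae <- c(val_mae, mae(validation$Y, vprop * rowSums(validation$Y)))
      }
    }
  }

  finalize_fit(th, opts, cfg, ds, elbo_trace, mae_iter, train_mae,
               if (is.null(validation)) NULL else val_mae, diverged,
               mode = "vb")
}

#' Fit the maximum a posteriori baseline
#'
#' Point-estimate counterpart of [fit_spikemm()]: maximizes the multinomial
#' log-likelihood plus Gaussian log-priors over the embedding and bias
#' matrices themselves, with the same minibatch scheme and Adam updates.
#' There is no selection machinery; inclusion probabilities in the returned
#' fit are identically 1.
#'
#' @param ds a [paired_omics_dataset()].
#' @param cfg a [model_config()] with `mode = "map"`.
#' @param validation optional held-out dataset for MAE traces.
#' @return object of class `spikemm_fit`; the objective trace is stored in
#'   `elbo_trace` (here the penalized log-likelihood, not an ELBO).
#' @export
fit_map <- function(ds, cfg = model_config(mode = "map"), validation = NULL) {
  stopifnot(inherits(ds, "paired_omics"), inherits(cfg, "spikemm_config"))
  if (cfg$mode != "map") stop("fit_map requires cfg$mode = 'map'")
  K <- nrow(ds$X); N <- ncol(ds$X); M <- ncol(ds$Y)
  opts <- engine_opts(cfg, N = N, K = K, M = M)

  set.seed(cfg$seed)
  th <- init_map_params(N, M, L = cfg$latent_dim)
  if (!is.na(opts$anchor)) {
    th$aV[opts$anchor, ] <- 0
    th$av0[opts$anchor] <- 0
  }
  state <- adam_state(th)
  draw_batch <- minibatch_sampler(ds, cfg$batch_size)
  Wk <- rowSums(ds$Y)
  w_scale <- sum(ds$X) / cfg$batch_size

  elbo_trace <- numeric(cfg$epochs)
  mae_iter <- integer(0); train_mae <- numeric(0); val_mae <- numeric(0)
  diverged <- FALSE

  for (it in seq_len(cfg$epochs)) {
    pairs <- draw_batch()
    stats <- minibatch_data_stats(pairs[, 1L], pairs[, 2L], ds$Y, Wk,
                                  w = w_scale, K = K, N = N)
    vg <- map_value_grad(th, stats, opts)
    if (!is.finite(vg$value)) {
      warning("non-finite objective at step ", it, "; aborting with last finite state")
      elbo_trace <- elbo_trace[seq_len(it - 1L)]
      diverged <- TRUE
      break
    }
    elbo_trace[it] <- vg$value
    upd <- adam_step(th, vg$grad, state, cfg$learning_rate,
                     cfg$adam_beta1, cfg$adam_beta2)
    th <- upd$th; state <- upd$state
    if (!is.na(opts$anchor)) {
      th$aV[opts$anchor, ] <- 0
      th$av0[opts$anchor] <- 0
    }
    if (it %% cfg$eval_every == 0L || it == cfg$epochs) {
      post <- params_to_posteriors(th, opts, cfg, mode = "map")
      mae_iter <- c(mae_iter, it)
      prop <- predict_from_posteriors(post$ss, post$g, ds$X)
      train_mae <- c(train_mae, mae(ds$Y, prop * rowSums(ds$Y)))
      if (!is.null(validation)) {
        vprop <- predict_from_posteriors(post$ss, post$g, validation$X)
        val_mae <- c(val_mae, mae(validation$Y, vprop * rowSums(validation$Y)))
      }
    }
  }

  finalize_fit(th, opts, cfg, ds, elbo_trace, mae_iter, train_mae,
               if (is.null(validation)) NULL else val_mae, diverged,
               mode = "map")
}

finalize_fit <- function(th, opts, cfg, ds, elbo_trace, mae_iter, train_mae,
                         val_mae, diverged, mode) {
  post <- params_to_posteriors(th, opts, cfg, mode = mode)
  gt <- gamma_tilde(post$ss$xi)
  names(gt) <- ds$taxon_ids
  lp <- cooccurrence_logprobs(post$ss, post$g)
  dimnames(lp) <- list(ds$metabolite_ids, ds$taxon_ids)
  structure(
    list(u_posterior = post$ss, v_posterior = post$g,
         gamma_tilde = gt, cooccurrence_logprob = lp,
         elbo_trace = elbo_trace,
         train_mae_trace = data.frame(iteration = mae_iter, mae = train_mae),
         val_mae_trace = if (is.null(val_mae)) NULL else
           data.frame(iteration = mae_iter, mae = val_mae),
         config = cfg, lambda = opts$lambda, rng_seed = cfg$seed,
         diverged = diverged,
         taxon_ids = ds$taxon_ids, metabolite_ids = ds$metabolite_ids),
    class = "spikemm_fit"
  )
}

#' @export
print.spikemm_fit <- function(x, ...) {
  cat("spikemm fit (", x$config$mode,
      if (x$config$mode == "vb" && !x$config$spike_slab_enabled) ", no spike-slab",
      "): ", length(x$taxon_ids), " taxa, ", length(x$metabolite_ids),
      " metabolites, L = ", x$config$latent_dim, "\n", sep = "")
  cat("  steps:", length(x$elbo_trace),
      "; final objective (window-50 mean):",
      format(mean(utils::tail(x$elbo_trace, 50)), digits = 6), "\n")
  cat("  lambda:", format(x$lambda, digits = 4),
      "; gamma_tilde range:", paste(format(range(x$gamma_tilde), digits = 3),
                                    collapse = " - "), "\n")
  if (x$diverged) cat("  NOTE: optimization aborted at last finite state\n")
  invisible(x)
}

# moving-average ELBO used for plateau reporting and trend tests
smoothed_elbo <- function(fit, window = 50L) {
  tr <- fit$elbo_trace
  if (length(tr) < window) return(tr)
  stats::filter(tr, rep(1 / window, window), sides = 1)
}
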