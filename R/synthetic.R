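#' Generate a paired microbiome-metabolome dataset with known truth
#'
#' Draws data from the model's own generative process so that inference and
#' selection can be scored against ground truth. A small informative subset
#' of taxa receives nonzero latent embeddings (`N(0, effect_scale^2)` rows);
#' all other taxon rows are exactly zero. Microbial compositions follow a
#' log-normal-softmax model. Null taxa draw baseline log-abundances
#' `N(0, base_abundance_sd^2)` — a heavy-tailed, mostly-rare spectrum like a
#' real 16S table — with moderate per-sample log-normal variation
#' (`sample_noise_sd`). Informative taxa are modelled as condition-driven
#' keystone taxa: consistently present (baseline
#' `N(informative_prevalence, informative_prevalence_sd^2)`) but strongly
#' fluctuating across samples (`informative_variability`), the pattern of
#' diet- or disease-responsive blooms. Both choices are what makes the
#' inclusion mask recoverable at all: a taxon that is too rare to observe, or
#' that never varies, carries no co-occurrence signal for any method, and a
#' highly variable background would drown the informative signal in
#' compositional confounding. Counts are multinomial at a depth drawn
#' uniformly from `x_depth`. Metabolite profiles mix the conditional
#' probability columns by each sample's observed taxon composition and are
#' multinomially sampled at a depth from `y_depth` (mass-spectrometry-like
#' scale).
#'
#' @param K,N,M,L samples, taxa, metabolites, latent dimension.
#' @param n_informative number of taxa with nonzero embeddings (<= N).
#' @param x_depth,y_depth length-2 integer ranges of per-sample sequencing /
#'   abundance depths.
#' @param effect_scale standard deviation of informative embedding entries.
#' @param base_abundance_sd spread of null-taxon baseline log-abundances.
#' @param sample_noise_sd per-sample log-normal variation of null taxa.
#' @param informative_prevalence,informative_prevalence_sd mean and spread of
#'   informative-taxon baseline log-abundances.
#' @param informative_variability per-sample log-normal variation of
#'   informative taxa.
#' @param metabolite_bias_sd spread of the true metabolite biases; 0 (the
#'   default) makes metabolites exchangeable when no taxon is informative.
#' @param seed integer seed; the draw is fully deterministic given it.
#' @return list with `dataset` (a [paired_omics_dataset()]) and `truth`
#'   (class `synthetic_truth`: `U_true`, `V_true`, `v_bias_true`,
#'   `inclusion_mask`, depth ranges, seed).
#' @export
generate_paired_omics <- function(K, N, M, L = 3L, n_informative,
                                  x_depth = c(1000L, 10000L),
                                  y_depth = c(10000L, 100000L),
                                  effect_scale = 1, base_abundance_sd = 2.5,
                                  sample_noise_sd = 1,
                                  informative_prevalence = 2,
                                  informative_prevalence_sd = 0.75,
                                  informative_variability = 2.5,
                                  metabolite_bias_sd = 0, seed = 1L) {
  if (n_informative > N) stop("n_informative must be <= N")
  if (n_informative < 0) stop("n_informative must be >= 0")
  stopifnot(length(x_depth) == 2L, length(y_depth) == 2L,
            all(x_depth >= 1), all(y_depth >= 1), K >= 1, M >= 2, L >= 1)
  set.seed(seed)

  U_true <- matrix(0, N, L)
  informative <- if (n_informative > 0) sort(sample.int(N, n_informative)) else integer(0)
  U_true[informative, ] <- rnorm(n_informative * L, 0, effect_scale)
  V_true <- matrix(rnorm(M * L), M, L)
  v_bias_true <- if (metabolite_bias_sd > 0) rnorm(M, 0, metabolite_bias_sd) else numeric(M)
  mask <- integer(N); mask[informative] <- 1L

  base <- rnorm(N, 0, base_abundance_sd)
  base[informative] <- rnorm(n_informative, informative_prevalence,
                             informative_prevalence_sd)
  noise_sd <- rep(sample_noise_sd, N)
  noise_sd[informative] <- informative_variability

  P_true <- conditional_prob_matrix(U_true, V_true, v_bias = v_bias_true)
  X <- matrix(0L, K, N); Y <- matrix(0L, K, M)
  for (k in seq_len(K)) {
    comp <- exp(base + rnorm(N, 0, noise_sd))
    comp <- comp / sum(comp)
    dx <- sample(x_depth[1]:x_depth[2], 1L)
    X[k, ] <- rmultinom(1L, dx, comp)
    if (sum(X[k, ]) == 0L) X[k, which.max(comp)] <- 1L
    p_mix <- as.vector(P_true %*% (X[k, ] / sum(X[k, ])))
    dy <- sample(y_depth[1]:y_depth[2], 1L)
    Y[k, ] <- rmultinom(1L, dy, p_mix)
  }

  ds <- paired_omics_dataset(
    X, Y,
    sample_ids = sprintf("S%03d", seq_len(K)),
    taxon_ids = sprintf("taxon_%03d", seq_len(N)),
    metabolite_ids = sprintf("metabolite_%03d", seq_len(M))
  )
  truth <- structure(
    list(U_true = U_true, V_true = V_true, v_bias_true = v_bias_true,
         inclusion_mask = mask, x_depth = x_depth, y_depth = y_depth,
         effect_scale = effect_scale, seed = seed),
    class = "synthetic_truth"
  )
  list(dataset = ds, truth = truth)
}

#' Score a fit against synthetic ground truth
#'
#' Reports how well the fitted model recovers the generating structure:
#' the area under the ROC curve of the `gamma_tilde` ranking against the true
#' inclusion mask, and embedding alignment errors after orthogonal Procrustes
#' rotation (embeddings are identified only up to rotation; the taxon side is
#' compared on informative rows only, since null rows are zero by
#' construction).
#'
#' @param truth a `synthetic_truth` from [generate_paired_omics()].
#' @param fit a `spikemm_fit` on the matching dataset.
#' @return list with `selection_auroc`, `v_alignment_error`,
#'   `u_alignment_error` (root-mean-square residual per element after
#'   rotation; `NA` when fewer than 2 informative taxa).
#' @export
recovery_metrics <- function(truth, fit) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(fit, "spikemm_fit"))
  gt <- fit$gamma_tilde
  if (length(gt) != length(truth$inclusion_mask)) stop("fit does not match truth")
  m <- posterior_mean_embeddings(fit$u_posterior, fit$v_posterior)
  inf <- which(truth$inclusion_mask == 1L)
  list(
    selection_auroc = rank_auroc(gt, truth$inclusion_mask),
    v_alignment_error = procrustes_rmse(truth$V_true, m$V),
    u_alignment_error = if (length(inf) >= 2L) {
      procrustes_rmse(truth$U_true[inf, , drop = FALSE],
                      m$U[inf, , drop = FALSE])
    } else NA_real_
  )
}

# Wilcoxon/Mann-Whitney AUROC of a score against binary labels
rank_auroc <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# RMS residual per element after centring and optimal orthogonal rotation
# (reflections allowed) of `fitted` onto `target`
procrustes_rmse <- function(target, fitted) {
  stopifnot(all(dim(target) == dim(fitted)))
  tc <- scale(target, center = TRUE, scale = FALSE)
  fc <- scale(fitted, center = TRUE, scale = FALSE)
  s <- svd(crossprod(tc, fc))
  rot <- s$v %*% t(s$u)
  sqrt(mean((fc %*% rot - tc)^2))
}
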