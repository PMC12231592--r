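#' Split a paired dataset into training and test samples
#'
#' Random partition of samples (features are untouched): `round(test_fraction
#' * K)` samples are held out. Deterministic given `seed` (R's default
#' Mersenne-Twister stream via `sample.int`).
#'
#' @param ds a [paired_omics_dataset()].
#' @param test_fraction fraction of samples held out (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` datasets and `spec` (a list holding
#'   `test_fraction`, `seed`, `train_indices`, `test_indices`).
#' @export
train_test_split <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "paired_omics"))
  K <- nrow(ds$X)
  if (K < 2L) stop("need at least 2 samples to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly in (0, 1)")
  }
  n_test <- round(test_fraction * K)
  n_test <- min(max(n_test, 1L), K - 1L)
  set.seed(seed)
  test_idx <- sort(sample.int(K, n_test))
  train_idx <- setdiff(seq_len(K), test_idx)
  list(train = subset_samples(ds, train_idx),
       test = subset_samples(ds, test_idx),
       spec = list(test_fraction = test_fraction, seed = seed,
                   train_indices = train_idx, test_indices = test_idx))
}

#' Predict metabolite abundances for new microbial samples
#'
#' For each test sample, the predicted metabolite profile is the sample's
#' total metabolite abundance times the mixture of conditional probability
#' columns weighted by the sample's taxon composition:
#' `yhat = w * P_bar %*% (x / sum(x))`, with `P_bar` the conditional matrix at
#' the posterior means. With `resample = n > 0` the taxon composition is
#' replaced by the empirical frequency of `n` categorical draws from it,
#' which converges to the deterministic expectation form as `n` grows.
#'
#' @param fit a `spikemm_fit`.
#' @param X_new matrix of microbial counts (samples x taxa), taxon order as in
#'   the fitted data; a single profile may be given as a vector.
#' @param totals per-sample total metabolite abundances `w` used to scale the
#'   predictions. These must be supplied for genuinely new samples; for
#'   evaluation on held-out data pass the observed test totals.
#' @param resample 0 for the deterministic expectation form, otherwise the
#'   number of categorical draws per sample.
#' @return matrix (samples x metabolites) of predicted abundances; each row
#'   sums to its `totals` entry.
#' @export
predict_metabolites <- function(fit, X_new, totals, resample = 0L) {
  stopifnot(inherits(fit, "spikemm_fit"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1L)
  if (ncol(X_new) != length(fit$taxon_ids)) {
    stop("X_new must have one column per fitted taxon")
  }
  if (any(rowSums(X_new) <= 0)) stop("zero-depth sample cannot be predicted")
  if (length(totals) == 1L) totals <- rep(totals, nrow(X_new))
  if (length(totals) != nrow(X_new)) stop("totals length must match samples")
  Pbar <- exp(fit$cooccurrence_logprob)    # M x N at posterior means
  xt <- X_new / rowSums(X_new)
  if (resample > 0L) {
    xt <- t(apply(xt, 1L, function(p) {
      as.vector(rmultinom(1L, resample, p)) / resample
    }))
  }
  yhat <- xt %*% t(Pbar) * totals
  colnames(yhat) <- fit$metabolite_ids
  yhat
}

# shared prediction path used for MAE traces during training
predict_from_posteriors <- function(ss, g, X_new) {
  m <- posterior_mean_embeddings(ss, g)
  P <- conditional_prob_matrix(m$U, m$V, v_bias = m$v_bias, u_bias = m$u_bias)
  xt <- X_new / rowSums(X_new)
  xt %*% t(P)    # per-sample metabolite proportions; scaled by caller
}

#' Mean absolute error over test samples
#'
#' Mean, over samples, of the summed elementwise absolute prediction error:
#' `MAE = (1/K') sum_k' sum_j |Y_k'j - Yhat_k'j|`.
#'
#' @param Y,Yhat observed and predicted abundance matrices of equal shape
#'   (samples x metabolites); vectors are treated as single samples.
#' @return non-negative scalar; 0 iff the matrices are identical.
#' @export
mae <- function(Y, Yhat) {
  Y <- rbind(Y); Yhat <- rbind(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat shapes differ")
  mean(rowSums(abs(Y - Yhat)))
}

#' Symmetric mean absolute percentage error
#'
#' `SMAPE = (100/K') sum_k' mean_j |y - yhat| / (|y| + |yhat|)`, with `0/0`
#' terms defined as 0 (both absent means no error). Bounded in `[0, 100]`:
#' 0 for exact prediction, 100 when every nonzero observation is predicted
#' as zero (or vice versa).
#'
#' @inheritParams mae
#' @return scalar in `[0, 100]`.
#' @export
smape <- function(Y, Yhat) {
  Y <- rbind(Y); Yhat <- rbind(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat shapes differ")
  num <- abs(Y - Yhat)
  den <- abs(Y) + abs(Yhat)
  ratio <- ifelse(den == 0, 0, num / den)
  100 * mean(rowMeans(ratio))
}

#' Evaluate a fit on held-out samples
#'
#' Predicts the held-out metabolite profiles with [predict_metabolites()]
#' (expectation form, scaled by the observed test totals) and reports both
#' accuracy metrics.
#'
#' @param fit a `spikemm_fit`.
#' @param test a [paired_omics_dataset()] of held-out samples.
#' @return list with `mae`, `smape`, and the prediction matrix `Yhat`.
#' @export
evaluate_fit <- function(fit, test) {
  stopifnot(inherits(test, "paired_omics"))
  yhat <- predict_metabolites(fit, test$X, totals = rowSums(test$Y))
  list(mae = mae(test$Y, yhat), smape = smape(test$Y, yhat), Yhat = yhat)
}
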