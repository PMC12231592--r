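#' Per-taxon inclusion probability
#'
#' Averages the variational inclusion probabilities over latent dimensions:
#' `gamma_tilde_i = sum_l xi_il / L`. This is the feature-selection score a
#' fitted model reports per taxon.
#'
#' @param xi `N x L` matrix of inclusion probabilities in `[0, 1]`.
#' @return length-`N` vector in `[0, 1]`, named if `xi` has rownames.
#' @export
gamma_tilde <- function(xi) {
  xi <- as.matrix(xi)
  if (any(xi < 0 | xi > 1)) stop("inclusion probabilities must lie in [0, 1]")
  rowMeans(xi)
}

#' Select core taxa by inclusion probability
#'
#' Deterministic selection of taxa from their `gamma_tilde` scores, either by
#' a threshold (`{i : gamma_tilde_i >= threshold}`) or as the `top_k` highest
#' scores. Ties at the `top_k` boundary are broken by taxon identifier order
#' and reported via a message.
#'
#' @param gamma_tilde numeric vector of per-taxon scores in `[0, 1]`; names
#'   are used as taxon identifiers (generated if absent). A `spikemm_fit`
#'   may be given directly.
#' @param threshold scalar in `[0, 1]`; exactly one of `threshold` / `top_k`.
#' @param top_k integer number of taxa to keep.
#' @return object of class `selection_report`: `gamma_tilde`, the rule used,
#'   `selected_taxa` identifiers, and the per-taxon `rank` (1 = highest
#'   score, ties by identifier order).
#' @export
select_taxa <- function(gamma_tilde, threshold = NULL, top_k = NULL) {
  if (inherits(gamma_tilde, "spikemm_fit")) gamma_tilde <- gamma_tilde$gamma_tilde
  if (is.null(threshold) == is.null(top_k)) {
    stop("give exactly one of threshold or top_k")
  }
  gt <- as.numeric(gamma_tilde)
  ids <- names(gamma_tilde) %||% paste0("taxon_", seq_along(gt))
  if (any(gt < 0 | gt > 1)) stop("gamma_tilde values must lie in [0, 1]")
  ord <- order(-gt, seq_along(gt))        # score desc, identifier order breaks ties
  rnk <- integer(length(gt)); rnk[ord] <- seq_along(gt)
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k > length(gt)) stop("top_k exceeds the number of taxa")
    if (top_k < length(gt) && gt[ord][top_k] == gt[ord][top_k + 1L]) {
      message("tie at the top_k boundary broken by taxon identifier order")
    }
    sel <- ids[ord][seq_len(top_k)]
  } else {
    if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
    sel <- ids[gt >= threshold][order(rnk[gt >= threshold])]
  }
  structure(list(gamma_tilde = stats::setNames(gt, ids),
                 threshold = threshold, top_k = top_k,
                 selected_taxa = sel, rank = stats::setNames(rnk, ids)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  rule <- if (!is.null(x$threshold)) paste0("gamma_tilde >= ", x$threshold)
          else paste0("top ", x$top_k)
  cat("selection_report:", length(x$selected_taxa), "of", length(x$gamma_tilde),
      "taxa selected (", rule, ")\n")
  invisible(x)
}

#' Co-occurrence log-probability matrix at posterior means
#'
#' Logarithm of the conditional probability matrix evaluated at the posterior
#' mean embeddings (`xi * alpha_U` on the taxon side — the expected embedding
#' under the spike-and-slab family — and `alpha_V` on the metabolite side).
#' Columns log-sum-exp to zero.
#'
#' @param ss a [spike_slab_posterior()] (or a `spikemm_fit`, from which both
#'   posteriors are taken).
#' @param g a [gaussian_posterior()]; ignored when `ss` is a fit.
#' @return `M x N` matrix of log conditional probabilities.
#' @export
cooccurrence_logprobs <- function(ss, g = NULL) {
  if (inherits(ss, "spikemm_fit")) {
    g <- ss$v_posterior; ss <- ss$u_posterior
  }
  m <- posterior_mean_embeddings(ss, g)
  log(conditional_prob_matrix(m$U, m$V, v_bias = m$v_bias, u_bias = m$u_bias))
}

#' Rank taxon-metabolite relationships
#'
#' Orders all (taxon, metabolite) pairs by the magnitude of their co-occurrence
#' log-probability (or by signed value with `signed = TRUE`), with stable
#' tie-breaking by taxon then metabolite identifier order.
#'
#' @param logprobs `M x N` log conditional probability matrix (metabolites in
#'   rows), e.g. from [cooccurrence_logprobs()].
#' @param top_n number of pairs to return; truncated to `M * N` with a warning
#'   if larger.
#' @param signed rank by signed log-probability (largest first) instead of
#'   absolute value.
#' @return data.frame with columns `taxon_id`, `metabolite_id`,
#'   `log_conditional_probability`, `rank`.
#' @export
rank_relationships <- function(logprobs, top_n = 50L, signed = FALSE) {
  if (!all(is.finite(logprobs))) stop("log-probability matrix must be finite")
  M <- nrow(logprobs); N <- ncol(logprobs)
  if (top_n > M * N) {
    warning("top_n exceeds the number of pairs; truncated to ", M * N)
    top_n <- M * N
  }
  mets <- rownames(logprobs) %||% paste0("metabolite_", seq_len(M))
  taxa <- colnames(logprobs) %||% paste0("taxon_", seq_len(N))
  df <- data.frame(
    taxon_id = rep(taxa, each = M),
    metabolite_id = rep(mets, times = N),
    log_conditional_probability = as.vector(logprobs),
    stringsAsFactors = FALSE
  )
  key <- if (signed) -df$log_conditional_probability else
    -abs(df$log_conditional_probability)
  ord <- order(key, rep(seq_len(N), each = M), rep(seq_len(M), times = N))
  out <- df[ord[seq_len(top_n)], , drop = FALSE]
  out$rank <- seq_len(top_n)
  rownames(out) <- NULL
  out
}

#' Heatmap row and column ordering by Ward clustering
#'
#' Leaf orderings of agglomerative hierarchical clusterings (Ward's method on
#' Euclidean distances) of the rows and of the columns of a matrix — the
#' standard ordering for co-occurrence heatmaps. Degenerate axes (a single
#' row or column) get the identity order.
#'
#' @param mat finite numeric matrix.
#' @return list with integer vectors `row_order` and `col_order` and the two
#'   `hclust` objects (`row_hclust`, `col_hclust`, `NULL` when degenerate).
#' @export
cluster_order <- function(mat) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("matrix must be finite")
  one_axis <- function(m) {
    if (nrow(m) < 2L) return(list(order = seq_len(nrow(m)), hclust = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
    list(order = hc$order, hclust = hc)
  }
  r <- one_axis(mat); c_ <- one_axis(t(mat))
  list(row_order = r$order, col_order = c_$order,
       row_hclust = r$hclust, col_hclust = c_$hclust)
}
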