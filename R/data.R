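#' Paired microbiome-metabolome dataset
#'
#' Bundles an aligned pair of count tables: a `K x N` microbial taxon-count
#' matrix `X` and a `K x M` metabolite-abundance matrix `Y` sharing sample
#' order. Abundances may be non-integer (mass-spectrometry intensities) but
#' must be non-negative, and every sample needs a positive total in both
#' tables.
#'
#' @param X numeric matrix, samples x taxa, non-negative.
#' @param Y numeric matrix, samples x metabolites, non-negative.
#' @param sample_ids,taxon_ids,metabolite_ids optional unique identifier
#'   vectors; defaults are taken from dimnames or generated.
#' @return an object of class `paired_omics` with elements `X`, `Y`,
#'   `sample_ids`, `taxon_ids`, `metabolite_ids`.
#' @export
paired_omics_dataset <- function(X, Y, sample_ids = NULL, taxon_ids = NULL,
                                 metabolite_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of samples (rows): ",
         nrow(X), " vs ", nrow(Y))
  }
  if (nrow(X) == 0L) stop("empty dataset")
  if (!is.numeric(X) || !is.numeric(Y)) stop("count tables must be numeric")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite abundances")
  if (any(X < 0) || any(Y < 0)) stop("negative abundances are not allowed")
  if (any(rowSums(X) <= 0)) stop("every sample needs a positive taxon total")
  if (any(rowSums(Y) <= 0)) stop("every sample needs a positive metabolite total")

  sample_ids <- sample_ids %||% rownames(X) %||% paste0("S", seq_len(nrow(X)))
  taxon_ids <- taxon_ids %||% colnames(X) %||% paste0("taxon_", seq_len(ncol(X)))
  metabolite_ids <- metabolite_ids %||% colnames(Y) %||%
    paste0("metabolite_", seq_len(ncol(Y)))
  for (ids in list(sample_ids, taxon_ids, metabolite_ids)) {
    if (anyDuplicated(ids)) stop("identifier lists must be unique")
  }
  if (length(sample_ids) != nrow(X)) stop("sample_ids length mismatch")
  if (length(taxon_ids) != ncol(X)) stop("taxon_ids length mismatch")
  if (length(metabolite_ids) != ncol(Y)) stop("metabolite_ids length mismatch")

  dimnames(X) <- list(sample_ids, taxon_ids)
  dimnames(Y) <- list(sample_ids, metabolite_ids)
  structure(
    list(X = X, Y = Y, sample_ids = as.character(sample_ids),
         taxon_ids = as.character(taxon_ids),
         metabolite_ids = as.character(metabolite_ids)),
    class = "paired_omics"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.paired_omics <- function(x, ...) {
  cat("paired_omics dataset:", nrow(x$X), "samples,",
      ncol(x$X), "taxa,", ncol(x$Y), "metabolites\n")
  cat("  taxon depth range:", paste(range(rowSums(x$X)), collapse = "-"),
      "; metabolite depth range:", paste(range(rowSums(x$Y)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
dim.paired_omics <- function(x) {
  c(K = nrow(x$X), N = ncol(x$X), M = ncol(x$Y))
}

# subset samples, keeping both tables aligned
subset_samples <- function(ds, idx) {
  paired_omics_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx, , drop = FALSE],
                       sample_ids = ds$sample_ids[idx],
                       taxon_ids = ds$taxon_ids,
                       metabolite_ids = ds$metabolite_ids)
}
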