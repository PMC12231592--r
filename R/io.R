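#' Read a feature count table
#'
#' Reads a CSV, TSV or BIOM table into a labelled numeric matrix. For CSV/TSV
#' the first column holds feature or sample identifiers and the header row the
#' other axis; orientation (samples in rows or columns) is not decided here —
#' [align_samples()] resolves it from the identifier overlap between the two
#' tables of a pair. BIOM tables (JSON dialect, 1.0, or HDF5 2.x if the
#' installed reader supports it) are returned observation-by-sample as
#' stored. Negative, missing or non-numeric cells are rejected with the
#' offending row and column named.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"biom"`.
#' @return numeric matrix with row and column names.
#' @export
read_count_table <- function(path, format = c("auto", "csv", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", biom = "biom",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(check_count_matrix(m, path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("table needs an identifier column and data columns: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate identifiers in first column of ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate identifiers in header of ", path)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stop("non-numeric cell at row '", ids[bad[1L, 1L]], "', column '",
           colnames(m)[bad[1L, 2L]], "' in ", path)
    }
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- ids
  check_count_matrix(m, path)
}

check_count_matrix <- function(m, path) {
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value at row '", rownames(m)[bad[1L]], "', column '",
         colnames(m)[bad[2L]], "' in ", path)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at row '", rownames(m)[bad[1L]], "', column '",
         colnames(m)[bad[2L]], "' in ", path)
  }
  m
}

#' Write a count table in the dialects the reader accepts
#'
#' @param m labelled numeric matrix (identifiers in rownames; header from
#'   colnames).
#' @param path destination; the extension picks the dialect unless `format`
#'   is given.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"biom"` (JSON dialect).
#' @param id_header name of the identifier column for CSV/TSV output.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path, format = c("auto", "csv", "tsv", "biom"),
                              id_header = "feature_id") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", biom = "biom",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("writing BIOM files requires the biomformat package")
    }
    biomformat::write_biom(biomformat::make_biom(m), path)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_header
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a microbial and a metabolite table into a paired dataset
#'
#' Determines the orientation of each table (samples in rows or columns) from
#' the overlap of identifiers across the pair, keeps the intersection of
#' sample identifiers in the order they appear in the microbial table, and
#' reports dropped samples. Ambiguous orientation (both axes overlap equally)
#' or empty intersection is an error.
#'
#' @param x labelled microbial count matrix, e.g. from [read_count_table()].
#' @param y labelled metabolite abundance matrix.
#' @param samples `"auto"` to detect orientation, or `"rows"` / `"columns"`
#'   to force where samples live in both tables.
#' @return a [paired_omics_dataset()].
#' @export
align_samples <- function(x, y, samples = c("auto", "rows", "columns")) {
  samples <- match.arg(samples)
  if (samples == "auto") {
    combos <- expand.grid(xr = c(TRUE, FALSE), yr = c(TRUE, FALSE))
    ids <- function(m, rows) if (rows) rownames(m) else colnames(m)
    ov <- mapply(function(xr, yr) length(intersect(ids(x, xr), ids(y, yr))),
                 combos$xr, combos$yr)
    if (max(ov) == 0L) stop("the two tables share no sample identifiers")
    best <- which(ov == max(ov))
    if (length(best) > 1L) {
      stop("sample orientation is ambiguous; pass samples = 'rows' or 'columns'")
    }
    xo <- if (combos$xr[best]) x else t(x)
    yo <- if (combos$yr[best]) y else t(y)
  } else {
    flip <- identical(samples, "columns")
    xo <- if (flip) t(x) else x
    yo <- if (flip) t(y) else y
  }
  common <- intersect(rownames(xo), rownames(yo))
  if (length(common) == 0L) {
    stop("the two tables share no sample identifiers")
  }
  dropped <- setdiff(union(rownames(xo), rownames(yo)), common)
  if (length(dropped)) {
    message(length(dropped), " sample(s) without a partner dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  paired_omics_dataset(xo[common, , drop = FALSE], yo[common, , drop = FALSE],
                       sample_ids = common)
}

#' Write the standard output files of a fit
#'
#' Emits, under `dir`: `U_posterior.tsv` and `V_posterior.tsv` (posterior
#' mean and standard deviation per embedding element, plus biases and, for
#' taxa, inclusion probabilities), `ranks.tsv` (the M x N co-occurrence
#' log-probability matrix), `selection_probabilities.tsv` (taxon,
#' gamma_tilde), `traces.tsv` (per-step objective and MAE traces),
#' `metrics.json` and `config.json`. Output is byte-reproducible given the
#' same fit.
#'
#' @param fit a `spikemm_fit`.
#' @param dir output directory, created if needed.
#' @param selection optional [select_taxa()] report; adds `selection.tsv`.
#' @param metrics optional named list of evaluation metrics for
#'   `metrics.json` (e.g. from [evaluate_fit()]); traces summaries are always
#'   included.
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(fit, dir, selection = NULL, metrics = NULL) {
  stopifnot(inherits(fit, "spikemm_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- fit$config$latent_dim
  files <- character(0)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }

  ss <- fit$u_posterior; g <- fit$v_posterior
  u_df <- data.frame(taxon_id = fit$taxon_ids,
                     setNames(as.data.frame(ss$alpha_U), paste0("mean_", 1:L)),
                     setNames(as.data.frame(ss$beta_U), paste0("std_", 1:L)),
                     setNames(as.data.frame(ss$xi), paste0("xi_", 1:L)),
                     bias_mean = ss$u_bias_alpha, bias_std = ss$u_bias_beta,
                     check.names = FALSE)
  tsv(u_df, "U_posterior.tsv")
  v_df <- data.frame(metabolite_id = fit$metabolite_ids,
                     setNames(as.data.frame(g$alpha_V), paste0("mean_", 1:L)),
                     setNames(as.data.frame(g$beta_V), paste0("std_", 1:L)),
                     bias_mean = g$v_bias_alpha, bias_std = g$v_bias_beta,
                     check.names = FALSE)
  tsv(v_df, "V_posterior.tsv")

  ranks <- data.frame(metabolite_id = fit$metabolite_ids,
                      fit$cooccurrence_logprob, check.names = FALSE)
  tsv(ranks, "ranks.tsv")

  tsv(data.frame(taxon_id = fit$taxon_ids, gamma_tilde = fit$gamma_tilde),
      "selection_probabilities.tsv")

  tr <- data.frame(iteration = seq_along(fit$elbo_trace), elbo = fit$elbo_trace)
  tr$train_mae <- NA_real_
  tr$train_mae[fit$train_mae_trace$iteration] <- fit$train_mae_trace$mae
  if (!is.null(fit$val_mae_trace)) {
    tr$val_mae <- NA_real_
    tr$val_mae[fit$val_mae_trace$iteration] <- fit$val_mae_trace$mae
  }
  tsv(tr, "traces.tsv")

  if (!is.null(selection)) {
    stopifnot(inherits(selection, "selection_report"))
    tsv(data.frame(taxon_id = selection$selected_taxa,
                   gamma_tilde = selection$gamma_tilde[selection$selected_taxa],
                   rank = selection$rank[selection$selected_taxa]),
        "selection.tsv")
  }

  base_metrics <- list(
    final_elbo_window50 = mean(utils::tail(fit$elbo_trace, 50L)),
    final_train_mae = utils::tail(fit$train_mae_trace$mae, 1L),
    final_val_mae = if (!is.null(fit$val_mae_trace))
      utils::tail(fit$val_mae_trace$mae, 1L) else NULL,
    lambda = fit$lambda, seed = fit$rng_seed, diverged = fit$diverged
  )
  mj <- file.path(dir, "metrics.json")
  jsonlite::write_json(c(base_metrics, metrics), mj, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- c(files, mj)

  cj <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(fit$config), cj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, cj)
  invisible(files)
}

#' Read a ranks-style TSV back into a matrix
#'
#' Inverse of the `ranks.tsv` writer in [write_outputs()].
#'
#' @param path file written with an identifier first column.
#' @return numeric matrix with identifiers as rownames.
#' @export
read_ranks_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
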