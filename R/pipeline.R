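# End-to-end orchestration: preprocess -> mixture -> robust correlation ->
# weighted graphical lasso -> lambda selection, with on-disk artifacts and
# a JSON manifest for reproducibility.

#' Companion log matrix for mixture fitting
#'
#' Given the log matrix `X = log10(C + 1)`, returns
#' `Y = log10(C + 1.01) = log10(10^X + 0.01)` — the matrix the dropout
#' mixture is fitted on (its extra pseudo-count keeps zero counts strictly
#' positive). Useful when only a log-scale matrix is at hand, e.g. from the
#' simulation module.
#'
#' @param X Log matrix with pseudo-count 1.
#' @return Log matrix with pseudo-count 1.01.
#' @export
log_y_from_x <- function(X) {
  log10(10^X + 0.01)
}

#' Robust co-expression from a log expression matrix
#'
#' Fits the per-gene dropout mixtures on the companion matrix Y, builds the
#' detection mask, and computes the robust correlation, covariance and its
#' PSD repair — the complete first stage of the method.
#'
#' @param X Cells x genes log matrix (pseudo-count 1).
#' @param Y Optional matching log matrix with pseudo-count 1.01; derived
#'   from `X` via [log_y_from_x()] when `NULL`.
#' @param t Non-detection probability threshold (default 0.5).
#' @param min_pairs Minimum complete cells per pair before the Pearson
#'   fallback (default 10).
#' @param seed Optional seed for EM restarts.
#' @return List with `fits`, `mask`, `corr`, `sigma_hat`, `S`, `Sp`, `tau`.
#' @export
infer_coexpression <- function(X, Y = NULL, t = 0.5, min_pairs = 10L,
                               seed = NULL) {
  if (is.null(Y)) Y <- log_y_from_x(X)
  fits <- fit_mixtures(Y, seed = seed)
  mask <- detection_mask(Y, fits, t = t)
  out <- robust_coexpression(X, mask, fits, min_pairs = min_pairs)
  c(list(fits = fits, mask = mask), out)
}

#' Infer a sparse co-expression network from a log expression matrix
#'
#' Runs the full method: robust co-expression ([infer_coexpression()])
#' followed by the adaptively weighted graphical lasso over a lambda grid,
#' with the regularization parameter chosen by BIC or a target sparsity
#' level.
#'
#' @inheritParams infer_coexpression
#' @param lambda_grid Decreasing grid of penalty values (default
#'   `seq(1, 0.05, by = -0.05)`).
#' @param selection `"bic"`, `"sparsity"`, or `"none"` (return the full
#'   path without selecting).
#' @param max_edge_fraction Edge budget for `selection = "sparsity"`
#'   (default 0.05).
#' @param weights `"adaptive"` (default) or `"constant"` penalty weights.
#' @return List with `coexpression` (stage-one results), `path`
#'   (`"lambda_path"`), and — unless `selection = "none"` — `lambda` and
#'   `estimate` (the selected `"network_estimate"`).
#' @export
infer_network <- function(X, Y = NULL, t = 0.5, min_pairs = 10L,
                          lambda_grid = seq(1, 0.05, by = -0.05),
                          selection = c("bic", "sparsity", "none"),
                          max_edge_fraction = 0.05,
                          weights = c("adaptive", "constant"),
                          seed = NULL) {
  selection <- match.arg(selection)
  weights <- match.arg(weights)
  coex <- infer_coexpression(X, Y, t = t, min_pairs = min_pairs, seed = seed)
  W <- if (weights == "adaptive") penalty_weights(coex$corr) else NULL
  sel <- switch(selection,
    bic = select_lambda_bic(coex$Sp, lambda_grid, n = nrow(X), W = W),
    sparsity = select_lambda_sparsity(coex$Sp, lambda_grid, max_edge_fraction, W = W),
    none = list(path = glasso_path(coex$Sp, lambda_grid, W = W, n = nrow(X)),
                lambda = NULL, estimate = NULL)
  )
  list(coexpression = coex, path = sel$path, lambda = sel$lambda,
       estimate = sel$estimate)
}

#' Build a pipeline run configuration
#'
#' Collects all tunables of [run_pipeline()] into a serializable list
#' (round-trips through JSON unchanged).
#'
#' @param input Path to the count matrix, or `NULL` when a matrix is
#'   passed to [run_pipeline()] directly.
#' @param format,orientation Passed to [read_expression()].
#' @param norm_mode,m_value Passed to [normalize_library_size()].
#' @param top_genes Keep the top-k genes by mean normalized expression
#'   (`NULL` to keep all).
#' @param t,min_pairs,lambda_grid,selection,max_edge_fraction,weights
#'   Passed to [infer_network()].
#' @param seed Single run seed; each stage derives its own sub-seed.
#' @param out_dir Output directory for artifacts (`NULL` for none).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, format = "csv",
                            orientation = "cells_by_genes",
                            norm_mode = "median", m_value = NULL,
                            top_genes = NULL, t = 0.5, min_pairs = 10L,
                            lambda_grid = seq(1, 0.05, by = -0.05),
                            selection = "sparsity", max_edge_fraction = 0.05,
                            weights = "adaptive", seed = 1L, out_dir = NULL) {
  structure(list(
    input = input, format = format, orientation = orientation,
    norm_mode = norm_mode, m_value = m_value, top_genes = top_genes,
    t = t, min_pairs = as.integer(min_pairs), lambda_grid = lambda_grid,
    selection = selection, max_edge_fraction = max_edge_fraction,
    weights = weights, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Preprocess (normalize, log transform, optional gene filter), fit the
#' dropout mixtures, compute the robust co-expression matrices, fit the
#' weighted graphical lasso path, select lambda, and (if `out_dir` is set)
#' write the mixture-parameter table, correlation matrices, path summary,
#' selected edge list and a JSON manifest.
#'
#' @param config A `"pipeline_config"`.
#' @param counts Optional cells x genes count matrix, used instead of
#'   reading `config$input`.
#' @return List with `config`, `kept_genes`, `result` (from
#'   [infer_network()]), and `manifest`.
#' @export
run_pipeline <- function(config, counts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- if (!is.null(counts)) counts else {
    if (is.null(config$input)) stopf("config$input is NULL and no matrix supplied")
    read_expression(config$input, config$format, config$orientation)
  }
  validate_counts(raw)

  C <- normalize_library_size(raw, config$norm_mode, config$m_value)
  kept <- seq_len(ncol(C))
  if (!is.null(config$top_genes)) {
    fg <- filter_genes(C, "top_k_by_mean_expression", k = config$top_genes)
    C <- fg$matrix
    kept <- fg$kept
  }
  X <- log_transform(C, 1.0)
  Y <- log_transform(C, 1.01)

  res <- infer_network(X, Y, t = config$t, min_pairs = config$min_pairs,
                       lambda_grid = config$lambda_grid,
                       selection = config$selection,
                       max_edge_fraction = config$max_edge_fraction,
                       weights = config$weights,
                       seed = derive_seed(config$seed, "mixture"))

  manifest <- list(
    package = "scnet",
    version = as.character(utils::packageVersion("scnet")),
    config = unclass(config),
    n_cells = nrow(X), n_genes = ncol(X),
    selected_lambda = res$lambda,
    n_edges = if (is.null(res$estimate)) NA_integer_ else res$estimate$n_edges
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_mixture_params(res$coexpression$fits, out("mixture_params.tsv"))
    write_correlation(res$coexpression$corr, out("robust_correlation.tsv"))
    write_correlation(res$coexpression$Sp, out("covariance_psd.tsv"))
    path_tab <- data.frame(lambda = res$path$grid,
                           n_edges = res$path$edge_counts)
    if (!is.null(res$path$bic)) path_tab$bic <- res$path$bic
    write.table(path_tab, out("lambda_path.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(res$estimate)) {
      write_edge_list(res$estimate, out("edges.tsv"), r = res$coexpression$corr$r)
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  list(config = config, kept_genes = kept, result = res, manifest = manifest)
}
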