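# Sparse Gaussian graphical model estimation with data-adaptive penalties.
#
# The estimator maximizes
#   logdet(Theta) - tr(Sp Theta) - lambda * sum_{j1 != j2} W[j1,j2] |theta_{j1j2}|
# over positive-definite Theta, where the adaptive weights are
# W = 1 - |r| (strongly co-expressed pairs are penalized less) and Sp is
# the PSD-repaired robust covariance. Constant weights W == 1 give the
# ordinary graphical lasso.

#' Adaptive penalty weights from a correlation matrix
#'
#' `W[j1, j2] = 1 - |r[j1, j2]|` off the diagonal, 0 on the diagonal (the
#' diagonal of the concentration matrix is never penalized).
#'
#' @param r A `"robust_correlation"` object or correlation matrix.
#' @return Symmetric weight matrix with entries in `[0, 1]`.
#' @export
penalty_weights <- function(r) {
  rmat <- if (inherits(r, "robust_correlation")) r$r else r
  W <- 1 - abs(rmat)
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  W
}

#' Weighted graphical lasso
#'
#' Solves the penalized Gaussian log-likelihood problem above by block
#' coordinate descent (compiled). With `W = NULL` all off-diagonal entries
#' receive the constant weight 1, i.e. the ordinary graphical lasso.
#'
#' @param Sp Symmetric positive semidefinite covariance estimate.
#' @param lambda Regularization parameter (> 0).
#' @param W Optional symmetric penalty-weight matrix (zero diagonal,
#'   entries in `[0, 1]`); `NULL` for constant weights.
#' @param tol Relative convergence tolerance (default 1e-4).
#' @param max_iter Maximum outer sweeps (default 100).
#' @param warm_start Optional previous `"network_estimate"` used to warm
#'   start the solver (as along a lambda path).
#' @param zero_tol Entries of the symmetrized concentration matrix at or
#'   below this magnitude are treated as absent edges.
#' @return An object of class `"network_estimate"`: list with `theta`
#'   (concentration matrix), `adjacency` (logical, zero diagonal),
#'   `partial_corr`, `lambda`, `weights_mode` (`"adaptive"` or
#'   `"constant"`), `objective` (penalized log-likelihood), `converged`,
#'   `n_edges`, plus solver state (`w`, `b`) for warm starts.
#' @export
weighted_glasso <- function(Sp, lambda, W = NULL, tol = 1e-4, max_iter = 100L,
                            warm_start = NULL, zero_tol = 1e-8) {
  check_square_symmetric(Sp, "Sp")
  p <- nrow(Sp)
  if (lambda <= 0) stopf("`lambda` must be positive")
  ev_min <- min(eigen(Sp, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    stopf("`Sp` is not positive semidefinite (smallest eigenvalue %.3g); apply psd_projection() first",
          ev_min)
  }
  weights_mode <- if (is.null(W)) "constant" else "adaptive"
  if (is.null(W)) {
    W <- matrix(1, p, p)
    diag(W) <- 0
  } else {
    check_square_symmetric(W, "W")
    if (any(W < -1e-12) || any(W > 1 + 1e-12)) stopf("penalty weights must lie in [0, 1]")
    diag(W) <- 0
  }
  P <- lambda * W

  fit <- wglasso_cpp(Sp, P, tol, as.integer(max_iter),
                     if (is.null(warm_start)) NULL else warm_start$w,
                     if (is.null(warm_start)) NULL else warm_start$b)
  if (!fit$converged) {
    warning(sprintf("weighted glasso did not converge in %d sweeps (lambda = %g)",
                    max_iter, lambda))
  }
  theta <- fit$theta
  dimnames(theta) <- dimnames(Sp)
  adjacency <- extract_edges(theta, zero_tol = zero_tol)
  theta_z <- theta
  theta_z[!adjacency & row(theta) != col(theta)] <- 0

  obj <- glasso_objective(theta_z, Sp, P)
  structure(list(
    theta = theta_z, adjacency = adjacency,
    partial_corr = partial_correlation(theta_z),
    lambda = lambda, weights_mode = weights_mode,
    objective = obj, converged = fit$converged,
    n_edges = sum(adjacency[upper.tri(adjacency)]),
    w = fit$w, b = fit$b
  ), class = "network_estimate")
}

# Penalized log-likelihood (up to constants): logdet - tr(S Theta) - sum P|theta|
glasso_objective <- function(theta, S, P) {
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  ld <- if (is.null(ch)) determinant(theta, logarithm = TRUE)$modulus[1]
        else 2 * sum(log(diag(ch)))
  ld - sum(S * theta) - sum(P * abs(theta))
}

#' @export
print.network_estimate <- function(x, ...) {
  cat(sprintf(
    "Sparse network estimate: %d genes, %d edges (lambda = %g, %s weights%s)\n",
    nrow(x$theta), x$n_edges, x$lambda, x$weights_mode,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Ordinary graphical lasso and its variants
#'
#' Constant-weight graphical lasso on a covariance estimate. The three
#' baseline variants differ only in the covariance fed to the solver:
#' * `glasso` — sample covariance of the log matrix X;
#' * `glasso-r` — the PSD-repaired robust covariance `Sp` (identical to
#'   [weighted_glasso()] with constant weights on the same `Sp`);
#' * `glasso-f` — sample covariance after removing cells with more than
#'   70% zero counts ([filter_cells()]).
#'
#' @param Sigma Covariance matrix for the chosen variant.
#' @inheritParams weighted_glasso
#' @return A `"network_estimate"`.
#' @export
glasso <- function(Sigma, lambda, tol = 1e-4, max_iter = 100L,
                   warm_start = NULL, zero_tol = 1e-8) {
  weighted_glasso(Sigma, lambda, W = NULL, tol = tol, max_iter = max_iter,
                  warm_start = warm_start, zero_tol = zero_tol)
}

#' Edge set of a concentration matrix
#'
#' @param theta Symmetric concentration matrix.
#' @param zero_tol Magnitude at or below which an entry counts as zero.
#' @return Symmetric logical adjacency matrix with a zero diagonal.
#' @export
extract_edges <- function(theta, zero_tol = 1e-8) {
  A <- abs(theta) > zero_tol
  diag(A) <- FALSE
  A
}

#' Partial correlations from a concentration matrix
#'
#' `pcor[j1, j2] = -theta[j1, j2] / sqrt(theta[j1, j1] * theta[j2, j2])`,
#' with unit diagonal.
#'
#' @param theta Symmetric concentration matrix with positive diagonal.
#' @return Symmetric partial-correlation matrix.
#' @export
partial_correlation <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 1
  pc
}

#' Bayesian information criterion for a fitted network
#'
#' `BIC(lambda) = n * tr(Sp Theta) - n * logdet(Theta) + m * log(n)` with
#' `m` the number of (unordered) edges.
#'
#' @param Sp Covariance estimate used in the fit.
#' @param theta Estimated concentration matrix (positive definite).
#' @param n Number of cells.
#' @param m Edge count; defaults to the upper-triangle count of
#'   [extract_edges()].
#' @return Scalar BIC value.
#' @export
bic_score <- function(Sp, theta, n, m = NULL) {
  if (is.null(m)) {
    A <- extract_edges(theta)
    m <- sum(A[upper.tri(A)])
  }
  ch <- chol(theta) # errors if not PD
  ld <- 2 * sum(log(diag(ch)))
  n * sum(Sp * theta) - n * ld + m * log(n)
}

#' Fit a network along a decreasing lambda path
#'
#' Fits [weighted_glasso()] for every value of a decreasing lambda grid,
#' warm starting each fit from the previous (sparser) solution.
#'
#' @param Sp Covariance estimate.
#' @param lambda_grid Numeric vector of penalty values (sorted decreasing
#'   internally).
#' @param W Optional adaptive weights (`NULL` for constant).
#' @param n Optional number of cells; when given, a BIC score is attached
#'   per lambda.
#' @inheritParams weighted_glasso
#' @return An object of class `"lambda_path"`: list with `grid`
#'   (decreasing), `estimates` (one `"network_estimate"` per lambda),
#'   `edge_counts` and (if `n` given) `bic`.
#' @export
glasso_path <- function(Sp, lambda_grid, W = NULL, n = NULL, tol = 1e-4,
                        max_iter = 100L, zero_tol = 1e-8) {
  grid <- sort(unique(lambda_grid), decreasing = TRUE)
  fits <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    fits[[i]] <- weighted_glasso(Sp, grid[i], W = W, tol = tol,
                                 max_iter = max_iter, warm_start = prev,
                                 zero_tol = zero_tol)
    prev <- fits[[i]]
  }
  edge_counts <- vapply(fits, `[[`, numeric(1), "n_edges")
  bic <- if (is.null(n)) NULL else
    vapply(fits, function(f) bic_score(Sp, f$theta, n, f$n_edges), numeric(1))
  structure(list(grid = grid, estimates = fits, edge_counts = edge_counts,
                 bic = bic), class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("Lambda path with %d values in [%g, %g]; edges %s\n",
              length(x$grid), min(x$grid), max(x$grid),
              paste(x$edge_counts, collapse = ", ")))
  invisible(x)
}

#' Select lambda by BIC
#'
#' Fits the lambda path and returns the fit minimizing the BIC; ties go to
#' the larger lambda (sparser network).
#'
#' @inheritParams glasso_path
#' @param n Number of cells (required).
#' @return List with `path` (the `"lambda_path"`), `lambda` (selected) and
#'   `estimate` (the selected `"network_estimate"`).
#' @export
select_lambda_bic <- function(Sp, lambda_grid, n, W = NULL, tol = 1e-4,
                              max_iter = 100L) {
  path <- glasso_path(Sp, lambda_grid, W = W, n = n, tol = tol,
                      max_iter = max_iter)
  best <- which.min(path$bic) # grid is decreasing; which.min takes the
                              # first (largest-lambda) minimizer on ties
  list(path = path, lambda = path$grid[best], estimate = path$estimates[[best]])
}

#' Maximum edge budget at a target sparsity level
#'
#' `floor(fraction * p * (p - 1) / 2)` — e.g. 5% of the 124,750 pairs among
#' 500 genes is 6237 edges.
#'
#' @param p Number of genes.
#' @param fraction Fraction of all unordered gene pairs, in (0, 1].
#' @return Integer edge budget.
#' @export
max_edges_for_sparsity <- function(p, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  as.integer(floor(fraction * p * (p - 1) / 2))
}

#' Select lambda by a target sparsity level
#'
#' Returns the smallest lambda in the grid whose network has no more edges
#' than the budget `max_edges_for_sparsity(p, max_edge_fraction)`. If no
#' grid value qualifies, the sparsest (largest-lambda) network is returned
#' with a warning.
#'
#' @inheritParams glasso_path
#' @param max_edge_fraction Maximum fraction of gene pairs allowed as
#'   edges, in (0, 1).
#' @return List with `path`, `lambda` and `estimate`.
#' @export
select_lambda_sparsity <- function(Sp, lambda_grid, max_edge_fraction,
                                   W = NULL, tol = 1e-4, max_iter = 100L) {
  stopifnot(max_edge_fraction > 0, max_edge_fraction < 1)
  path <- glasso_path(Sp, lambda_grid, W = W, tol = tol, max_iter = max_iter)
  budget <- max_edges_for_sparsity(nrow(Sp), max_edge_fraction)
  ok <- which(path$edge_counts <= budget)
  if (length(ok) == 0L) {
    warning(sprintf("no lambda in the grid meets the %d-edge budget; returning the sparsest network",
                    budget))
    best <- 1L
  } else {
    best <- max(ok) # grid is decreasing: the last qualifying index is the smallest lambda
  }
  list(path = path, lambda = path$grid[best], estimate = path$estimates[[best]])
}

#' Baseline network by correlation thresholding
#'
#' Edge wherever `|corr| >= threshold` (inclusive), diagonal excluded.
#'
#' @param corr_matrix Symmetric correlation matrix.
#' @param threshold Absolute-correlation threshold.
#' @return Logical adjacency matrix.
#' @export
correlation_threshold_network <- function(corr_matrix, threshold) {
  A <- abs(corr_matrix) >= threshold
  diag(A) <- FALSE
  A
}

#' Gene modules by hierarchical clustering of partial correlations
#'
#' Clusters genes with distance `1 - |partial correlation|` and cuts the
#' dendrogram at `cut_height`; modules smaller than `min_size` are set to
#' `NA`.
#'
#' @param partial_corr Symmetric partial-correlation matrix.
#' @param cut_height Dendrogram cut height (default 0.85).
#' @param min_size Minimum module size to keep a label.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return Integer vector of module labels (NA for dropped modules), named
#'   by gene if names are available.
#' @export
gene_modules <- function(partial_corr, cut_height = 0.85, min_size = 1L,
                         linkage = "complete") {
  d <- as.dist(1 - abs(partial_corr))
  hc <- hclust(d, method = linkage)
  labels <- cutree(hc, h = cut_height)
  if (min_size > 1L) {
    sizes <- table(labels)
    labels[labels %in% as.integer(names(sizes)[sizes < min_size])] <- NA_integer_
  }
  labels
}

#' Write a network edge list
#'
#' Long-form TSV of the estimated edges: gene1, gene2, theta, partial_corr
#' and (optionally) the robust correlation.
#'
#' @param estimate A `"network_estimate"`.
#' @param path Output path.
#' @param r Optional correlation matrix to report per edge.
#' @return The edge table, invisibly.
#' @export
write_edge_list <- function(estimate, path, r = NULL) {
  A <- estimate$adjacency
  p <- nrow(A)
  genes <- colnames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  idx <- upper_tri_pairs(p)
  idx <- idx[A[idx], , drop = FALSE]
  tab <- data.frame(
    gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
    theta = estimate$theta[idx], partial_corr = estimate$partial_corr[idx]
  )
  if (!is.null(r)) tab$r <- r[idx]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
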