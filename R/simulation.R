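# Synthetic gene networks and dropout-thinned expression data.
#
# Ground truth is a block-diagonal connectivity matrix (power-law or hub
# topology within blocks, plus a fixed number of random between-block
# edges, with +/-1 edge signs). Partial correlations are drawn uniformly on
# +/-[0.4, 0.7], PD-repaired, converted to a correlation matrix, and cells
# are drawn from a multivariate normal on the log scale. Dropout thinning
# zeroes entry (i, j) with probability exp(-rho * X0[i, j]^2), so lowly
# expressed values drop out most often.

#' Simulate a ground-truth connectivity matrix
#'
#' @param p Number of genes.
#' @param topology `"power_law"` (node degrees sampled from
#'   `a_k = k^-alpha / zeta(alpha)`) or `"hub"` (a few hubs wired to
#'   disjoint shares of the remaining block genes).
#' @param block_sizes Integer vector summing to `p`; default one block of
#'   `p` genes split into blocks of ~50.
#' @param n_interblock Number of random between-block edges (default 0).
#' @param power_alpha Power-law exponent alpha (default 2.3).
#' @param n_hubs_per_block Hubs per block for the hub topology (default 1).
#' @param seed Optional RNG seed.
#' @return An object of class `"connectivity"`: list with `E` (symmetric
#'   p x p matrix with entries in -1/0/+1, zero diagonal), `block_sizes`,
#'   `topology`, `n_interblock`.
#' @export
simulate_connectivity <- function(p, topology = c("power_law", "hub"),
                                  block_sizes = NULL, n_interblock = 0L,
                                  power_alpha = 2.3, n_hubs_per_block = 1L,
                                  seed = NULL) {
  topology <- match.arg(topology)
  if (is.null(block_sizes)) {
    n_blocks <- max(1L, round(p / 50))
    block_sizes <- rep(p %/% n_blocks, n_blocks)
    rem <- p - sum(block_sizes)
    if (rem > 0) block_sizes[seq_len(rem)] <- block_sizes[seq_len(rem)] + 1L
  }
  if (sum(block_sizes) != p) stopf("block sizes sum to %d, not p = %d", sum(block_sizes), p)

  with_seed(seed, {
    E <- matrix(0, p, p)
    offset <- 0L
    for (bs in block_sizes) {
      nodes <- offset + seq_len(bs)
      adj <- switch(topology,
        power_law = block_power_law(bs, power_alpha),
        hub = block_hub(bs, n_hubs_per_block)
      )
      E[nodes, nodes] <- adj
      offset <- offset + bs
    }
    # between-block edges, sampled uniformly among between-block pairs
    if (n_interblock > 0L) {
      blk <- rep(seq_along(block_sizes), block_sizes)
      idx <- upper_tri_pairs(p)
      between <- which(blk[idx[, 1]] != blk[idx[, 2]])
      if (n_interblock > length(between)) {
        stopf("n_interblock = %d exceeds the %d between-block pairs",
              n_interblock, length(between))
      }
      pick <- sample(between, n_interblock)
      for (k in pick) {
        E[idx[k, 1], idx[k, 2]] <- 1
        E[idx[k, 2], idx[k, 1]] <- 1
      }
    }
    # +/-1 signs, equiprobable per edge
    idx <- upper_tri_pairs(p)
    on <- which(E[idx] != 0)
    signs <- sample(c(-1, 1), length(on), replace = TRUE)
    for (k in seq_along(on)) {
      i <- idx[on[k], 1]; j <- idx[on[k], 2]
      E[i, j] <- signs[k]
      E[j, i] <- signs[k]
    }
    structure(list(E = E, block_sizes = block_sizes, topology = topology,
                   n_interblock = as.integer(n_interblock)),
              class = "connectivity")
  })
}

# Power-law block: sample a degree sequence from the (truncated) zeta law
# a_k = k^-alpha / zeta(alpha), resample until graphical, realize with a
# deterministic construction, then rewire preserving degrees.
block_power_law <- function(bs, alpha) {
  if (bs < 2L) return(matrix(0, bs, bs))
  kmax <- bs - 1L
  pk <- (seq_len(kmax))^(-alpha)
  pk <- pk / sum(pk)
  degs <- NULL
  for (trial in 1:100) {
    d <- sample.int(kmax, bs, replace = TRUE, prob = pk)
    if (sum(d) %% 2L == 0L && igraph::is_graphical(d)) {
      degs <- d
      break
    }
  }
  if (is.null(degs)) stopf("no graphical power-law degree sequence after 100 resamples")
  g <- igraph::realize_degseq(degs)
  n_rewire <- 10L * igraph::ecount(g)
  if (n_rewire > 0) {
    g <- igraph::rewire(g, igraph::keeping_degseq(niter = n_rewire))
  }
  as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
}

# Hub block: hubs split the remaining nodes into (near-)disjoint shares.
block_hub <- function(bs, n_hubs) {
  adj <- matrix(0, bs, bs)
  if (bs < 2L) return(adj)
  n_hubs <- min(n_hubs, bs - 1L)
  hubs <- seq_len(n_hubs)
  others <- setdiff(seq_len(bs), hubs)
  share <- rep(hubs, length.out = length(others))
  share <- share[sample.int(length(share))]
  for (k in seq_along(others)) {
    adj[share[k], others[k]] <- 1
    adj[others[k], share[k]] <- 1
  }
  adj
}

#' Draw partial correlations on a connectivity pattern
#'
#' Magnitudes are i.i.d. Uniform(0.4, 0.7) with the sign taken from the
#' connectivity matrix; the result is PD-repaired by a diagonal shift of
#' `|min(0, tau)|` (`tau` = smallest eigenvalue).
#'
#' @param E A `"connectivity"` object or signed -1/0/+1 matrix.
#' @param seed Optional RNG seed.
#' @return List with `Lambda` (raw), `Lambda_p` (repaired) and `tau`.
#' @export
simulate_partial_correlations <- function(E, seed = NULL) {
  Em <- if (inherits(E, "connectivity")) E$E else E
  p <- nrow(Em)
  with_seed(seed, {
    L <- matrix(0, p, p)
    idx <- upper_tri_pairs(p)
    on <- which(Em[idx] != 0)
    vals <- runif(length(on), 0.4, 0.7) * Em[idx][on]
    for (k in seq_along(on)) {
      i <- idx[on[k], 1]; j <- idx[on[k], 2]
      L[i, j] <- vals[k]
      L[j, i] <- vals[k]
    }
    tau <- min(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    Lp <- L
    shift <- abs(min(0, tau))
    if (shift > 0) Lp <- Lp + diag(shift, p)
    list(Lambda = L, Lambda_p = Lp, tau = tau)
  })
}

#' Correlation matrix implied by a partial-correlation pattern
#'
#' Builds the unit-diagonal precision-like matrix `K` with
#' `K[j1, j2] = -Lambda_p[j1, j2]`, shifts its diagonal by `|tau_K| + 0.01`
#' if it is not positive definite, inverts it, and standardizes the
#' inverse to a correlation matrix.
#'
#' @param Lambda_p Symmetric partial-correlation matrix (off-diagonal part
#'   is used; any diagonal is ignored).
#' @return Correlation matrix `R` (unit diagonal, positive definite).
#' @export
partial_to_correlation <- function(Lambda_p) {
  p <- nrow(Lambda_p)
  K <- -Lambda_p
  diag(K) <- 1
  tauK <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (tauK <= 0) K <- K + diag(abs(tauK) + 0.01, p)
  Sigma <- tryCatch(solve(K), error = function(e)
    stopf("precision construction is singular even after the diagonal shift"))
  d <- 1 / sqrt(diag(Sigma))
  R <- Sigma * tcrossprod(d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Per-gene expression means and standard deviations
#'
#' `source = "default"` draws log10-scale means from Uniform(0.5, 3.5) and
#' standard deviations from Uniform(0.3, 1.0) — stand-in distributions
#' spanning the range typical of highly expressed genes. With
#' `source = "from_matrix"`, the Gamma-Normal mixture is fitted to a
#' supplied log matrix Y and the Normal-component `(mu, sigma)` of `p`
#' sampled genes are returned.
#'
#' @param p Number of genes.
#' @param source `"default"` or `"from_matrix"`.
#' @param Y Log matrix (pseudo-count 1.01) for `source = "from_matrix"`.
#' @param seed Optional RNG seed.
#' @return List with `means` and `sds`, both length `p`.
#' @export
sample_gene_params <- function(p, source = c("default", "from_matrix"),
                               Y = NULL, seed = NULL) {
  source <- match.arg(source)
  if (p == 0L) return(list(means = numeric(0), sds = numeric(0)))
  with_seed(seed, {
    if (source == "default") {
      list(means = runif(p, 0.5, 3.5), sds = runif(p, 0.3, 1.0))
    } else {
      if (is.null(Y)) stopf("source = \"from_matrix\" requires `Y`")
      fits <- fit_mixtures(Y, seed = seed)
      mus <- vapply(fits, `[[`, numeric(1), "mu")
      sds <- vapply(fits, `[[`, numeric(1), "sigma")
      keep <- which(sds > 0)
      # keep gene order when the request covers all usable genes
      pick <- if (p == length(keep)) keep
              else if (length(keep) >= p) sort(sample(keep, p))
              else sample(keep, p, replace = TRUE)
      list(means = mus[pick], sds = sds[pick])
    }
  })
}

#' Simulate full (pre-dropout) log-scale expression
#'
#' Rows are i.i.d. multivariate normal with mean `means` and covariance
#' `diag(sds) %*% R %*% diag(sds)`; negative draws are floored at 0 since
#' observed matrices are non-negative log counts.
#'
#' @param R Correlation matrix.
#' @param means,sds Per-gene parameters.
#' @param n Number of cells.
#' @param seed Optional RNG seed.
#' @return An `n x p` matrix `X0`.
#' @export
simulate_expression <- function(R, means, sds, n, seed = NULL) {
  p <- nrow(R)
  stopifnot(length(means) == p, length(sds) == p, n >= 1)
  with_seed(seed, {
    ch <- chol(R + diag(1e-10, p))
    Z <- matrix(rnorm(n * p), n, p)
    X0 <- sweep(Z %*% ch, 2L, sds, `*`)
    X0 <- sweep(X0, 2L, means, `+`)
    X0[X0 < 0] <- 0
    X0
  })
}

#' Apply expression-dependent dropout
#'
#' Each entry is zeroed with probability `exp(-rho * X0^2)`: entries at or
#' near zero expression always drop out, highly expressed ones rarely do.
#' The study grid for `rho` is 0.07, 0.10, 0.13, 0.16 (larger `rho` means
#' fewer induced zeros).
#'
#' @param X0 Full log-scale expression matrix.
#' @param rho Dropout-decay parameter (> 0).
#' @param seed Optional RNG seed.
#' @return List with `dropout_prob` (matrix `p_ij`), `I` (0/1 indicator
#'   matrix of zeroed entries) and `X` (observed matrix).
#' @export
apply_dropout <- function(X0, rho, seed = NULL) {
  stopifnot(rho > 0)
  with_seed(seed, {
    prob <- exp(-rho * X0^2)
    I <- matrix(rbinom(length(X0), 1L, prob), nrow(X0), ncol(X0))
    X <- X0 * (1 - I)
    list(dropout_prob = prob, I = I, X = X)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: connectivity, partial correlations, implied
#' correlation matrix, gene parameters, multivariate-normal expression and
#' dropout thinning. Every stage consumes a sub-seed derived from `seed`,
#' so identical seeds give bit-identical datasets.
#'
#' @inheritParams simulate_connectivity
#' @param n Number of cells (default 300).
#' @param rho Dropout parameter (default 0.10).
#' @param means,sds Optional per-gene parameters; drawn by
#'   [sample_gene_params()] when `NULL`.
#' @param seed RNG seed (required, for reproducibility).
#' @return An object of class `"synthetic_dataset"`: list with
#'   `connectivity`, `truth` (logical adjacency `|E| > 0`), `Lambda`,
#'   `Lambda_p`, `R`, `gene_means`, `gene_sds`, `X0`, `dropout_prob`, `I`,
#'   `X`, `rho`, `seed`.
#' @export
simulate_dataset <- function(p = 100L, n = 300L,
                             topology = c("power_law", "hub"),
                             rho = 0.10, block_sizes = NULL,
                             n_interblock = 0L, power_alpha = 2.3,
                             n_hubs_per_block = 1L, means = NULL, sds = NULL,
                             seed = 1L) {
  topology <- match.arg(topology)
  conn <- simulate_connectivity(p, topology, block_sizes, n_interblock,
                                power_alpha, n_hubs_per_block,
                                seed = derive_seed(seed, "connectivity"))
  pc <- simulate_partial_correlations(conn, seed = derive_seed(seed, "partial"))
  R <- partial_to_correlation(pc$Lambda_p)
  if (is.null(means) || is.null(sds)) {
    gp <- sample_gene_params(p, seed = derive_seed(seed, "gene_params"))
    if (is.null(means)) means <- gp$means
    if (is.null(sds)) sds <- gp$sds
  }
  X0 <- simulate_expression(R, means, sds, n, seed = derive_seed(seed, "expression"))
  dr <- apply_dropout(X0, rho, seed = derive_seed(seed, "dropout"))
  structure(list(
    connectivity = conn, truth = abs(conn$E) > 0,
    Lambda = pc$Lambda, Lambda_p = pc$Lambda_p, R = R,
    gene_means = means, gene_sds = sds,
    X0 = X0, dropout_prob = dr$dropout_prob, I = dr$I, X = dr$X,
    rho = rho, seed = seed
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d cells x %d genes (%s topology, %d true edges, rho = %g, %.1f%% zeros)\n",
    nrow(x$X), ncol(x$X), x$connectivity$topology,
    sum(x$truth[upper.tri(x$truth)]), x$rho, 100 * mean(x$X == 0)))
  invisible(x)
}
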