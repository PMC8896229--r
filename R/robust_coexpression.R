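# Detection-aware robust correlation and covariance.
#
# For genes j1, j2 the robust correlation is the pairwise-complete Pearson
# coefficient computed over the cells in which BOTH genes are confidently
# measured (non-detection probability below the threshold). Pairs with
# fewer than `min_pairs` complete cells fall back to the ordinary
# full-sample Pearson coefficient.

#' Robust pairwise-complete correlation matrix
#'
#' @param X Cells x genes log matrix (pseudo-count 1).
#' @param mask A `"detection_mask"` (from [detection_mask()]) of the same
#'   shape, or a logical cells x genes matrix of confident entries.
#' @param min_pairs Minimum number of complete cells per pair before falling
#'   back to the full-sample Pearson coefficient (default 10).
#' @param center `"complete"` (default) centers each pair at the means over
#'   its own complete cells — the pairwise-complete Pearson coefficient.
#'   `"full"` centers at the full-sample gene means while still summing
#'   over complete cells only; with substantial dropout the full-sample
#'   means sit far below the confidently measured values, biasing every
#'   pair toward +1, so this variant is offered for comparison only.
#' @return An object of class `"robust_correlation"`: list with
#'   * `r` — symmetric correlation matrix, unit diagonal;
#'   * `n_complete` — integer matrix of complete-cell counts per pair;
#'   * `fallback` — logical matrix marking pairs where the Pearson
#'     coefficient was substituted (too few complete cells) or the
#'     complete-set denominator vanished.
#' @export
robust_correlation <- function(X, mask, min_pairs = 10L,
                               center = c("complete", "full")) {
  center <- match.arg(center)
  conf <- if (inherits(mask, "detection_mask")) mask$confident else mask
  if (!is.logical(conf)) stopf("`mask` must be a detection_mask or logical matrix")
  if (!identical(dim(conf), dim(X))) stopf("`X` and `mask` shapes differ")
  p <- ncol(X)
  if (p < 2L) stopf("need at least 2 genes")
  n <- nrow(X)

  M <- matrix(as.numeric(conf), n, p)
  n_complete <- round(crossprod(M))
  storage.mode(n_complete) <- "integer"

  if (center == "full") {
    Xc <- sweep(X, 2L, colMeans(X))
    XM <- Xc * M
    num <- crossprod(XM)          # sum over complete cells of Xc_j1 * Xc_j2
    a <- crossprod(Xc^2 * M, M)   # a[j1, j2] = sum Xc_j1^2 over complete cells
  } else {
    # per-pair complete-set moments, all via cross products
    XM <- X * M
    Sx <- crossprod(XM, M)        # Sx[j1, j2] = sum of X_j1 over complete cells
    nc <- pmax(n_complete, 1L)
    num <- crossprod(XM) - Sx * t(Sx) / nc
    a <- crossprod(X^2 * M, M) - Sx^2 / nc
    a <- pmax(a, 0)
  }

  denom <- sqrt(a * t(a))
  r <- matrix(0, p, p)
  ok <- denom > 0
  r[ok] <- num[ok] / denom[ok]

  pearson <- suppressWarnings(cor(X))
  pearson[!is.finite(pearson)] <- 0

  fallback <- n_complete < min_pairs
  zero_denom <- !ok & !fallback
  r[fallback] <- pearson[fallback]
  r[zero_denom] <- 0
  fallback <- fallback | zero_denom

  r <- (r + t(r)) / 2
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  diag(fallback) <- FALSE
  if (!is.null(colnames(X))) {
    dimnames(r) <- list(colnames(X), colnames(X))
    dimnames(n_complete) <- dimnames(r)
    dimnames(fallback) <- dimnames(r)
  }

  structure(list(r = r, n_complete = n_complete, fallback = fallback,
                 min_pairs = as.integer(min_pairs)),
            class = "robust_correlation")
}

#' Robust covariance from the robust correlation
#'
#' `S[j1, j2] = sigma_hat[j1] * sigma_hat[j2] * r[j1, j2]`, with the
#' per-gene standard deviations taken from the Normal component of the
#' mixture fits (degenerate genes: sample standard deviation of X).
#'
#' @param r A `"robust_correlation"` object or a correlation matrix.
#' @param sigma_hat Vector of per-gene standard deviations (> 0).
#' @return Symmetric covariance matrix with diagonal `sigma_hat^2`.
#' @export
robust_covariance <- function(r, sigma_hat) {
  rmat <- if (inherits(r, "robust_correlation")) r$r else r
  if (length(sigma_hat) != ncol(rmat)) {
    stopf("`sigma_hat` has length %d but there are %d genes",
          length(sigma_hat), ncol(rmat))
  }
  if (any(sigma_hat <= 0)) stopf("`sigma_hat` must be positive")
  S <- rmat * tcrossprod(sigma_hat)
  dimnames(S) <- dimnames(rmat)
  S
}

#' Per-gene standard deviations for the robust covariance
#'
#' Normal-component sd from each mixture fit; degenerate fits fall back to
#' the sample sd of the corresponding column of `X`.
#'
#' @param fits List of `"gene_mixture"` fits.
#' @param X Cells x genes log matrix used as the fallback for degenerate fits.
#' @return Numeric vector of standard deviations.
#' @export
mixture_sigma <- function(fits, X) {
  vapply(seq_along(fits), function(j) {
    f <- fits[[j]]
    s <- if (f$degenerate) sd(X[, j]) else f$sigma
    max(s, 1e-8)
  }, numeric(1))
}

#' Positive semidefinite repair of a covariance matrix
#'
#' Shifts the diagonal by the magnitude of the most negative eigenvalue:
#' `Sp = S + |min(0, tau)| * I` with `tau` the smallest eigenvalue of `S`.
#'
#' @param S Symmetric matrix.
#' @return List with `Sp` (repaired matrix), `tau` (smallest eigenvalue of
#'   `S`) and `shift` (the diagonal shift applied).
#' @export
psd_projection <- function(S) {
  check_square_symmetric(S, "S")
  tau <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  shift <- abs(min(0, tau))
  Sp <- S
  if (shift > 0) Sp <- Sp + diag(shift, nrow(S))
  list(Sp = Sp, tau = tau, shift = shift)
}

#' Robust correlation, covariance and PSD repair in one call
#'
#' Convenience wrapper running [robust_correlation()], [robust_covariance()]
#' (with [mixture_sigma()]) and [psd_projection()].
#'
#' @inheritParams robust_correlation
#' @param fits Per-gene mixture fits.
#' @return List with `corr` (robust_correlation), `sigma_hat`, `S`, `Sp`,
#'   `tau`.
#' @export
robust_coexpression <- function(X, mask, fits, min_pairs = 10L) {
  corr <- robust_correlation(X, mask, min_pairs = min_pairs)
  sig <- mixture_sigma(fits, X)
  S <- robust_covariance(corr, sig)
  proj <- psd_projection(S)
  list(corr = corr, sigma_hat = sig, S = S, Sp = proj$Sp, tau = proj$tau)
}

#' Write a square matrix or its long form to TSV
#'
#' @param x A `"robust_correlation"` object or square matrix.
#' @param path Output path.
#' @param long If `TRUE`, write the upper triangle in long form
#'   (gene1, gene2, r, n_complete, fallback); requires a
#'   `"robust_correlation"` input.
#' @export
write_correlation <- function(x, path, long = FALSE) {
  if (long) {
    stopifnot(inherits(x, "robust_correlation"))
    p <- ncol(x$r)
    idx <- upper_tri_pairs(p)
    genes <- colnames(x$r)
    if (is.null(genes)) genes <- paste0("g", seq_len(p))
    tab <- data.frame(
      gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
      r = x$r[idx], n_complete = x$n_complete[idx], fallback = x$fallback[idx]
    )
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- if (inherits(x, "robust_correlation")) x$r else x
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(path)
}
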