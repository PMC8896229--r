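# Independent oracles used to cross-check the package implementations.
# Each one deliberately uses a different algorithm or a naive scalar
# formulation than the code path it verifies.

# Graphical lasso by ADMM (scaled dual splitting with an eigendecomposition
# X-update), independent of the package's block-coordinate-descent solver.
# `rho_mat` is the elementwise penalty; its diagonal is not penalized.
admm_glasso <- function(S, rho_mat, mu = 1, max_iter = 10000, tol = 1e-10) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  for (it in seq_len(max_iter)) {
    A <- mu * (Z - U) - S
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    xi <- (e$values + sqrt(e$values^2 + 4 * mu)) / (2 * mu)
    X <- e$vectors %*% (xi * t(e$vectors))
    Z_old <- Z
    V <- X + U
    Z <- sign(V) * pmax(abs(V) - rho_mat / mu, 0)
    diag(Z) <- diag(V)
    U <- U + X - Z
    if (norm(X - Z, "F") < tol * p && mu * norm(Z - Z_old, "F") < tol * p) break
  }
  (Z + t(Z)) / 2
}

# Robust pairwise-complete correlation, scalar loops straight from the
# definition (no shared code with robust_correlation()).
brute_robust_corr <- function(X, conf, min_pairs = 10L,
                              center = c("complete", "full")) {
  center <- match.arg(center)
  p <- ncol(X)
  n <- nrow(X)
  r <- diag(p)
  full_means <- colMeans(X)
  for (j1 in seq_len(p - 1)) {
    for (j2 in (j1 + 1):p) {
      cells <- which(conf[, j1] & conf[, j2])
      if (length(cells) < min_pairs) {
        rr <- cor(X[, j1], X[, j2])
        if (!is.finite(rr)) rr <- 0
      } else {
        m1 <- if (center == "full") full_means[j1] else mean(X[cells, j1])
        m2 <- if (center == "full") full_means[j2] else mean(X[cells, j2])
        num <- sum((X[cells, j1] - m1) * (X[cells, j2] - m2))
        a <- sum((X[cells, j1] - m1)^2)
        b <- sum((X[cells, j2] - m2)^2)
        rr <- if (a * b > 0) num / sqrt(a * b) else 0
      }
      r[j1, j2] <- r[j2, j1] <- rr
    }
  }
  r
}

# Precision-recall / ROC areas by explicit enumeration over every distinct
# score threshold, trapezoidal integration on the collected points.
brute_pr_roc <- function(scores, truth) {
  ut <- upper.tri(scores)
  s <- abs(scores[ut])
  y <- as.logical(truth[ut])
  P <- sum(y)
  N <- sum(!y)
  th <- sort(unique(s), decreasing = TRUE)
  rec <- prec <- tpr <- fpr <- numeric(length(th))
  for (k in seq_along(th)) {
    pred <- s >= th[k]
    tp <- sum(pred & y)
    rec[k] <- tp / P
    prec[k] <- tp / sum(pred)
    tpr[k] <- rec[k]
    fpr[k] <- sum(pred & !y) / N
  }
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  list(
    auprc = trap(c(0, rec), c(prec[1], prec)),
    auroc = trap(c(0, fpr, 1), c(0, tpr, 1))
  )
}

# Penalized log-likelihood of a candidate concentration matrix, used for
# solver sanity checks.
penalized_objective <- function(theta, S, lambda, W) {
  P <- lambda * W
  diag(P) <- 0
  ld <- determinant(theta, logarithm = TRUE)$modulus[1]
  ld - sum(S * theta) - sum(P * abs(theta))
}

# Draw from the Gamma-Normal mixture with known parameters.
rmix_gamma_normal <- function(n, lambda, alpha, beta, mu, sigma) {
  z <- rbinom(n, 1, lambda)
  y <- ifelse(z == 1, rgamma(n, alpha, rate = beta), rnorm(n, mu, sigma))
  pmax(y, 1e-4)
}

# Small random PD covariance for solver tests.
random_covariance <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + 0.5 * diag(p)
}
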