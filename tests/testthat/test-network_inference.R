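test_that("solver matches the ADMM oracle for constant and adaptive weights", {
  set.seed(31)
  for (rep in 1:5) {
    p <- sample(c(5, 10), 1)
    S <- random_covariance(p)
    lam <- runif(1, 0.1, 0.3)

    # constant weights
    fit <- weighted_glasso(S, lam, tol = 1e-7, max_iter = 500)
    P <- matrix(lam, p, p); diag(P) <- 0
    expect_lt(max(abs(fit$theta - admm_glasso(S, P))), 1e-4)

    # adaptive weights
    W <- 1 - abs(cov2cor(S)); diag(W) <- 0
    fitw <- weighted_glasso(S, lam, W = W, tol = 1e-7, max_iter = 500)
    expect_lt(max(abs(fitw$theta - admm_glasso(S, lam * W))), 1e-4)
  }
})

test_that("p = 2 solution equals the soft-thresholded covariance inverse", {
  Sp <- matrix(c(1, 0.8, 0.8, 1), 2)
  W <- matrix(c(0, 0.2, 0.2, 0), 2)
  fit <- weighted_glasso(Sp, 0.1, W = W, tol = 1e-9)
  Sig <- Sp
  Sig[1, 2] <- Sig[2, 1] <- sign(0.8) * max(abs(0.8) - 0.1 * 0.2, 0)
  expect_equal(fit$theta, solve(Sig), tolerance = 1e-6)
})

test_that("full shrinkage at large lambda yields a diagonal estimate", {
  set.seed(32)
  S <- random_covariance(6)
  lam <- max(abs(S - diag(diag(S)))) * 1.01
  fit <- weighted_glasso(S, lam)
  expect_equal(fit$n_edges, 0L)
  expect_equal(fit$theta, diag(1 / diag(S)), tolerance = 1e-8)

  # identity covariance: zero edges for any positive lambda
  expect_equal(glasso(diag(5), 0.01)$n_edges, 0L)
})

test_that("returned objective beats diagonal and inverse starts", {
  set.seed(33)
  S <- random_covariance(8)
  lam <- 0.15
  W1 <- matrix(1, 8, 8); diag(W1) <- 0
  fit <- weighted_glasso(S, lam, tol = 1e-7, max_iter = 500)
  obj_fit <- penalized_objective(fit$theta, S, lam, W1)
  expect_gte(obj_fit, penalized_objective(diag(1 / diag(S)), S, lam, W1) - 1e-8)
  expect_gte(obj_fit, penalized_objective(solve(S + 0.1 * diag(8)), S, lam, W1) - 1e-8)
})

test_that("solver rejects indefinite inputs and flags them for repair", {
  S <- matrix(c(1, 2, 2, 1), 2)
  expect_error(weighted_glasso(S, 0.1), "psd_projection")
})

test_that("edge extraction applies the zero tolerance symmetrically", {
  expect_equal(sum(extract_edges(diag(3))), 0)
  th <- matrix(c(2, -1, 0.5, -1, 2, -0.8, 0.5, -0.8, 2), 3)
  expect_equal(sum(extract_edges(th)[upper.tri(th)]), 3L)
  th2 <- diag(3); th2[1, 2] <- th2[2, 1] <- 5e-9 # below zero_tol = 1e-8
  expect_equal(sum(extract_edges(th2)), 0)
  # invariant to joint permutation
  set.seed(34)
  th3 <- random_covariance(5)
  perm <- sample(5)
  expect_equal(extract_edges(th3)[perm, perm], extract_edges(th3[perm, perm]))
})

test_that("partial correlations follow the concentration-matrix identity", {
  expect_equal(partial_correlation(diag(4)), diag(4))
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_correlation(th)[1, 2], 0.5)
  set.seed(35)
  th2 <- random_covariance(5)
  pc <- partial_correlation(th2)
  off <- upper.tri(th2)
  expect_true(all(sign(pc[off]) == -sign(th2[off]) | th2[off] == 0))
  expect_equal(diag(pc), rep(1, 5))
})

test_that("BIC matches its closed form and edge-count additivity", {
  expect_equal(bic_score(diag(7), diag(7), n = 10, m = 0), 70) # n * p
  # adding m edges adds m * log(n)
  set.seed(36)
  S <- random_covariance(4)
  fit <- weighted_glasso(S, 0.05, tol = 1e-7)
  b0 <- bic_score(S, fit$theta, n = 50, m = 0)
  b3 <- bic_score(S, fit$theta, n = 50, m = 3)
  expect_equal(b3 - b0, 3 * log(50))
  # independent scalar evaluation on a fixed 3-gene instance
  th <- matrix(c(2, -0.5, 0, -0.5, 1.5, -0.3, 0, -0.3, 1.8), 3)
  Sp <- matrix(c(1, 0.4, 0.1, 0.4, 1.2, 0.2, 0.1, 0.2, 0.9), 3)
  manual <- 20 * sum(diag(Sp %*% th)) - 20 * log(det(th)) + 2 * log(20)
  expect_equal(bic_score(Sp, th, n = 20), manual, tolerance = 1e-10)
})

test_that("lambda paths are warm-started and near-monotone in edges", {
  set.seed(37)
  viol <- 0; steps <- 0
  for (rep in 1:5) {
    S <- random_covariance(10)
    path <- glasso_path(S, seq(0.5, 0.02, by = -0.04), n = 60)
    expect_true(all(diff(path$grid) < 0))
    d <- diff(path$edge_counts)
    viol <- viol + sum(d < 0)
    steps <- steps + length(d)
    expect_length(path$bic, length(path$grid))
  }
  expect_gte(1 - viol / steps, 0.95)
})

test_that("BIC selection returns the path minimizer, preferring sparser fits", {
  set.seed(38)
  D <- simulate_dataset(p = 20, n = 150, topology = "hub", rho = 0.10, seed = 38)
  S <- psd_projection(cov(D$X))$Sp
  sel <- select_lambda_bic(S, seq(0.6, 0.05, by = -0.05), n = 150)
  expect_equal(sel$lambda, sel$path$grid[which.min(sel$path$bic)])
  expect_equal(sel$estimate$n_edges,
               sel$path$edge_counts[which.min(sel$path$bic)])
})

test_that("sparsity selection takes the smallest lambda within the edge budget", {
  expect_equal(max_edges_for_sparsity(500, 0.05), 6237L)
  expect_equal(max_edges_for_sparsity(1000, 0.01), 4995L)
  expect_equal(max_edges_for_sparsity(51, 1.0), 1275L)

  set.seed(39)
  S <- random_covariance(12)
  grid <- seq(0.6, 0.05, by = -0.05)
  sel <- select_lambda_sparsity(S, grid, max_edge_fraction = 0.1)
  budget <- max_edges_for_sparsity(12, 0.1)
  expect_lte(sel$estimate$n_edges, budget)
  # every smaller grid lambda must bust the budget
  smaller <- sel$path$grid < sel$lambda
  expect_true(all(sel$path$edge_counts[smaller] > budget))

  # all-empty path: the smallest grid value qualifies
  sel2 <- select_lambda_sparsity(2 * diag(12), grid, max_edge_fraction = 0.1)
  expect_equal(sel2$lambda, min(grid))
  expect_equal(sel2$estimate$n_edges, 0L)
})

test_that("correlation thresholding uses an inclusive boundary", {
  set.seed(40)
  r <- cov2cor(random_covariance(5))
  expect_equal(sum(correlation_threshold_network(r, 0)[upper.tri(r)]), 10L)
  expect_equal(sum(correlation_threshold_network(r, 1.01)), 0L)
  th <- abs(r[1, 2])
  expect_true(correlation_threshold_network(r, th)[1, 2])
})

test_that("baseline variants compose as documented", {
  set.seed(41)
  D <- simulate_dataset(p = 15, n = 120, topology = "power_law", rho = 0.16,
                        seed = 41)
  # glasso-r: constant weights on the robust covariance == glasso on Sp
  coex <- infer_coexpression(D$X, seed = 41)
  f1 <- glasso(coex$Sp, 0.3)
  f2 <- weighted_glasso(coex$Sp, 0.3, W = NULL)
  expect_equal(f1$theta, f2$theta)

  # glasso-f with no high-zero cells is plain glasso
  X_dense <- D$X0 # pre-dropout matrix, few zeros
  kept <- filter_cells(X_dense, 0.7)
  expect_equal(nrow(kept$matrix), nrow(X_dense))
  expect_equal(glasso(psd_projection(cov(kept$matrix))$Sp, 0.2)$theta,
               glasso(psd_projection(cov(X_dense))$Sp, 0.2)$theta)
})

test_that("gene modules split at the dendrogram cut", {
  # two blocks: |pcor| 0.9 within, 0 between -> 2 modules at cut 0.85
  pc <- diag(6)
  pc[1:3, 1:3] <- 0.9; pc[4:6, 4:6] <- 0.9; diag(pc) <- 1
  labels <- gene_modules(pc, cut_height = 0.85)
  expect_equal(length(unique(labels)), 2L)
  expect_equal(length(unique(labels[1:3])), 1L)
  expect_true(labels[1] != labels[4])

  # cut at 0: every gene its own module
  expect_equal(length(unique(gene_modules(pc, cut_height = 0))), 6L)
  # identity pcor at a high cut: distances are all 1 > 0.999
  expect_equal(length(unique(gene_modules(diag(5), cut_height = 0.999))), 5L)
  # min_size drops small modules
  lab <- gene_modules(pc, cut_height = 0.85, min_size = 4L)
  expect_true(all(is.na(lab)))
})
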