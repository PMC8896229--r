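test_that("hub topology with one hub is a star", {
  conn <- simulate_connectivity(10, "hub", block_sizes = 10,
                                n_hubs_per_block = 1, seed = 51)
  A <- abs(conn$E)
  deg <- rowSums(A)
  expect_equal(sum(A[upper.tri(A)]), 9)
  expect_equal(sort(deg, decreasing = TRUE), c(9, rep(1, 9)))
})

test_that("block structure and interblock edges are respected", {
  conn <- simulate_connectivity(20, "hub", block_sizes = c(10, 10),
                                n_interblock = 0, seed = 52)
  expect_true(all(conn$E[1:10, 11:20] == 0))

  conn2 <- simulate_connectivity(20, "hub", block_sizes = c(10, 10),
                                 n_interblock = 4, seed = 52)
  expect_equal(sum(abs(conn2$E[1:10, 11:20])), 4)
  expect_equal(conn2$E, t(conn2$E))
  expect_true(all(conn2$E %in% c(-1, 0, 1)))
  expect_true(all(diag(conn2$E) == 0))

  expect_error(simulate_connectivity(4, "hub", block_sizes = c(2, 2),
                                     n_interblock = 100, seed = 1),
               "between-block")
})

test_that("power-law blocks have heavy-tailed degree distributions", {
  degree_one_most_frequent <- 0
  slopes <- numeric(20)
  for (s in 1:20) {
    conn <- simulate_connectivity(100, "power_law", block_sizes = 100,
                                  power_alpha = 2.3, seed = s)
    deg <- rowSums(abs(conn$E))
    tab <- table(deg[deg > 0])
    if (names(which.max(tab))[1] == "1") {
      degree_one_most_frequent <- degree_one_most_frequent + 1
    }
    freq <- as.numeric(tab)
    k <- as.numeric(names(tab))
    slopes[s] <- coef(lm(log(freq) ~ log(k)))[2]
  }
  expect_gte(degree_one_most_frequent, 18)
  expect_lt(mean(slopes), 0)
})

test_that("partial correlations respect the edge pattern and magnitudes", {
  conn <- simulate_connectivity(30, "power_law", block_sizes = 30, seed = 53)
  pc <- simulate_partial_correlations(conn, seed = 53)
  on <- conn$E != 0
  expect_true(all(abs(pc$Lambda[on]) >= 0.4 & abs(pc$Lambda[on]) <= 0.7))
  expect_true(all(pc$Lambda[!on & row(conn$E) != col(conn$E)] == 0))
  expect_true(all(sign(pc$Lambda[on]) == sign(conn$E[on])))

  # zero connectivity -> zero matrices
  pc0 <- simulate_partial_correlations(matrix(0, 5, 5), seed = 1)
  expect_equal(pc0$Lambda, matrix(0, 5, 5))
  expect_equal(pc0$Lambda_p, matrix(0, 5, 5))

  # PD repair property over seeds
  set.seed(54)
  for (s in 1:50) {
    E <- matrix(0, 8, 8)
    idx <- which(upper.tri(E))
    on <- sample(idx, 10)
    E[on] <- sample(c(-1, 1), 10, TRUE)
    E <- E + t(E)
    lp <- simulate_partial_correlations(E)$Lambda_p
    ev <- eigen(lp, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("partial-correlation to correlation conversion is exact where known", {
  expect_equal(partial_to_correlation(matrix(0, 4, 4)), diag(4))
  # p = 2: partial correlation equals correlation
  L <- matrix(c(0, 0.5, 0.5, 0), 2)
  R <- partial_to_correlation(L)
  expect_equal(R[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(diag(R), rep(1, 2))

  conn <- simulate_connectivity(20, "hub", block_sizes = 20, seed = 55)
  pc <- simulate_partial_correlations(conn, seed = 55)
  R2 <- partial_to_correlation(pc$Lambda_p)
  expect_equal(diag(R2), rep(1, 20))
  ev <- eigen(R2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("gene parameter sampling covers both sources", {
  expect_equal(sample_gene_params(0), list(means = numeric(0), sds = numeric(0)))
  gp <- sample_gene_params(50, seed = 56)
  expect_true(all(gp$sds >= 0.3 & gp$sds <= 1.0))
  expect_true(all(gp$means >= 0.5 & gp$means <= 3.5))

  # from_matrix recovers the Normal component of a known mixture
  set.seed(57)
  Y <- matrix(rmix_gamma_normal(30 * 500, 0.3, 2, 60, 2, 0.5), 500, 30)
  gp2 <- sample_gene_params(30, "from_matrix", Y = Y, seed = 57)
  expect_equal(mean(gp2$means), 2, tolerance = 0.1)
  expect_equal(mean(gp2$sds), 0.5, tolerance = 0.1)
  expect_true(all(abs(gp2$means - 2) < 0.2))
})

test_that("multivariate-normal expression has the requested moments", {
  set.seed(58)
  p <- 6
  means <- runif(p, 1.5, 3)
  sds <- runif(p, 0.3, 0.6)
  X0 <- simulate_expression(diag(p), means, sds, n = 2000, seed = 58)
  emp <- cor(X0)
  offd <- abs(emp[upper.tri(emp)])
  expect_gte(mean(offd <= 4 / sqrt(2000)), 0.95)
  expect_true(all(abs(colMeans(X0) - means) <= 3 * sds / sqrt(2000) + 1e-3))
  expect_equal(dim(simulate_expression(diag(3), rep(2, 3), rep(1, 3), 1, seed = 1)),
               c(1L, 3L))
  expect_true(all(X0 >= 0))
})

test_that("dropout thinning follows the exponential-decay model", {
  X0 <- matrix(c(0, 3, 1, 2), 2)
  dr <- apply_dropout(X0, 0.07, seed = 59)
  expect_equal(dr$dropout_prob[1, 1], 1) # zero expression always drops
  expect_equal(dr$X[1, 1], 0)
  expect_equal(dr$dropout_prob[2, 1], exp(-0.07 * 9), tolerance = 1e-12)
  expect_equal(dr$X, X0 * (1 - dr$I))

  # average observed zero fraction decreases as rho grows
  set.seed(60)
  X0_big <- matrix(runif(5000, 0, 4), 100)
  zf <- sapply(c(0.07, 0.10, 0.13, 0.16), function(rho) {
    mean(sapply(1:20, function(s) mean(apply_dropout(X0_big, rho, seed = s)$X == 0)))
  })
  expect_true(all(diff(zf) < 0))
})

test_that("the full generator is deterministic and truth-preserving", {
  D1 <- simulate_dataset(p = 40, n = 100, topology = "power_law", rho = 0.10,
                         seed = 61)
  D2 <- simulate_dataset(p = 40, n = 100, topology = "power_law", rho = 0.10,
                         seed = 61)
  expect_identical(D1$X, D2$X)
  expect_identical(D1$connectivity$E, D2$connectivity$E)

  expect_identical(D1$truth, abs(D1$connectivity$E) > 0)
  expect_equal(D1$X, D1$X0 * (1 - D1$I))
  expect_equal(D1$dropout_prob, exp(-0.10 * D1$X0^2))

  D3 <- simulate_dataset(p = 40, n = 100, topology = "power_law", rho = 0.10,
                         seed = 62)
  expect_false(identical(D1$X, D3$X))
})
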