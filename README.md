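# scnet

Sparse gene co-expression networks from single-cell RNA-seq data.

Single-cell expression matrices are dominated by zeros and unreliably low
counts: a truly expressed transcript is often missed by the protocol
(dropout), and the resulting false zeros corrupt the Pearson or Spearman
correlations that bulk-RNA-seq network methods rely on. `scnet` infers
cell-type-specific co-expression networks that account for this explicitly.
It is aimed at computational biologists who have a counts matrix for one
cell type and want a sparse, interpretable gene-gene dependency graph
rather than a dense correlation heat map.

## The model

Working on the log scale (`X = log10(C + 1)` after library-size
normalization), the method has three stages:

1. **Dropout model.** Each gene *j*'s log expression across cells is a
   Gamma-Normal mixture,

   ```
   f_j(y) = lambda_j Gamma(y; alpha_j, beta_j) + (1 - lambda_j) Normal(y; mu_j, sigma_j)
   ```

   fitted by EM. The Gamma component captures non-detected values near
   zero, the Normal component actual expression; `lambda_j` is the gene's
   non-detection rate. The posterior probability `d_ij` that entry
   *(i, j)* came from the Gamma component is its non-detection
   probability; entries with `d_ij < t` (default `t = 0.5`) count as
   confidently measured.

2. **Robust correlation and covariance.** For each gene pair, the
   correlation `r` is the pairwise-complete Pearson coefficient over the
   cells in which *both* genes are confident (pairs with fewer than 10
   such cells fall back to the ordinary Pearson coefficient). The
   covariance estimate is `S = sigma_hat_j1 sigma_hat_j2 r`, with
   `sigma_hat` the Normal-component standard deviations, repaired to
   positive semidefinite by `Sp = S + |min(0, tau)| I` (`tau` the smallest
   eigenvalue).

3. **Weighted graphical lasso.** The concentration matrix is estimated by

   ```
   Theta_hat = argmax_{Theta > 0}  logdet(Theta) - tr(Sp Theta)
                                   - lambda * sum_{j1 != j2} (1 - |r_j1j2|) |theta_j1j2|
   ```

   so strongly co-expressed pairs are penalized less. An absent edge
   (`theta_j1j2 = 0`) means the two genes are conditionally independent
   given all others. `lambda` is chosen by BIC
   (`n tr(Sp Theta) - n logdet(Theta) + m log n`, `m` = edge count) or by
   a target sparsity level (e.g. at most 5% of gene pairs).

The package also ships the companion simulation framework (power-law and
hub ground-truth networks, partial-correlation sampling, multivariate
normal expression, dropout thinning with `p_ij = exp(-rho X0_ij^2)`) and
evaluation tools (AUPRC/AUROC against a known network, resampling
robustness scores, differential-edge comparisons between conditions).

## Worked example

Simulate a 50-gene power-law network with dropout, run the full method,
and score it against the ground truth:

```r
library(scnet)

sim <- simulate_dataset(p = 50, n = 300, topology = "power_law",
                        rho = 0.10, seed = 11)
sim
#> Synthetic dataset: 300 cells x 50 genes (power_law topology, 54 true edges, rho = 0.1, 63.9% zeros)

fit <- infer_network(sim$X, selection = "sparsity",
                     max_edge_fraction = 0.05, seed = 11)
fit$estimate
#> Sparse network estimate: 50 genes, 61 edges (lambda = 1, adaptive weights)

pr_roc_from_path(fit$path, sim$truth)
#> Curve (lambda_path): AUPRC = 0.1142

baseline <- glasso_path(cov(sim$X), seq(1, 0.05, by = -0.05))
pr_roc_from_path(baseline, sim$truth)$auprc
#> [1] 0.04573454
```

At 64% zeros the detection-aware estimator more than doubles the path
AUPRC of the generic graphical lasso on the same data (0.114 vs 0.046;
the all-edges prevalence is 54/1225 = 0.044). `fit$estimate$partial_corr`
holds the partial correlations, `gene_modules()` cuts them into modules,
and `run_pipeline(pipeline_config(...))` runs the same stages from a raw
counts file and writes TSV/JSON artifacts.

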