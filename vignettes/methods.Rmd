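---
title: "Detection-aware inference of sparse single-cell co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection-aware inference of sparse single-cell co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

# The problem

Single-cell RNA-seq measures expression in individual cells, but the
capture efficiency per cell is low: a gene that is genuinely expressed is
frequently recorded as a zero or a spuriously low count (dropout). For
co-expression analysis this is fatal to naive estimators — a pair of genes
with 60–80% zeros each can show almost any Pearson correlation depending
on how the zeros happen to align, and graphical models built on the sample
covariance inherit that noise. `scnet` treats the measurement question
("is this value trustworthy?") and the dependence question ("are these
genes conditionally dependent?") as separate stages.

All matrices are cells × genes. Counts are normalized so every cell has
the same library size M (default: the median library size; a constant such
as 1e5 may be supplied instead), then log-transformed twice: `Y =
log10(C + 1.01)` for mixture fitting — the extra 0.01 keeps zero counts
strictly positive, inside the Gamma support — and `X = log10(C + 1)` for
correlation and network estimation.

# Stage 1: the dropout mixture

Per gene, the log expression across cells is modeled as
$$f_j(y) = \lambda_j\,\mathrm{Gamma}(y;\alpha_j,\beta_j) +
          (1-\lambda_j)\,\mathrm{Normal}(y;\mu_j,\sigma_j),$$
with $\lambda_j$ the gene's non-detection rate. The EM fit
(`fit_gamma_normal()`) uses:

* **Initialization** by a median split: $\lambda^0$ is the fraction of
  values at or below the median, the Gamma component is moment-matched on
  the lower half and the Normal on the upper half. This mirrors the
  low/high bimodality the model targets and needs no randomness.
* **M step**: the mixing weight and Normal moments are closed-form; the
  Gamma parameters are re-estimated by responsibility-weighted maximum
  likelihood (a Newton solve of the digamma stationarity equation). This
  is a true M step, so the observed-data log-likelihood is non-decreasing
  across iterations — a property the test suite asserts with 1e-8 slack.
  A faster responsibility-weighted moment-matching step is available
  (`gamma_method = "moment"`), but it is not an ascent step and can let
  the likelihood dip slightly, so it is not the default.
* **Convergence**: relative log-likelihood change below `tol = 1e-6`,
  at most 100 iterations; failed iterations restart from a seeded
  perturbation of the initializer (at most 3 restarts).
* **Floors**: $\sigma \ge 10^{-4}$; $\lambda$ clipped to
  $[10^{-6}, 1-10^{-6}]$ during iteration; $\alpha,\beta$ capped at
  $10^4$ *jointly* — both are scaled by the same factor, so the component
  mean $\alpha/\beta$ is preserved. The joint cap matters: after
  library-size normalization all dropout zeros of a gene map to one
  identical log value, the weighted variance of the Gamma component
  collapses toward zero, and independent caps would silently recenter the
  component at mean 1 and destroy the fit.
* **Degenerate genes** (fewer than 20 distinct values, or standard
  deviation below 1e-6) skip EM: $\lambda = 0$ and $(\mu,\sigma)$ are the
  sample moments, so such genes are never masked. Highly filtered inputs
  make this path rare.
* **Identifiability guard**: a Gamma with a large shape parameter can
  mimic the Normal component, so unimodal genes admit a spurious
  two-component solution with $\lambda$ far from 0 at essentially the
  same likelihood. If the fitted Gamma mean exceeds $\mu - \sigma$, the
  components are not separated — there is no distinct low mode to call
  dropout — and the gene is reported with $\lambda = 0$. On genuine
  dropout the Gamma mean sits near the zero-count log value
  ($\approx 0.004$) while $\mu - \sigma$ is typically above 1, so the
  guard never triggers there.

The non-detection probability of an entry is the posterior weight of the
Gamma component, evaluated in log space; entries with $d_{ij} < t$
(default $t = 0.5$) are confident. The threshold matters little in
practice because $d$ is strongly bimodal; $t = 1$ disables masking
entirely and reduces the whole method to a Pearson-covariance analysis,
which the tests use as a consistency check.

# Stage 2: robust correlation and covariance

The robust correlation of a gene pair is the Pearson coefficient computed
over the pair's *complete* cells — those confident in both genes — with
the means and sum-of-squares taken over that same complete set (the
pairwise-complete Pearson coefficient). The definition leaves one choice
open: where to center. Centering at the full-sample gene means instead
(available as `center = "full"`) looks closer to one printed form of the
estimator, but is not what "pairwise-complete Pearson" means, and it
fails in exactly the regime the method is for: with substantial dropout
the complete cells are the high-expression cells, the full-sample means
are dragged down by the masked zeros, and every pair's centered products
become predominantly positive — on simulated data with ~70% zeros the
full-centered estimate is pushed toward +1 everywhere (RMSE to the true
correlation ≈ 0.77, against ≈ 0.22 for complete-set centering, which also
beats the plain Pearson's ≈ 0.27). Complete-set centering is therefore
the default. Both variants satisfy $|r| \le 1$ by Cauchy–Schwarz, since
numerator and denominators run over the same cell set.

Pairs with fewer than `min_pairs = 10` complete cells carry too little
information and fall back to the full-sample Pearson coefficient
(recorded in the `fallback` matrix; the penalty weights below use the
reported `r` whatever its provenance).

The covariance estimate rescales correlations by the Normal-component
standard deviations, $S_{j_1 j_2} = \hat\sigma_{j_1} \hat\sigma_{j_2}
r_{j_1 j_2}$ (degenerate genes use the sample standard deviation of X).
$S$ need not be positive semidefinite, so the smallest eigenvalue
$\tau$ is computed and $S_p = S + |\min(0, \tau)| I$ is passed on. The
shift leaves the off-diagonal structure untouched; when $\tau < 0$ the
smallest eigenvalue of $S_p$ is exactly 0, which the solver tolerates
because off-diagonal penalties keep the objective bounded.

# Stage 3: the weighted graphical lasso

The network is the support of
$$\hat\Theta = \arg\max_{\Theta \succ 0}\;
  \log\det\Theta - \mathrm{tr}(S_p\Theta)
  - \lambda \sum_{j_1 \ne j_2} (1-|r_{j_1 j_2}|)\,|\theta_{j_1 j_2}|,$$
an L1-penalized Gaussian log-likelihood whose per-edge weights
$1-|r|$ relax the penalty on strongly co-expressed pairs. The diagonal is
never penalized. Constant weights recover the ordinary graphical lasso;
the package exposes this as `glasso()` together with the covariance
variants used as baselines (sample covariance; robust covariance with
constant weights; sample covariance after dropping cells with more than
70% zeros).

The solver (`src/wglasso.cpp`) is block coordinate descent over columns
of the working covariance — each column update is a lasso solved by
coordinate descent, warm-started across sweeps and across the λ path.
Convergence is declared when the largest working-covariance update falls
below `tol` times the mean absolute off-diagonal of $S_p$ (`tol = 1e-4`,
`max_iter = 100` sweeps by default; tests use tighter tolerances where
they compare against references). Exact zeros come from the lasso
soft-threshold; entries are declared edges when the symmetrized
$|\hat\theta|$ exceeds `zero_tol = 1e-8`. The test suite cross-checks the
solver against an independently written ADMM solver (different algorithm,
different code path) to 1e-4 elementwise, and against the closed-form
2×2 solution (the inverse of the soft-thresholded covariance) to 1e-6.

λ selection offers two rules. The BIC,
$n\,\mathrm{tr}(S_p\hat\Theta) - n\log\det\hat\Theta + m\log n$, counts
each unordered edge once in $m$; ties prefer the larger λ (sparser
model). The sparsity rule takes the smallest grid value whose network
stays within `floor(fraction * p(p-1)/2)` edges — with 500 genes and a 5%
budget that is 6237 edges, with 1000 genes and 1% it is 4995 — and falls
back to the sparsest network with a warning when nothing qualifies. The
default grid is $\{1, 0.95, \ldots, 0.05\}$; denser or lower grids are a
user choice. Gene modules come from complete-linkage hierarchical
clustering of $1 - |\text{partial correlation}|$ cut at height 0.85
(linkage is configurable; the cut height is the scale at which
\"module\" stops meaning $|pcor| > 0.15$ somewhere in the cluster).

# The simulation framework

The generator produces data with a known network so that inference can be
scored. A block-diagonal connectivity matrix (blocks of ~50 genes by
default) gets one of two within-block topologies: **power-law**, with
node degrees drawn from $a_k = k^{-\alpha}/\zeta(\alpha)$ (truncated at
the block size, resampled until graphical, realized and then
degree-preservingly rewired), or **hub**, where a few hub nodes connect
to disjoint shares of the remaining block genes. A configurable number of
between-block edges is added uniformly at random, and every edge receives
a ±1 sign equiprobably — the generator needs a sign convention and the
ground truth only constrains magnitudes.

Edge partial correlations are drawn uniformly from ±[0.4, 0.7], the
matrix is PD-repaired by the same diagonal-shift rule as $S_p$, and the
implied correlation matrix is obtained by building the unit-diagonal
precision-like matrix $K$ ($K_{j_1 j_2} = -\Lambda_{j_1 j_2}$), shifting
its diagonal by $|\tau_K| + 0.01$ if needed, inverting, and standardizing
— the standard partial-correlation identity run backwards. Cells are then
i.i.d. multivariate normal on the log scale with per-gene means from
Uniform(0.5, 3.5) and standard deviations from Uniform(0.3, 1.0) —
stand-in ranges typical of the highly expressed genes one would keep
after filtering; `sample_gene_params(source = "from_matrix")` instead
estimates $(\mu, \sigma)$ from any real matrix via the stage-1 mixture.
Negative draws are floored at 0, since observed log matrices are
non-negative.

Dropout thinning zeroes entry $(i,j)$ with probability
$p_{ij} = \exp(-\rho\,X^0_{ij}{}^2)$: zero-expression entries always drop
out and highly expressed ones rarely do. The study grid is
$\rho \in \{0.07, 0.10, 0.13, 0.16\}$; note that **larger ρ means fewer
zeros** — at $X^0 = 3$, $\rho = 0.07$ drops 53% of entries and
$\rho = 0.16$ only 24% — so $\rho = 0.07$ is the hardest condition. Every
stage consumes a sub-seed derived from the dataset seed, so a seed fixes
the dataset bit-for-bit.

What the generator does *not* emulate: count-level noise (data are
Gaussian on the log scale by construction), library-size variation,
batch effects, cell subpopulations, or doublets. Passing the simulation
benchmarks therefore shows that the estimator chain recovers conditional
dependence under dropout of the modeled form, not that it is robust to
every artifact of real protocols.

# Evaluation conventions

Score-based PR/ROC curves sweep every distinct absolute score over the
upper triangle, grouping ties at one threshold, and integrate by
trapezoid. Curves along a λ path have one point per non-empty network
(empty networks have no defined precision and are skipped), are sorted by
recall, and are integrated from recall 0 at the sparsest non-empty
network's precision up to the largest recall achieved — a *path* AUPRC
that is not interpolated to recall 1 and therefore not numerically
comparable to a score-based AUPRC; comparisons between path methods use
path areas on the identical grid.

The robustness score of $L$ networks inferred from repeated half-cell
subsamples counts, for each edge that appears at all, how many of the
$L$ networks contain it:
$$RS = \frac{\sum_{j_1<j_2}\sum_{l=1}^{L}(l-1)\,\mathbb{1}\{E^s_{j_1 j_2}=l\}}
            {(L-1)\sum_{j_1<j_2}\mathbb{1}\{E^s_{j_1 j_2}>0\}},$$
so $RS = 1$ for identical networks and $RS = 0$ when no edge recurs.
Subsampling is without replacement, default $n_r = n/2$ and $L = 10$.
Differential edges between two conditions require a correlation change
*strictly* greater than `min_delta = 0.5`.

# Problem sizes used by the tests

The test suite and acceptance checks run at desk scale, chosen to exercise
every code path while keeping the default run fast: solver
cross-validation at $p \in \{5, 10\}$ over 20 instances; mixture recovery
at $n = 5000$ over 10 seeds; the simulation benchmark at $p = 100$
power-law networks, $n = 300$ cells, 10 replicates per condition, with
$\rho \in \{0.07, 0.10, 0.16\}$. On that benchmark the detection-aware
estimator's mean path AUPRC exceeds the generic graphical lasso's, and
every method improves from the sparsest ($\rho = 0.07$) to the densest
($\rho = 0.16$) condition — orderings of replicate means, not fixed
numbers, as befits a stochastic benchmark.

# Known limitations

* The Gaussian copula is assumed on the log scale; heavy-tailed or
  multimodal expression within a cell type violates it and the mixture
  will misattribute the extra mode.
* The robust correlation needs enough doubly confident cells; at extreme
  sparsity most pairs hit the Pearson fallback and the method degrades
  toward the baseline it improves on.
* Edges are statistical dependencies, not causal or directed regulatory
  relationships.
* The BIC treats the penalized fit as if it were an unpenalized MLE on
  the selected support; for very small $n$ the sparsity-target rule is
  the more stable choice.
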