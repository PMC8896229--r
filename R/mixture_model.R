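# Per-gene Gamma-Normal mixture for dropout modeling.
#
# A gene's log expression Y across cells is modeled as
#   f(y) = lambda * Gamma(y; alpha, beta) + (1 - lambda) * Normal(y; mu, sigma)
# where the Gamma component captures non-detected (technically unreliable)
# values and the Normal component the actual expression level; lambda is the
# gene's non-detection rate.

# Numerical floors keeping EM away from boundary collapse
.MIX_SIGMA_MIN <- 1e-4
.MIX_AB_MIN <- 1e-4
.MIX_AB_MAX <- 1e4
.MIX_LAMBDA_EPS <- 1e-6

#' Fit a Gamma-Normal mixture to one gene's log expression
#'
#' Fits the two-component mixture by expectation-maximization. The E step is
#' computed in log space; the M step re-estimates the mixing weight, the
#' Normal moments, and the Gamma parameters (responsibility-weighted moment
#' matching by default, or weighted maximum likelihood via a Newton step on
#' the digamma equation with `gamma_method = "mle"`).
#'
#' Genes with fewer than 20 distinct values or (near-)zero variance take a
#' degenerate path: `lambda = 0`, `(mu, sigma)` set to the sample moments,
#' and every cell is treated as confidently measured downstream.
#'
#' @param y Numeric vector of one gene's log-scale expression across cells
#'   (matrix Y, pseudo-count 1.01, so strictly positive).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the relative log-likelihood change.
#' @param seed Seed for the (rarely needed) perturbed restarts.
#' @param gamma_method `"mle"` (default) or `"moment"` for the Gamma M step.
#'   The weighted maximum-likelihood step is a true EM M step, so the
#'   observed-data log-likelihood is non-decreasing across iterations;
#'   moment matching is faster per iteration but is not an ascent step.
#' @return An object of class `"gene_mixture"`: list with `lambda`, `alpha`,
#'   `beta`, `mu`, `sigma`, `converged`, `loglik`, `degenerate`, `n_iter`.
#' @export
fit_gamma_normal <- function(y, max_iter = 100L, tol = 1e-6, seed = NULL,
                             gamma_method = c("mle", "moment")) {
  gamma_method <- match.arg(gamma_method)
  if (length(y) == 0L) stopf("empty expression vector")
  if (!all(is.finite(y))) stopf("non-finite expression values")

  if (length(unique(y)) < 20L || sd(y) < 1e-6) {
    return(structure(list(
      lambda = 0, alpha = NA_real_, beta = NA_real_,
      mu = mean(y), sigma = max(sd(y), 0),
      converged = TRUE, loglik = NA_real_, degenerate = TRUE, n_iter = 0L
    ), class = "gene_mixture"))
  }

  fit <- NULL
  for (attempt in 0:3) {
    init <- mixture_init(y)
    if (attempt > 0) {
      init <- with_seed(if (is.null(seed)) NULL else seed + attempt, {
        within(init, {
          lambda <- min(max(lambda * runif(1, 0.5, 1.5), 0.05), 0.95)
          alpha <- alpha * runif(1, 0.5, 2)
          beta <- beta * runif(1, 0.5, 2)
          mu <- mu + rnorm(1, 0, 0.2 * sigma)
        })
      })
    }
    fit <- tryCatch(mixture_em(y, init, max_iter, tol, gamma_method),
                    error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(
      lambda = 0, alpha = NA_real_, beta = NA_real_,
      mu = mean(y), sigma = sd(y),
      converged = FALSE, loglik = NA_real_, degenerate = TRUE, n_iter = 0L
    ), class = "gene_mixture"))
  }
  # Identifiability guard: the dropout component must sit below the
  # expression component. A Gamma with large shape can mimic the Normal,
  # splitting unimodal data into two coincident components; when the fitted
  # Gamma mean reaches into the Normal bulk (above mu - sigma), there is no
  # separated low mode, so the gene is treated as having no detectable
  # dropout component.
  fit$separated <- (fit$alpha / fit$beta) <= (fit$mu - fit$sigma)
  if (!fit$separated) {
    fit$lambda <- 0
    fit$mu <- mean(y)
    fit$sigma <- sd(y)
  }
  structure(fit, class = "gene_mixture")
}

# Initialization: split at the median; Gamma moment-matched on the lower
# half, Normal on the upper half.
mixture_init <- function(y) {
  med <- median(y)
  lo <- y[y <= med]
  hi <- y[y > med]
  if (length(hi) < 2L) hi <- y
  m_lo <- mean(lo); v_lo <- max(var(lo), 1e-6)
  list(
    lambda = min(max(mean(y <= med), .MIX_LAMBDA_EPS), 1 - .MIX_LAMBDA_EPS),
    alpha = min(max(m_lo^2 / v_lo, .MIX_AB_MIN), .MIX_AB_MAX),
    beta = min(max(m_lo / v_lo, .MIX_AB_MIN), .MIX_AB_MAX),
    mu = mean(hi),
    sigma = max(sd(hi), .MIX_SIGMA_MIN)
  )
}

mixture_em <- function(y, par, max_iter, tol, gamma_method) {
  n <- length(y)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # E step (log space)
    lg <- log(par$lambda) + dgamma(y, shape = par$alpha, rate = par$beta, log = TRUE)
    ln <- log1p(-par$lambda) + dnorm(y, par$mu, par$sigma, log = TRUE)
    mx <- pmax(lg, ln)
    ll_i <- mx + log(exp(lg - mx) + exp(ln - mx))
    ll <- sum(ll_i)
    if (!is.finite(ll)) stopf("non-finite log-likelihood in EM")
    trace <- c(trace, ll)
    g <- exp(lg - ll_i) # responsibility of the Gamma component

    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll

    # M step
    sg <- sum(g)
    par$lambda <- min(max(sg / n, .MIX_LAMBDA_EPS), 1 - .MIX_LAMBDA_EPS)
    if (sg > 1e-8) {
      mg <- sum(g * y) / sg
      vg <- max(sum(g * (y - mg)^2) / sg, 1e-10)
      if (gamma_method == "moment") {
        par$alpha <- mg^2 / vg
        par$beta <- mg / vg
      } else {
        par$alpha <- gamma_mle_shape(sum(g * log(y)) / sg, mg, par$alpha)
        par$beta <- par$alpha / mg
      }
      # cap jointly so the component mean alpha/beta survives (the dropout
      # mass can be a near-point spike, driving both parameters upward)
      sc <- max(1, par$alpha / .MIX_AB_MAX, par$beta / .MIX_AB_MAX)
      par$alpha <- max(par$alpha / sc, .MIX_AB_MIN)
      par$beta <- max(par$beta / sc, .MIX_AB_MIN)
    }
    w <- 1 - g
    sw <- sum(w)
    if (sw > 1e-8) {
      par$mu <- sum(w * y) / sw
      par$sigma <- max(sqrt(sum(w * (y - par$mu)^2) / sw), .MIX_SIGMA_MIN)
    }
    if (par$sigma <= 0 || par$alpha <= 0 || par$beta <= 0) {
      stopf("parameter collapsed during EM")
    }
  }
  list(lambda = par$lambda, alpha = par$alpha, beta = par$beta,
       mu = par$mu, sigma = par$sigma, converged = converged,
       loglik = ll_old, degenerate = FALSE, n_iter = iter,
       loglik_trace = trace)
}

# Weighted Gamma MLE for the shape: solve log(a) - digamma(a) = log(mbar) - lbar
# by Newton iterations, started from the current shape.
gamma_mle_shape <- function(lbar, mbar, a0) {
  s <- log(mbar) - lbar
  if (!is.finite(s) || s <= 0) return(a0)
  a <- max(a0, (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s))
  for (i in 1:25) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    a_new <- a - f / fp
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) {
      a <- a_new
      break
    }
    a <- a_new
  }
  a
}

#' @export
print.gene_mixture <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Gamma-Normal mixture (degenerate): mu=%.4g sigma=%.4g\n",
                x$mu, x$sigma))
  } else {
    cat(sprintf(
      "Gamma-Normal mixture: lambda=%.3f alpha=%.3f beta=%.3f mu=%.3f sigma=%.3f (%s, loglik %.2f)\n",
      x$lambda, x$alpha, x$beta, x$mu, x$sigma,
      if (x$converged) sprintf("converged in %d iter", x$n_iter) else "not converged",
      x$loglik))
  }
  invisible(x)
}

#' Posterior non-detection probability
#'
#' Probability that an observed value arises from the Gamma (unreliable)
#' component of the fitted mixture:
#' `d = lambda * Gamma(y) / (lambda * Gamma(y) + (1 - lambda) * Normal(y))`,
#' evaluated in log space. Degenerate fits return 0 for every cell.
#'
#' @param y Numeric vector of log-scale expression values.
#' @param params A `"gene_mixture"` fit.
#' @return Vector of non-detection probabilities in `[0, 1)`.
#' @export
nondetection_probability <- function(y, params) {
  stopifnot(inherits(params, "gene_mixture"))
  if (params$degenerate) return(rep(0, length(y)))
  if (params$lambda <= 0) return(rep(0, length(y)))
  lg <- log(params$lambda) +
    dgamma(y, shape = params$alpha, rate = params$beta, log = TRUE)
  ln <- log1p(-params$lambda) + dnorm(y, params$mu, params$sigma, log = TRUE)
  bad <- !is.finite(pmax(lg, ln))
  if (any(bad)) {
    stopf("non-finite mixture density at value(s) %s",
          paste(head(signif(y[bad], 4), 5), collapse = ", "))
  }
  d <- 1 / (1 + exp(ln - lg))
  # both densities can underflow to -Inf together only if bad above
  d[is.nan(d)] <- 0
  # keep d strictly below 1 (the posterior ratio never reaches 1; only
  # floating-point underflow of the Normal density produces an exact 1)
  pmin(d, 1 - 1e-12)
}

#' Fit the mixture for every gene of a matrix
#'
#' @param Y Cells x genes log matrix (pseudo-count 1.01).
#' @param max_iter,tol,seed,gamma_method Passed to [fit_gamma_normal()]; the
#'   per-gene restart seed is derived from `seed` and the gene index.
#' @return List of `"gene_mixture"` fits, one per gene (named if `Y` has
#'   column names).
#' @export
fit_mixtures <- function(Y, max_iter = 100L, tol = 1e-6, seed = NULL,
                         gamma_method = "mle") {
  fits <- lapply(seq_len(ncol(Y)), function(j) {
    fit_gamma_normal(Y[, j], max_iter = max_iter, tol = tol,
                     seed = if (is.null(seed)) NULL else seed + j,
                     gamma_method = gamma_method)
  })
  names(fits) <- colnames(Y)
  fits
}

#' Non-detection probabilities and confidence mask for a matrix
#'
#' Applies [nondetection_probability()] gene by gene and flags entries with
#' `d < t` as confidently measured. Degenerate genes are fully confident.
#'
#' @param Y Cells x genes log matrix the mixtures were fitted on.
#' @param fits List of per-gene `"gene_mixture"` fits (from [fit_mixtures()]).
#' @param t Confidence threshold on `d`; default 0.5.
#' @return An object of class `"detection_mask"`: list with `d` (matrix of
#'   non-detection probabilities), `confident` (logical matrix `d < t`) and
#'   `t`.
#' @export
detection_mask <- function(Y, fits, t = 0.5) {
  if (length(fits) != ncol(Y)) {
    stopf("got %d mixture fits for %d genes", length(fits), ncol(Y))
  }
  d <- vapply(seq_len(ncol(Y)), function(j) nondetection_probability(Y[, j], fits[[j]]),
              numeric(nrow(Y)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(Y))
  dimnames(d) <- dimnames(Y)
  structure(list(d = d, confident = d < t, t = t), class = "detection_mask")
}

#' Write a table of mixture parameters
#'
#' @param fits List of `"gene_mixture"` fits.
#' @param path Output TSV path.
#' @return The table (invisibly) with columns gene, lambda, alpha, beta, mu,
#'   sigma, converged, loglik.
#' @export
write_mixture_params <- function(fits, path) {
  tab <- data.frame(
    gene = if (is.null(names(fits))) seq_along(fits) else names(fits),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    mu = vapply(fits, `[[`, numeric(1), "mu"),
    sigma = vapply(fits, `[[`, numeric(1), "sigma"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik")
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
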