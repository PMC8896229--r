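# Scoring inferred networks against ground truth, resampling robustness,
# and differential-network comparisons.

#' Precision-recall and ROC curves from an edge-score matrix
#'
#' Treats the absolute upper-triangle scores as a ranking of gene pairs and
#' sweeps all distinct thresholds (tied scores grouped at one threshold).
#' Areas are trapezoidal. Constant scores give a single operating point and
#' reduce to AUPRC = prevalence, AUROC = 0.5.
#'
#' @param score_matrix Symmetric score matrix (e.g. correlations or
#'   concentration-matrix magnitudes).
#' @param truth_adjacency Symmetric logical (or 0/1) ground-truth adjacency.
#' @return An object of class `"curve_result"`: list with `pr` (recall,
#'   precision points), `roc` (fpr, tpr points), `auprc`, `auroc`,
#'   `mode = "score_threshold"`.
#' @export
pr_roc_from_scores <- function(score_matrix, truth_adjacency) {
  check_square_symmetric(score_matrix, "score_matrix")
  ut <- upper.tri(score_matrix)
  s <- abs(score_matrix[ut])
  y <- as.logical(truth_adjacency[ut])
  P <- sum(y); N <- sum(!y)
  if (P == 0L || N == 0L) {
    stopf("ground truth must contain both edges and non-edges (got %d of %d positive)",
          P, length(y))
  }
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  # group ties: cumulative counts at the last index of each distinct score
  last <- which(diff(s) != 0)
  cut <- c(last, length(s))
  tp <- cumsum(y)[cut]
  fp <- cumsum(!y)[cut]
  recall <- tp / P
  precision <- tp / (tp + fp)
  tpr <- recall
  fpr <- fp / N

  auprc <- trapezoid_area(c(0, recall), c(precision[1], precision))
  auroc <- trapezoid_area(c(0, fpr, 1), c(0, tpr, 1))
  structure(list(
    pr = list(recall = recall, precision = precision),
    roc = list(fpr = fpr, tpr = tpr),
    auprc = auprc, auroc = auroc, mode = "score_threshold"
  ), class = "curve_result")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Precision-recall curve along a lambda path
#'
#' One (recall, precision) point per fitted network on the path; lambdas
#' with empty networks have no defined precision and are skipped. Points
#' are sorted by recall and integrated by trapezoid from recall 0 (at the
#' precision of the sparsest non-empty network) up to the largest recall
#' achieved — a path area, not interpolated to recall 1.
#'
#' @param path A `"lambda_path"` (or list of adjacency matrices).
#' @param truth Symmetric logical ground-truth adjacency.
#' @return A `"curve_result"` with `mode = "lambda_path"` (no ROC part).
#' @export
pr_roc_from_path <- function(path, truth) {
  nets <- if (inherits(path, "lambda_path")) {
    lapply(path$estimates, `[[`, "adjacency")
  } else {
    path
  }
  ut <- upper.tri(truth)
  y <- as.logical(truth[ut])
  P <- sum(y)
  if (P == 0L) stopf("ground truth has no edges")
  pts <- lapply(nets, function(A) {
    pred <- as.logical(A[ut])
    npred <- sum(pred)
    if (npred == 0L) return(NULL) # precision undefined on empty networks
    tp <- sum(pred & y)
    c(recall = tp / P, precision = tp / npred)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L) {
    stopf("all networks on the path are empty; no precision-recall point defined")
  }
  o <- order(pts[, "recall"], pts[, "precision"])
  recall <- pts[o, "recall"]; precision <- pts[o, "precision"]
  auprc <- trapezoid_area(c(0, recall), c(precision[1], precision))
  structure(list(
    pr = list(recall = recall, precision = precision),
    roc = NULL, auprc = auprc, auroc = NA_real_, mode = "lambda_path"
  ), class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf("Curve (%s): AUPRC = %.4f%s\n", x$mode, x$auprc,
              if (is.na(x$auroc)) "" else sprintf(", AUROC = %.4f", x$auroc)))
  invisible(x)
}

#' Robustness score of a set of resampled networks
#'
#' For L adjacency matrices inferred from repeated cell subsamples, let
#' `Es[j1, j2]` count how many of the L networks contain the edge. The
#' score is
#' `RS = sum_{pairs} sum_l (l - 1) I(Es = l) / ((L - 1) * sum_{pairs} I(Es > 0))`,
#' i.e. 1 when all networks are identical and 0 when no edge recurs.
#'
#' @param networks List of `L >= 2` adjacency matrices over the same genes.
#' @return An object of class `"robustness_result"`: list with `RS`, `L`,
#'   and `Es` (edge recurrence counts).
#' @export
robustness_score <- function(networks) {
  L <- length(networks)
  if (L < 2L) stopf("need at least 2 networks")
  dims <- vapply(networks, dim, integer(2))
  if (any(dims != dims[, 1])) stopf("networks must share the same gene set")
  Es <- Reduce(`+`, lapply(networks, function(A) {
    A <- A != 0
    diag(A) <- FALSE
    A * 1L
  }))
  ut <- Es[upper.tri(Es)]
  denom <- sum(ut > 0)
  if (denom == 0L) stopf("no edge appears in any network; robustness undefined")
  num <- sum((ut - 1L)[ut > 0])
  structure(list(RS = num / ((L - 1) * denom), L = L, Es = Es),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Robustness score over %d networks: RS = %.4f\n", x$L, x$RS))
  invisible(x)
}

#' Robustness of a network-inference method under cell resampling
#'
#' Draws `L` subsamples of `n_r` cells without replacement, runs the full
#' inference pipeline on each and scores the agreement of the resulting
#' networks with [robustness_score()].
#'
#' @param X_raw Cells x genes raw count matrix.
#' @param method A function `(X_raw_subsample) -> adjacency matrix`; see
#'   [run_pipeline()] for the standard pipeline, or supply a closure around
#'   any baseline.
#' @param n_r Cells per subsample (default: half of the cells).
#' @param L Number of subsamples (default 10).
#' @param seed RNG seed; subsample `l` uses a sub-seed derived from it.
#' @return A `"robustness_result"` with the subsampled networks attached as
#'   `networks`.
#' @export
resample_robustness <- function(X_raw, method, n_r = NULL, L = 10L, seed = 1L) {
  n <- nrow(X_raw)
  if (is.null(n_r)) n_r <- floor(n / 2)
  stopifnot(n_r >= 1, n_r <= n, L >= 2)
  nets <- lapply(seq_len(L), function(l) {
    idx <- with_seed(derive_seed(seed, paste0("resample", l)),
                     sort(sample.int(n, n_r)))
    method(X_raw[idx, , drop = FALSE])
  })
  res <- robustness_score(nets)
  res$networks <- nets
  res$n_r <- n_r
  res
}

#' Differential edges between two conditions
#'
#' Gene pairs whose correlation changes by strictly more than `min_delta`
#' between the two conditions, partitioned by presence pattern (edge only
#' in network 1, only in network 2, in both, in neither).
#'
#' @param net1,net2 Adjacency matrices of the two conditions.
#' @param r1,r2 Correlation matrices of the two conditions.
#' @param min_delta Minimum absolute correlation change, exclusive
#'   (default 0.5).
#' @return A data frame with columns gene1, gene2, r1, r2, delta,
#'   present_in (`"net1"`, `"net2"`, `"both"`, `"neither"`).
#' @export
differential_edges <- function(net1, net2, r1, r2, min_delta = 0.5) {
  p <- nrow(r1)
  idx <- upper_tri_pairs(p)
  delta <- r1[idx] - r2[idx]
  keep <- abs(delta) > min_delta
  idx <- idx[keep, , drop = FALSE]
  in1 <- net1[idx] != 0
  in2 <- net2[idx] != 0
  genes <- colnames(r1)
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  data.frame(
    gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
    r1 = r1[idx], r2 = r2[idx], delta = delta[keep],
    present_in = ifelse(in1 & in2, "both",
                 ifelse(in1, "net1", ifelse(in2, "net2", "neither")))
  )
}

#' Per-gene degree changes between two networks
#'
#' @param net1,net2 Adjacency matrices over the same genes.
#' @return Named vector of signed degree differences (net2 minus net1).
#' @export
degree_changes <- function(net1, net2) {
  d1 <- rowSums(net1 != 0)
  d2 <- rowSums(net2 != 0)
  d2 - d1
}
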