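#' Read a single-cell expression count matrix
#'
#' Reads a dense CSV/TSV table or a Matrix Market triplet file into a cells
#' x genes count matrix. Dense tables are expected to carry row and column
#' names (first column / header row); Matrix Market files must be
#' accompanied by one-name-per-line gene and cell files.
#'
#' @param path Path to the matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`.
#' @param orientation `"cells_by_genes"` (default) if rows are cells, or
#'   `"genes_by_cells"` if the file stores genes in rows (transposed on
#'   read; all downstream functions use the cells x genes convention).
#' @param gene_file,cell_file For `format = "mtx"`: text files with one
#'   gene / cell identifier per line, in matrix order.
#' @return A numeric cells x genes matrix with cell identifiers as row
#'   names and gene identifiers as column names.
#' @export
read_expression <- function(path,
                            format = c("csv", "tsv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)

  if (format == "mtx") {
    if (is.null(gene_file) || is.null(cell_file)) {
      stopf("mtx format requires `gene_file` and `cell_file`")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (orientation == "genes_by_cells") m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stopf("mtx dimensions (%d x %d) do not match %d cells x %d genes",
            nrow(m), ncol(m), length(cells), length(genes))
    }
    dimnames(m) <- list(cells, genes)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      read.table(path, sep = sep, header = TRUE, row.names = 1,
                 check.names = FALSE),
      error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e))
    )
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))), arr.ind = TRUE)
      stopf("non-numeric entry near line %d of %s",
            if (length(bad)) bad[1, 1] + 1L else NA_integer_, path)
    }
    if (orientation == "genes_by_cells") m <- t(m)
  }

  validate_counts(m)
  m
}

validate_counts <- function(m) {
  if (!all(is.finite(m))) stopf("count matrix contains non-finite entries")
  if (any(m < 0)) stopf("count matrix contains negative entries")
  if (any(abs(m - round(m)) > 1e-8)) stopf("count matrix contains non-integer entries")
  if (nrow(m) < 1L || ncol(m) < 2L) stopf("need at least 1 cell and 2 genes")
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    stopf("duplicate gene identifiers: %s",
          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  invisible(m)
}

#' Library-size normalization
#'
#' Rescales every cell to a common library size M, so that all rows of the
#' returned matrix sum to M: `C[i, j] = raw[i, j] * M / lib[i]`.
#'
#' @param raw Cells x genes count matrix.
#' @param m_mode `"median"` (M = median library size, the default) or
#'   `"constant"` (M supplied via `m_value`, e.g. `1e5`).
#' @param m_value Target library size when `m_mode = "constant"`.
#' @return The normalized matrix, with the target size in attribute
#'   `"target_size"`.
#' @export
normalize_library_size <- function(raw, m_mode = c("median", "constant"),
                                   m_value = NULL) {
  m_mode <- match.arg(m_mode)
  lib <- rowSums(raw)
  if (any(lib <= 0)) {
    bad <- which(lib <= 0)
    stopf("cells with zero library size: %s (filter cells before normalizing)",
          paste(head(if (is.null(rownames(raw))) bad else rownames(raw)[bad], 10),
                collapse = ", "))
  }
  M <- switch(m_mode,
    median = median(lib),
    constant = {
      if (is.null(m_value)) stopf("m_mode = \"constant\" requires `m_value`")
      m_value
    }
  )
  C <- raw * (M / lib)
  attr(C, "target_size") <- M
  C
}

#' Log10 transformation with a pseudo-count
#'
#' `log10(C + pseudo_count)` elementwise. Two variants are used downstream:
#' `pseudo_count = 1.01` (matrix Y, on which the dropout mixture is fitted;
#' the extra 0.01 keeps the Gamma component off zero) and
#' `pseudo_count = 1` (matrix X, on which correlations are computed).
#'
#' @param C Normalized cells x genes matrix.
#' @param pseudo_count Pseudo-count added before the log, `1` or `1.01`.
#' @return The transformed matrix with attribute `"pseudo_count"`.
#' @export
log_transform <- function(C, pseudo_count = 1.01) {
  stopifnot(is.numeric(pseudo_count), length(pseudo_count) == 1L, pseudo_count >= 1)
  out <- log10(C + pseudo_count)
  attr(out, "pseudo_count") <- pseudo_count
  out
}

#' Filter genes by expression level or detection rate
#'
#' Keeps either the `k` genes with highest mean expression, or all genes
#' detected (nonzero) in at least a given fraction of cells. Ties in mean
#' expression are broken by original column order.
#'
#' @param m Cells x genes matrix.
#' @param rule `"top_k_by_mean_expression"` or `"min_detection_rate"`.
#' @param k Number of genes to keep (top-k rule).
#' @param rate Minimum detection rate in (0, 1] (detection rule, inclusive
#'   boundary).
#' @return List with `matrix` (filtered) and `kept` (original column indices).
#' @export
filter_genes <- function(m, rule = c("top_k_by_mean_expression", "min_detection_rate"),
                         k = NULL, rate = NULL) {
  rule <- match.arg(rule)
  if (rule == "top_k_by_mean_expression") {
    if (is.null(k)) stopf("top-k rule requires `k`")
    if (k > ncol(m)) stopf("k = %d exceeds the number of genes (%d)", k, ncol(m))
    mu <- colMeans(m)
    # order() is stable: equal means keep their input order
    kept <- sort(order(-mu)[seq_len(k)])
  } else {
    if (is.null(rate) || rate <= 0 || rate > 1) stopf("`rate` must be in (0, 1]")
    det <- colMeans(m > 0)
    kept <- which(det >= rate)
  }
  list(matrix = m[, kept, drop = FALSE], kept = kept)
}

#' Filter low-quality cells by zero proportion
#'
#' Removes cells whose fraction of zero counts is strictly greater than
#' `max_zero_proportion` (a cell at exactly the threshold is kept).
#'
#' @param m Cells x genes matrix.
#' @param max_zero_proportion Maximum tolerated zero fraction, in (0, 1].
#' @return List with `matrix` (filtered) and `kept` (original row indices).
#' @export
filter_cells <- function(m, max_zero_proportion = 0.7) {
  stopifnot(max_zero_proportion > 0, max_zero_proportion <= 1)
  zf <- rowMeans(m == 0)
  kept <- which(zf <= max_zero_proportion)
  if (length(kept) == 0L) stopf("all cells removed at zero-proportion threshold %g",
                                max_zero_proportion)
  list(matrix = m[kept, , drop = FALSE], kept = kept)
}

#' Write an expression matrix to a dense TSV file
#'
#' @param m Cells x genes matrix.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
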