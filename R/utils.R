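# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` means: use the current stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Derive a deterministic 31-bit sub-seed from a run seed and a stage label,
# so pipeline stages can be re-run independently of each other.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_square_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("`%s` must be a square matrix", name)
  }
  if (max(abs(m - t(m))) > tol) {
    stopf("`%s` is not symmetric (max asymmetry %.3g > %.3g)",
          name, max(abs(m - t(m))), tol)
  }
  invisible(TRUE)
}

upper_tri_pairs <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}
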