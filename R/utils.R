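# Internal helpers shared across modules.

#' @importFrom stats pchisq pnorm qnorm quantile rnorm runif sd var
#' @importFrom utils combn read.csv write.csv write.table
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stage seed from a master seed; keeps results < 2^31.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483587)
}

# Upper-triangle (i < j) linear indices of an n x n matrix, column-major.
upper_tri_idx <- function(n) which(upper.tri(matrix(0L, n, n)))

# Map upper-triangle linear indices back to (i, j) pairs with i < j.
idx_to_pairs <- function(idx, n) {
  j <- ((idx - 1L) %/% n) + 1L
  i <- ((idx - 1L) %% n) + 1L
  cbind(i = i, j = j)
}

pairs_to_idx <- function(pairs, n) {
  i <- pmin(pairs[, 1L], pairs[, 2L])
  j <- pmax(pairs[, 1L], pairs[, 2L])
  (j - 1L) * n + i
}

# Rebuild a full symmetric matrix (zero diagonal) from an upper-triangle
# vector laid out as upper_tri_idx(n).
sym_from_ut <- function(values, n) {
  m <- matrix(0, n, n)
  m[upper_tri_idx(n)] <- values
  m + t(m)
}

# Extract upper-triangle values of a symmetric matrix.
ut_values <- function(m) m[upper.tri(m)]

is_symmetric_zero_diag <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol && max(abs(diag(m))) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
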