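# Internal numerical helpers shared across modules.

# Squared Euclidean distances between rows of a and rows of b.
# Clamps tiny negatives from catastrophic cancellation to zero.
sqdist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k nearest rows of ref to each row of query (Euclidean).
# Ties broken deterministically by lowest reference index (order() is stable
# on the index for equal keys). self_block: matrix of (query_row, ref_row)
# pairs to exclude (used when query and ref overlap).
knn_index <- function(query, ref, k, exclude_self = FALSE) {
  if (k > nrow(ref) - as.integer(exclude_self))
    stop("k = ", k, " exceeds the number of available reference cells")
  d2 <- sqdist(query, ref)
  if (exclude_self) {
    if (nrow(query) != nrow(ref))
      stop("exclude_self requires query and ref to be the same set")
    diag(d2) <- Inf
  }
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

# Row-wise log-sum-exp of a matrix.
row_lse <- function(m) {
  mx <- apply(m, 1, max)
  fin <- is.finite(mx)
  out <- mx
  out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  out
}

# Fix eigen/SVD sign ambiguity: flip each column so that its
# largest-magnitude entry is positive. Applied jointly to scores and
# loadings when both are given.
fix_signs <- function(scores, loadings = NULL) {
  for (j in seq_len(ncol(scores))) {
    v <- if (is.null(loadings)) scores[, j] else loadings[, j]
    s <- sign(v[which.max(abs(v))])
    if (s < 0) {
      scores[, j] <- -scores[, j]
      if (!is.null(loadings)) loadings[, j] <- -loadings[, j]
    }
  }
  if (is.null(loadings)) scores else list(scores = scores, loadings = loadings)
}
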