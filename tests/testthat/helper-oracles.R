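# Independent brute-force oracles. These deliberately avoid the code paths
# they check: plain loops, enumeration and textbook formulas only.

# Upper-tail hypergeometric probability by direct pmf enumeration.
hyper_tail_oracle <- function(x, K, N, k) {
  if (x <= 0) return(1)
  i <- x:min(k, K)
  i <- i[(k - i) <= (N - K)]
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, k - i)) / choose(N, k)
}

# All-pairs k nearest neighbours by full distance sort.
knn_oracle <- function(query, ref, k) {
  t(apply(query, 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    order(d)[seq_len(k)]
  }))
}

# AUROC of a score for a binary label via the rank-sum identity.
auroc_oracle <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exact optimal transport cost with uniform marginals via the simplex
# method (pracma::linprog on the flattened coupling).
lp_transport_cost <- function(C) {
  n <- nrow(C); m <- ncol(C)
  cc <- as.vector(C)
  Aeq <- matrix(0, n + m, n * m)
  for (i in seq_len(n)) Aeq[i, (seq_len(m) - 1) * n + i] <- 1
  for (j in seq_len(m)) Aeq[n + j, (j - 1) * n + seq_len(n)] <- 1
  beq <- c(rep(1 / n, n), rep(1 / m, m))
  res <- pracma::linprog(cc, Aeq = Aeq, beq = beq, maxiter = 20000)
  res$fval
}

# Centred rolling mean with truncated edges, written as an explicit loop.
rollmean_oracle <- function(v, half) {
  n <- length(v)
  sapply(seq_len(n), function(i) mean(v[max(1, i - half):min(n, i + half)]))
}

# Brute-force Gaussian kernel density sum on arbitrary 3D points.
kde3_oracle <- function(points, h, at) {
  apply(at, 1, function(g) {
    mean(apply(points, 1, function(p)
      prod(stats::dnorm(g, p, h))))
  })
}

# Jaccard overlap of two index sets.
jaccard_oracle <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Wrap a plain matrix as a normalized_matrix (for operating on constructed
# values directly, bypassing count normalization).
as_norm <- function(x) {
  structure(list(values = Matrix::Matrix(x, sparse = TRUE),
                 scale_total = 1e4, log_base = "natural",
                 zero_cells = rep(FALSE, nrow(x)),
                 cell_ids = paste0("c", seq_len(nrow(x))),
                 gene_ids = paste0("g", seq_len(ncol(x)))),
            class = "normalized_matrix")
}

# Small default params for fast module tests.
small_params <- function(...) {
  synth_params(n_genes = 300, n_cells_per_cluster = 40,
               timepoints_h = c(0, 12, 24, 30, 36, 42), ...)
}
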