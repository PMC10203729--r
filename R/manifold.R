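#' Diffusion map with adaptive Gaussian kernel
#'
#' Builds a random-walk transition matrix from an adaptive (local-sigma)
#' Gaussian kernel, `W_ij = exp(-d_ij^2 / (2 sigma_i sigma_j))` with
#' `sigma_i` the distance from cell i to its `ceiling(n_neighbors / 2)`-th
#' neighbour, restricted to the symmetrised `n_neighbors`-NN graph. The
#' walk is analysed through its symmetric conjugate
#' `S = D^{-1/2} W D^{-1/2}`: after dropping the trivial constant
#' eigenvector, the next `n_comps` right eigenvectors of the transition
#' matrix, scaled by their eigenvalues, are the diffusion components.
#'
#' @param emb An [embedding].
#' @param n_comps Number of diffusion components (< cell count).
#' @param n_neighbors Neighbourhood size for both the adaptive bandwidth
#'   and the kernel support (default 15).
#' @return List of class `diffusion_result`: `dcs` (cells x n_comps, columns
#'   `DC1..`), `eigenvalues` (decreasing, in (0, 1]), `phi` (unscaled
#'   eigenvectors), `stationary` (the walk's stationary distribution),
#'   `transition` (the row-stochastic transition matrix), `cell_ids`,
#'   `pseudotime` (`NULL` until [diffusion_pseudotime()]).
#' @export
diffusion_map <- function(emb, n_comps = 3, n_neighbors = 15) {
  x <- emb$coords
  n <- nrow(x)
  if (n_comps >= n) stop("n_comps must be smaller than the cell count")
  if (n_neighbors >= n) stop("n_neighbors must be smaller than the cell count")
  d2 <- sqdist(x, x)
  diag(d2) <- Inf
  ord <- apply(d2, 1, function(r) sort(r)[seq_len(n_neighbors)])
  kth <- ceiling(n_neighbors / 2)
  sigma <- sqrt(ord[kth, ])
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  nn <- knn_index(x, x, n_neighbors, exclude_self = TRUE)
  mask <- matrix(FALSE, n, n)
  mask[cbind(rep(seq_len(n), n_neighbors), as.vector(nn))] <- TRUE
  mask <- mask | t(mask)
  W <- matrix(0, n, n)
  W[mask] <- exp(-d2[mask] / (2 * (sigma %o% sigma)[mask]))
  # exact duplicates have d2 = 0 -> kernel 1 even if masked out by k-NN cuts
  dup <- d2 == 0
  W[dup] <- 1
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W > 0, mode = "undirected"))
  if (comp$no > 1) {
    sizes <- comp$csize
    stop("k-NN graph is disconnected: ", comp$no, " components of sizes ",
         paste(sizes, collapse = ", "),
         "; increase n_neighbors or analyse components separately")
  }
  deg <- rowSums(W)
  s <- 1 / sqrt(deg)
  S <- W * (s %o% s)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  ev <- eig$values
  vec <- eig$vectors
  keep <- 1 + seq_len(n_comps)
  phi <- vec[, keep, drop = FALSE] * s   # right eigenvectors of D^-1 W
  # normalise under the stationary-distribution inner product
  pi_st <- deg / sum(deg)
  nrm <- sqrt(colSums(phi^2 * pi_st))
  phi <- sweep(phi, 2, nrm, "/")
  phi <- fix_signs(phi)
  lambda <- ev[keep]
  dcs <- sweep(phi, 2, lambda, "*")
  colnames(dcs) <- paste0("DC", seq_len(n_comps))
  rownames(dcs) <- emb$cell_ids
  P <- W / deg
  structure(list(dcs = dcs, eigenvalues = lambda, phi = phi,
                 stationary = pi_st, cell_ids = emb$cell_ids,
                 transition = P, pseudotime = NULL, root = NULL),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("diffusion_result: %d cells, %d components (lambda1 = %.4f)\n",
              length(x$cell_ids), ncol(x$dcs), x$eigenvalues[1]))
  invisible(x)
}

#' Diffusion pseudotime from a root cell
#'
#' Pseudotime of cell c is its diffusion distance from the root in the
#' spectral representation,
#' `dpt(c) = sqrt(sum_l (lambda_l / (1 - lambda_l))^2 (phi_l(c) -
#' phi_l(root))^2)` over the computed components — the accumulated-transition
#' weighting that integrates the random walk over all scales. The root has
#' pseudotime 0 and the measure is invariant to cell relabelling.
#'
#' @param result A `diffusion_result`.
#' @param root Root cell id (or row index).
#' @return The `diffusion_result` with `pseudotime` and `root` filled.
#' @export
diffusion_pseudotime <- function(result, root) {
  if (is.character(root)) {
    ri <- match(root, result$cell_ids)
    if (is.na(ri)) stop("unknown root cell id: ", root)
  } else ri <- root
  w <- result$eigenvalues / (1 - pmin(result$eigenvalues, 1 - 1e-12))
  m <- sweep(result$phi, 2, w, "*")
  delta <- sweep(m, 2, m[ri, ], "-")
  result$pseudotime <- sqrt(rowSums(delta^2))
  names(result$pseudotime) <- result$cell_ids
  result$root <- result$cell_ids[ri]
  result
}

#' Expression ordered and smoothed along pseudotime
#'
#' Sorts cells by pseudotime and applies a centred rolling mean (window
#' truncated at the ends) to each requested gene's logCP10k expression —
#' the standard preparation for pseudotime heatmaps and line plots.
#'
#' @param cells A [cell_set].
#' @param result A `diffusion_result` with pseudotime computed.
#' @param genes Gene ids to include.
#' @param window_frac Rolling-window size as a fraction of the cell count
#'   (default 0.05; at least 1 cell).
#' @param norm Optional precomputed `normalized_matrix` for `cells`.
#' @return `data.frame`: `cell_id`, `pseudotime`, then one smoothed column
#'   per gene, rows sorted by pseudotime.
#' @export
order_genes_by_pseudotime <- function(cells, result, genes,
                                      window_frac = 0.05, norm = NULL) {
  if (is.null(result$pseudotime)) stop("compute diffusion_pseudotime first")
  missing <- setdiff(genes, cells$gene_ids)
  if (length(missing))
    stop("genes not found: ", paste(missing, collapse = ", "))
  if (is.null(norm)) norm <- normalize_logcp10k(cells)
  idx <- match(result$cell_ids, cells$cell_ids)
  if (anyNA(idx)) stop("diffusion result and cell set do not share cells")
  ord <- order(result$pseudotime)
  pt <- result$pseudotime[ord]
  expr <- as.matrix(norm$values[idx[ord], genes, drop = FALSE])
  n <- nrow(expr)
  h <- max(0L, floor(max(1L, round(window_frac * n)) / 2))
  smooth <- apply(expr, 2, function(v)
    vapply(seq_len(n), function(i)
      mean(v[max(1, i - h):min(n, i + h)]), numeric(1)))
  out <- data.frame(cell_id = result$cell_ids[ord], pseudotime = pt,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(smooth))
  rownames(out) <- NULL
  out
}
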