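#' Shared-nearest-neighbour weights of a query cell
#'
#' For query cell `j`, finds its `K` nearest reference cells in the shared
#' embedding and weights each by the Jaccard overlap between the
#' `k_graph`-nearest-neighbour set of `j` and that of the reference cell,
#' both computed in the pooled (query + reference) embedding — the standard
#' SNN similarity of the single-cell ecosystem. Weights are normalised by
#' their sum `c`; when every overlap is zero the weights fall back to
#' uniform `1/K` and the result is flagged.
#'
#' @param query [embedding] of the query cells.
#' @param reference A [spatial_reference] whose embedding shares the
#'   query's space.
#' @param j Query row index (or cell id).
#' @param K Number of reference neighbours to weight (default 10).
#' @param k_graph Neighbour-set size for the Jaccard overlap (default 20).
#' @param pooled_nn Optional precomputed pooled neighbour-index matrix from
#'   [pooled_knn_sets()] (avoids recomputation across cells).
#' @return List of class `snn_weights`: `query_cell`, `neighbor_indices`,
#'   `theta`, `theta_hat`, `c`, `zero_overlap`.
#' @export
snn_weights <- function(query, reference, j, K = 10, k_graph = 20,
                        pooled_nn = NULL) {
  check_shared_space(query, reference$embedding)
  nq <- nrow(query$coords); nr <- nrow(reference$embedding$coords)
  if (K > nr) stop("K = ", K, " exceeds the reference size")
  if (k_graph > nq + nr - 1) stop("k_graph exceeds the pooled cell count")
  if (is.character(j)) j <- match(j, query$cell_ids)
  if (is.null(pooled_nn)) pooled_nn <- pooled_knn_sets(query, reference, k_graph)
  d2 <- sqdist(query$coords[j, , drop = FALSE], reference$embedding$coords)
  nb <- order(d2[1, ])[seq_len(K)]
  set_q <- pooled_nn[j, ]
  theta <- vapply(nb, function(i) {
    set_r <- pooled_nn[nq + i, ]
    inter <- length(intersect(set_q, set_r))
    inter / (2 * length(set_q) - inter)
  }, numeric(1))
  cval <- sum(theta)
  zero <- cval == 0
  theta_hat <- if (zero) rep(1 / K, K) else theta / cval
  structure(list(query_cell = query$cell_ids[j], neighbor_indices = nb,
                 theta = theta, theta_hat = theta_hat, c = cval,
                 zero_overlap = zero),
            class = "snn_weights")
}

#' Pooled k-nearest-neighbour sets of query and reference cells
#'
#' Rows 1..nq are query cells, rows nq+1..nq+nr reference cells; each row
#' holds the indices (in the pooled ordering) of that cell's `k_graph`
#' nearest pooled neighbours, self excluded.
#'
#' @param query [embedding]; @param reference [spatial_reference].
#' @param k_graph Neighbour-set size.
#' @return Integer matrix ((nq + nr) x k_graph).
#' @export
pooled_knn_sets <- function(query, reference, k_graph = 20) {
  pooled <- rbind(query$coords, reference$embedding$coords)
  knn_index(pooled, pooled, k_graph, exclude_self = TRUE)
}

#' Project a query cell onto the reference's 3D coordinates
#'
#' The projected position is the SNN-weight-normalised average of the
#' neighbouring reference cells' positions, `R = sum_i theta_hat_i * r_i`,
#' hence always inside the convex hull of the neighbour positions.
#'
#' @param w An `snn_weights` object.
#' @param reference The [spatial_reference].
#' @return List of class `projected_position`: `query_cell`, `R` (length-3),
#'   `zero_overlap`.
#' @export
project_position <- function(w, reference) {
  pos <- reference$positions[w$neighbor_indices, , drop = FALSE]
  R <- as.numeric(crossprod(pos, w$theta_hat))
  names(R) <- c("x", "y", "z")
  structure(list(query_cell = w$query_cell, R = R,
                 zero_overlap = w$zero_overlap),
            class = "projected_position")
}

#' Project all query cells onto the 3D reference
#'
#' Convenience wrapper running [snn_weights()] + [project_position()] over
#' every query cell with one pooled KNN computation.
#'
#' @inheritParams snn_weights
#' @return `data.frame`: `cell_id`, `x`, `y`, `z`, `zero_overlap`.
#' @export
project_cells <- function(query, reference, K = 10, k_graph = 20) {
  pooled_nn <- pooled_knn_sets(query, reference, k_graph)
  rows <- lapply(seq_len(nrow(query$coords)), function(j) {
    w <- snn_weights(query, reference, j, K, k_graph, pooled_nn = pooled_nn)
    p <- project_position(w, reference)
    data.frame(cell_id = p$query_cell, x = p$R[1], y = p$R[2], z = p$R[3],
               zero_overlap = p$zero_overlap, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian kernel density of a projected cell group on a 3D grid
#'
#' Product-Gaussian kernel density estimate of the group's projected
#' positions, with Silverman's rule bandwidth per axis
#' (`sd * (4 / ((d + 2) n))^(1 / (d + 4))`, d = 3). The returned density
#' integrates to 1 over a grid that covers the data (within grid
#' resolution).
#'
#' @param projections `data.frame` from [project_cells()].
#' @param group Cell ids of the group (>= 2 members).
#' @param grid List with numeric vectors `x`, `y`, `z` of grid-node
#'   coordinates, or `NULL` for an automatic grid covering the group's
#'   positions plus 4 bandwidths at `n_grid` nodes per axis.
#' @param n_grid Nodes per axis of the automatic grid (default 25).
#' @param bandwidth Optional length-3 numeric overriding Silverman's rule.
#' @return List of class `density3d`: `grid` (the axis vectors), `density`
#'   (array nx x ny x nz), `bandwidth`, and `long` (`data.frame` x, y, z,
#'   density).
#' @export
group_density <- function(projections, group, grid = NULL, n_grid = 25,
                          bandwidth = NULL) {
  pts <- as.matrix(projections[projections$cell_id %in% group,
                               c("x", "y", "z")])
  n <- nrow(pts)
  if (n == 0) stop("empty group: no projected cells match the given ids")
  if (n < 2) stop("group density needs at least 2 projected cells")
  d <- 3
  if (is.null(bandwidth)) {
    bandwidth <- apply(pts, 2, stats::sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
    bandwidth[bandwidth == 0] <- 1e-8 * max(1, max(abs(pts)))
  }
  if (is.null(grid)) {
    grid <- lapply(1:3, function(a)
      seq(min(pts[, a]) - 4 * bandwidth[a], max(pts[, a]) + 4 * bandwidth[a],
          length.out = n_grid))
    names(grid) <- c("x", "y", "z")
  }
  # separable kernel: per-axis kernel matrices contracted slice by slice
  kx <- outer(grid$x, pts[, 1], function(g, p) stats::dnorm(g, p, bandwidth[1]))
  ky <- outer(grid$y, pts[, 2], function(g, p) stats::dnorm(g, p, bandwidth[2]))
  kz <- outer(grid$z, pts[, 3], function(g, p) stats::dnorm(g, p, bandwidth[3]))
  dens <- array(0, c(length(grid$x), length(grid$y), length(grid$z)))
  for (c3 in seq_along(grid$z))
    dens[, , c3] <- kx %*% t(ky * matrix(kz[c3, ], length(grid$y),
                                         n, byrow = TRUE)) / n
  long <- expand.grid(x = grid$x, y = grid$y, z = grid$z,
                      KEEP.OUT.ATTRS = FALSE)
  long$density <- as.vector(dens)
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 long = long),
            class = "density3d")
}

#' Mode (highest-density grid node) of a 3D density
#' @param dens A `density3d`.
#' @return Named length-3 numeric: grid node of maximal density.
#' @export
density_mode <- function(dens) {
  i <- which.max(dens$density)
  idx <- arrayInd(i, dim(dens$density))
  c(x = dens$grid$x[idx[1]], y = dens$grid$y[idx[2]], z = dens$grid$z[idx[3]])
}
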