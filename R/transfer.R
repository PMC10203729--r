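#' K nearest reference neighbours of each query cell
#'
#' Euclidean nearest neighbours in the shared embedding space; both
#' embeddings must carry the same `space_tag` and dimensionality. Exact
#' distance ties are broken deterministically by lowest reference index.
#'
#' @param query,reference [embedding]s in the same space.
#' @param k Number of neighbours (<= reference size).
#' @return Integer matrix (query cells x k) of reference row indices.
#' @export
knn_query_to_reference <- function(query, reference, k) {
  check_shared_space(query, reference)
  if (k > nrow(reference$coords))
    stop("k = ", k, " exceeds the reference size ", nrow(reference$coords))
  nn <- knn_index(query$coords, reference$coords, k)
  rownames(nn) <- query$cell_ids
  nn
}

#' Hypergeometric enrichment of reference labels among a cell's neighbours
#'
#' For each label with `x` occurrences among the `k` neighbours of a query
#' cell, computes the one-sided upper-tail probability
#' `p = P(X >= x)` with `X ~ Hypergeometric(N, K_label, k)` — the chance of
#' drawing at least `x` cells of that label when sampling `k` cells without
#' replacement from a reference of size `N` containing `K_label` of them.
#' Labels absent from the neighbourhood (`x = 0`) get `p = 1`.
#'
#' @param neighbor_labels Character vector: the labels of one cell's `k`
#'   neighbours.
#' @param label_counts Named integer vector: reference size of every label;
#'   must sum to `N`.
#' @param N Reference size.
#' @return `data.frame` with one row per candidate label: `label`, `x`,
#'   `K`, `N`, `k`, `p`.
#' @export
hypergeom_enrichment <- function(neighbor_labels, label_counts, N) {
  k <- length(neighbor_labels)
  if (sum(label_counts) != N)
    stop("label counts sum to ", sum(label_counts), ", not N = ", N)
  if (k > N) stop("more neighbours (", k, ") than reference cells (", N, ")")
  missing <- setdiff(unique(neighbor_labels), names(label_counts))
  if (length(missing))
    stop("neighbour labels absent from label_counts: ",
         paste(missing, collapse = ", "))
  labs <- names(label_counts)
  x <- as.integer(table(factor(neighbor_labels, levels = labs)))
  K <- as.integer(label_counts)
  p <- stats::phyper(x - 1L, K, N - K, k, lower.tail = FALSE)
  data.frame(label = labs, x = x, K = K, N = N, k = k, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign labels from per-cell enrichment tables
#'
#' Adjusts each cell's candidate p-values by Benjamini-Hochberg (within the
#' cell's label family) and assigns the label with the smallest adjusted
#' p-value among those significant at `alpha`. Cells with no significant
#' label stay [UNASSIGNED]. Exact adjusted-p ties are broken by smaller raw
#' p, then lexicographically by label.
#'
#' @param results Named list of per-cell `data.frame`s from
#'   [hypergeom_enrichment()] (names are cell ids), or one long
#'   `data.frame` with a `cell_id` column.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return `data.frame`: `cell_id`, `assigned_label`, `best_p`,
#'   `best_p_adj`, plus one `p_adj.<label>` column per candidate label.
#' @export
assign_labels <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.data.frame(results))
    results <- split(results, results$cell_id)[unique(results$cell_id)]
  out <- lapply(names(results), function(cid) {
    r <- results[[cid]]
    p_adj <- stats::p.adjust(r$p, method = "BH")
    sig <- p_adj < alpha
    if (any(sig)) {
      cand <- which(sig)
      cand <- cand[order(p_adj[cand], r$p[cand], r$label[cand])]
      best <- cand[1]
      lab <- r$label[best]; bp <- r$p[best]; bpa <- p_adj[best]
    } else {
      lab <- UNASSIGNED; bp <- NA_real_; bpa <- NA_real_
    }
    row <- data.frame(cell_id = cid, assigned_label = lab,
                      best_p = bp, best_p_adj = bpa,
                      stringsAsFactors = FALSE)
    wide <- as.data.frame(as.list(stats::setNames(p_adj,
                                                  paste0("p_adj.", r$label))))
    cbind(row, wide)
  })
  do.call(rbind, out)
}

#' Transfer reference labels onto query cells
#'
#' The full label-transfer pipeline: a KNN graph from query to reference in
#' the shared embedding, a per-cell hypergeometric enrichment test of every
#' reference annotation among the neighbours, BH adjustment within each
#' cell, and assignment of the most significant label (or [UNASSIGNED]).
#'
#' @param query,reference [embedding]s in the same space.
#' @param ref_labels Character vector of reference labels, one per
#'   reference cell.
#' @param k Neighbours per query cell (default 20).
#' @param alpha Significance level (default 0.05).
#' @return The assignment `data.frame` of [assign_labels()].
#' @export
transfer_labels <- function(query, reference, ref_labels, k = 20,
                            alpha = 0.05) {
  ref_labels <- as.character(ref_labels)
  if (length(ref_labels) != nrow(reference$coords))
    stop("ref_labels length does not match the reference")
  nn <- knn_query_to_reference(query, reference, k)
  label_counts <- table(ref_labels)
  N <- length(ref_labels)
  res <- enrichment_from_neighbors(nn, ref_labels, label_counts, N)
  assign_labels(res, alpha)
}

# Vectorised per-cell enrichment over a neighbour-index matrix; returns the
# named list form consumed by assign_labels(). Shared by transfer_labels()
# and the permutation control.
enrichment_from_neighbors <- function(nn, ref_labels, label_counts, N) {
  labs <- names(label_counts)
  k <- ncol(nn)
  n <- nrow(nn)
  lab_idx <- matrix(match(ref_labels[nn], labs), nrow = n)
  # joint (cell, label) tabulation in one pass
  cell_idx <- rep.int(seq_len(n), k)
  counts <- matrix(tabulate((as.vector(lab_idx) - 1L) * n + cell_idx,
                            nbins = n * length(labs)), n)
  K <- as.integer(label_counts)
  p <- matrix(stats::phyper(counts - 1L,
                            matrix(K, nrow(nn), length(labs), byrow = TRUE),
                            matrix(N - K, nrow(nn), length(labs), byrow = TRUE),
                            k, lower.tail = FALSE),
              nrow(nn))
  ids <- rownames(nn)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(nn)))
  stats::setNames(lapply(seq_len(nrow(nn)), function(i)
    data.frame(label = labs, x = counts[i, ], K = K, N = N, k = k,
               p = p[i, ], stringsAsFactors = FALSE)), ids)
}
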