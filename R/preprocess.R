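#' Log counts-per-10,000 normalization
#'
#' The standard droplet normalization: each cell's counts are scaled to a
#' common library size (default 10,000), a pseudocount of 1 is added and the
#' natural logarithm taken, i.e. `value = ln(1 + scale_total * count /
#' total)`. Cells with zero total counts yield all-zero rows and are
#' flagged rather than dropped.
#'
#' @param cells A [cell_set].
#' @param scale_total Library-size target (default 10,000).
#' @return An object of class `normalized_matrix` with elements `values`
#'   (sparse cells x genes), `scale_total`, `log_base` (`"natural"`) and
#'   `zero_cells` (logical flag per cell).
#' @export
normalize_logcp10k <- function(cells, scale_total = 1e4) {
  counts <- cells$counts
  totals <- Matrix::rowSums(counts)
  zero <- totals == 0
  scal <- ifelse(zero, 0, scale_total / totals)
  values <- Matrix::Diagonal(x = scal) %*% counts
  values@x <- log1p(values@x)
  values <- methods::as(values, "CsparseMatrix")
  dimnames(values) <- dimnames(counts)
  structure(list(values = values, scale_total = scale_total,
                 log_base = "natural", zero_cells = zero,
                 cell_ids = cells$cell_ids, gene_ids = cells$gene_ids),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (logCP%g): %d cells x %d genes (%d zero-count cells)\n",
              x$scale_total / 1e3 * 1e3, nrow(x$values), ncol(x$values),
              sum(x$zero_cells)))
  invisible(x)
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion z-score: genes are grouped into
#' `n_bins` bins of similar mean normalized expression, and each gene's
#' variance is standardised by the median and MAD of the variances in its
#' bin (the classic mean-variance-plot statistic, with robust bin moments
#' so that bins rich in genuinely variable genes do not mask their own
#' members). This removes the mean-variance trend so that genes varying
#' more than expected for their expression level rank highest.
#' Deterministic given the input.
#'
#' @param norm A `normalized_matrix`.
#' @param n_features Number of genes to return.
#' @param n_bins Number of mean bins for the trend (default 20).
#' @return Integer vector of gene column indices, ordered by decreasing
#'   dispersion statistic.
#' @export
select_hvg <- function(norm, n_features, n_bins = 20) {
  v <- norm$values
  n_genes <- ncol(v)
  if (n_features > n_genes)
    stop("n_features = ", n_features, " exceeds the ", n_genes, " genes")
  n <- nrow(v)
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  vr <- (ex2 - mu^2) * n / max(1, n - 1)
  # bins of ~equal occupancy over the mean; collapses gracefully when many
  # genes share a mean (e.g. all-zero genes)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
         else factor(rep(1L, n_genes))
  bm <- tapply(vr, bin, stats::median)
  bs <- tapply(vr, bin, stats::mad)
  bs[is.na(bs) | bs == 0] <- 1
  z <- (vr - bm[bin]) / bs[bin]
  ord <- order(-z, seq_len(n_genes))
  ord[seq_len(n_features)]
}

#' PCA embedding of normalized expression
#'
#' Centers (and by default unit-variance scales) the selected gene columns,
#' then computes principal-component scores by singular value
#' decomposition. Columns are ordered by decreasing explained variance and
#' the sign of each component is fixed so that its largest-magnitude gene
#' loading is positive, making results reproducible across platforms.
#'
#' @param norm A `normalized_matrix`.
#' @param genes Gene column indices to use (e.g. from [select_hvg()]);
#'   `NULL` uses all genes.
#' @param n_pcs Number of components (<= min(cells, genes)).
#' @param scale. Unit-variance scale the gene columns (default `TRUE`);
#'   zero-variance genes are left unscaled.
#' @param space_tag Tag for the returned [embedding]; default `"pca<n>"`.
#' @return An [embedding] whose attribute `"explained_variance"` holds the
#'   per-component explained-variance ratios.
#' @export
pca_embed <- function(norm, genes = NULL, n_pcs = 50, scale. = TRUE,
                      space_tag = NULL) {
  x <- if (is.null(genes)) norm$values else norm$values[, genes, drop = FALSE]
  x <- as.matrix(x)
  if (n_pcs > min(dim(x)))
    stop("n_pcs = ", n_pcs, " exceeds min(cells, genes) = ", min(dim(x)))
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr)
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, "/")
  }
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  fixed <- fix_signs(scores, sv$v)
  scores <- fixed$scores
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  ev <- sv$d^2 / sum(sv$d^2)
  if (is.null(space_tag)) space_tag <- paste0("pca", n_pcs)
  emb <- embedding(scores, norm$cell_ids, space_tag)
  attr(emb, "explained_variance") <- ev[seq_len(n_pcs)]
  attr(emb, "loadings") <- fixed$loadings
  emb
}
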