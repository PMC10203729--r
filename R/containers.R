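#' Sentinel used for cells without an assigned label
#'
#' Cells that fail the enrichment test, or that are absent from a metadata
#' table, carry this explicit sentinel rather than an empty string or `NA`.
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Construct a cell set
#'
#' The universal container of the package: a cells x genes matrix of raw
#' counts plus a per-cell metadata table. Counts are stored sparse
#' (`Matrix::dgCMatrix`) with cells as rows regardless of the on-disk
#' orientation of the source file.
#'
#' @param counts Non-negative integer matrix (cells x genes); dense or any
#'   `Matrix` sparse class.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column.
#' @param meta Optional per-cell `data.frame`. Recognised columns:
#'   `time_h` (hours, >= 0), `sample`, `cluster`, `label`, `lineage`.
#'   Missing labels are filled with [UNASSIGNED], missing times with `NA`.
#' @return An object of class `cell_set` with elements `counts`,
#'   `cell_ids`, `gene_ids`, `meta`.
#' @export
cell_set <- function(counts, cell_ids, gene_ids, meta = NULL) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids))
    stop("counts has ", nrow(counts), " rows but ", length(cell_ids),
         " cell ids were given")
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but ", length(gene_ids),
         " gene ids were given")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) stop("counts must be non-negative")
    if (any(x != round(x))) stop("counts must be integral")
  }
  if (is.null(meta)) {
    meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != length(cell_ids))
      stop("meta has ", nrow(meta), " rows but there are ",
           length(cell_ids), " cells")
    meta$cell_id <- cell_ids
  }
  if (is.null(meta$label)) meta$label <- rep(UNASSIGNED, nrow(meta))
  meta$label[is.na(meta$label)] <- UNASSIGNED
  if (is.null(meta$time_h)) meta$time_h <- rep(NA_real_, nrow(meta))
  if (!is.null(meta$time_h) && any(!is.na(meta$time_h) & meta$time_h < 0))
    stop("time_h must be >= 0")
  rownames(counts) <- cell_ids
  colnames(counts) <- gene_ids
  rownames(meta) <- NULL
  structure(list(counts = counts, cell_ids = cell_ids,
                 gene_ids = gene_ids, meta = meta),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("cell_set: %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_ids)))
  cat("meta columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a cell set
#' @param x A `cell_set`.
#' @return Integer cell count.
#' @export
n_cells <- function(x) length(x$cell_ids)

#' Subset a cell set by cells
#' @param x A `cell_set`.
#' @param i Logical, integer or character (cell id) index.
#' @return A `cell_set` restricted to the selected cells.
#' @export
subset_cells <- function(x, i) {
  if (is.character(i)) i <- match(i, x$cell_ids)
  cell_set(x$counts[i, , drop = FALSE], x$cell_ids[i], x$gene_ids,
           x$meta[i, , drop = FALSE])
}

#' Construct an embedding
#'
#' A cells x d coordinate matrix in a shared low-dimensional space,
#' row-matched to a [cell_set] through its `cell_ids`.
#'
#' @param coords Real matrix (cells x d), all entries finite.
#' @param cell_ids Unique cell identifiers, one per row.
#' @param space_tag String naming the space (e.g. `"pca50"`, `"aligned"`);
#'   embeddings are only comparable when their tags match.
#' @return An object of class `embedding`.
#' @export
embedding <- function(coords, cell_ids, space_tag = "aligned") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  cell_ids <- as.character(cell_ids)
  if (nrow(coords) != length(cell_ids))
    stop("coords rows and cell_ids differ in length")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (any(!is.finite(coords))) stop("embedding coordinates must be finite")
  rownames(coords) <- cell_ids
  structure(list(coords = coords, cell_ids = cell_ids,
                 space_tag = space_tag),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding [%s]: %d cells x %d dims\n",
              x$space_tag, nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' Construct a spatially resolved reference
#'
#' Reference cells with categorical lineage labels, 3D positions (arbitrary
#' length units) and an expression embedding shared with prospective query
#' cells.
#'
#' @param positions Real matrix (reference cells x 3).
#' @param labels Character vector of lineage labels, one per reference cell.
#' @param embedding An [embedding] row-matched to `positions`.
#' @param domain_centroids Optional matrix of true domain centroids
#'   (lineages x 3) when the reference is synthetic.
#' @return An object of class `spatial_reference`.
#' @export
spatial_reference <- function(positions, labels, embedding,
                              domain_centroids = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  if (any(!is.finite(positions))) stop("positions must be finite")
  labels <- as.character(labels)
  if (nrow(positions) != length(labels))
    stop("positions and labels differ in length")
  if (!inherits(embedding, "embedding")) stop("embedding must be an embedding")
  if (nrow(embedding$coords) != nrow(positions))
    stop("embedding rows and positions rows must match one-to-one")
  structure(list(positions = positions, labels = labels,
                 embedding = embedding,
                 domain_centroids = domain_centroids),
            class = "spatial_reference")
}

#' @export
print.spatial_reference <- function(x, ...) {
  cat(sprintf("spatial_reference: %d cells, %d lineage domains\n",
              nrow(x$positions), length(unique(x$labels))))
  invisible(x)
}

check_shared_space <- function(query, reference) {
  if (!inherits(query, "embedding") || !inherits(reference, "embedding"))
    stop("query and reference must be embeddings")
  if (ncol(query$coords) != ncol(reference$coords))
    stop("query (d=", ncol(query$coords), ") and reference (d=",
         ncol(reference$coords), ") embeddings have different dimensionality")
  if (!identical(query$space_tag, reference$space_tag))
    stop("query ('", query$space_tag, "') and reference ('",
         reference$space_tag, "') are not in the same embedding space")
  invisible(TRUE)
}
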