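#' Read a Matrix Market count triplet into a cell set
#'
#' Reads a 10X-style triplet: a coordinate-format `.mtx` matrix plus
#' one-name-per-line gene and cell (barcode) files. The on-disk orientation
#' is resolved by matching the matrix dimensions against the lengths of the
#' two name files: 10X matrices are genes x cells and are transposed on
#' read, so the returned object always has cells as rows. When both
#' orientations are consistent with the name files (a square matrix with
#' equally many genes and cells) the orientation is ambiguous and an error
#' is raised rather than guessing.
#'
#' @param matrix_path Path to the Matrix Market file.
#' @param genes_path Path to the gene-name file (one id per line).
#' @param cells_path Path to the cell-barcode file (one id per line).
#' @return A [cell_set].
#' @export
read_counts_mtx <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  gene_rows <- nrow(m) == length(genes) && ncol(m) == length(cells)
  cell_rows <- nrow(m) == length(cells) && ncol(m) == length(genes)
  if (gene_rows && cell_rows && nrow(m) != ncol(m)) gene_rows <- FALSE
  if (gene_rows && cell_rows)
    stop("matrix orientation is ambiguous: ", nrow(m), " x ", ncol(m),
         " fits both genes x cells and cells x genes; refusing to guess")
  if (!gene_rows && !cell_rows)
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither ", length(genes), " genes x ", length(cells),
         " cells nor its transpose")
  if (gene_rows) m <- Matrix::t(m)
  cell_set(m, cells, genes)
}

#' Write a cell set as a Matrix Market triplet
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `dir` following
#' the 10X convention (genes as matrix rows on disk; indices 1-based per the
#' Matrix Market standard).
#'
#' @param cells A [cell_set].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_counts_mtx <- function(cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  gp <- file.path(dir, "genes.tsv")
  bp <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(Matrix::t(cells$counts), mp)
  writeLines(cells$gene_ids, gp)
  writeLines(cells$cell_ids, bp)
  invisible(c(matrix = mp, genes = gp, barcodes = bp))
}

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t",
         stop("cannot infer delimiter from extension '.", ext,
              "' (use .csv or .tsv)"))
}

#' Read a delimited table
#'
#' Delimiter inferred from the extension (`.csv` comma, `.tsv`/`.txt` tab).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_table_auto <- function(path) {
  utils::read.table(path, sep = delim_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "")
}

#' Write a table as delimited text
#'
#' Round-trip safe for ordinary tables: reading the file back with
#' [read_table_auto()] returns an equal table.
#'
#' @param obj A `data.frame` (or coercible).
#' @param path Destination; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  obj <- as.data.frame(obj)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  utils::write.table(obj, path, sep = delim_for(path), quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Attach per-cell metadata from a delimited table
#'
#' Joins a metadata table onto a [cell_set] by its `cell_id` column. The
#' join order always follows the cell set, never the file. Cells absent
#' from the table keep an [UNASSIGNED] label and missing time; table rows
#' with unknown cell ids are ignored with a warning.
#'
#' @param path Path to a `.csv`/`.tsv` metadata table with a `cell_id`
#'   column.
#' @param cellset The [cell_set] to annotate.
#' @return The cell set with updated `meta`.
#' @export
read_metadata <- function(path, cellset) {
  tab <- read_table_auto(path)
  if (!"cell_id" %in% names(tab))
    stop("metadata table has no 'cell_id' column")
  if (anyDuplicated(tab$cell_id))
    stop("metadata table contains duplicated cell ids: ",
         paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "))
  unknown <- setdiff(tab$cell_id, cellset$cell_ids)
  if (length(unknown))
    warning(length(unknown), " metadata rows refer to unknown cells ",
            "and were ignored")
  idx <- match(cellset$cell_ids, tab$cell_id)
  meta <- cellset$meta
  for (col in setdiff(names(tab), "cell_id")) {
    vals <- tab[[col]][idx]
    meta[[col]] <- vals
  }
  if (!is.null(meta$label)) {
    meta$label[is.na(meta$label)] <- UNASSIGNED
  } else meta$label <- UNASSIGNED
  if (is.null(meta$time_h)) meta$time_h <- NA_real_
  cell_set(cellset$counts, cellset$cell_ids, cellset$gene_ids, meta)
}

#' Write an embedding as CSV
#'
#' Columns: `cell_id`, then one column per coordinate (named from the
#' embedding's column names, or `PC1..PCd`).
#'
#' @param emb An [embedding].
#' @param path Destination `.csv`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  cn <- colnames(emb$coords)
  if (is.null(cn)) cn <- paste0("PC", seq_len(ncol(emb$coords)))
  df <- data.frame(cell_id = emb$cell_ids, emb$coords)
  names(df) <- c("cell_id", cn)
  write_table(df, path)
}

#' Read an embedding from CSV
#'
#' @param path A `.csv` written by [write_embedding()] (first column
#'   `cell_id`, remaining columns coordinates).
#' @param space_tag Space tag to attach.
#' @return An [embedding].
#' @export
read_embedding <- function(path, space_tag = "aligned") {
  df <- read_table_auto(path)
  embedding(as.matrix(df[, -1, drop = FALSE]), df$cell_id, space_tag)
}
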