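#' Cell-by-gene count matrix with metadata
#'
#' A light container for unique-molecule counts: a sparse non-negative integer
#' matrix with cells as rows and genes as columns, plus a cell metadata table
#' keyed by barcode and a gene metadata table keyed by symbol. The gene table
#' must carry a logical `mito` flag; downstream QC uses the flag rather than
#' symbol prefixes, so mitochondrial naming conventions of either species are
#' irrelevant once the matrix is constructed.
#'
#' @param counts A matrix or sparse Matrix of non-negative counts, cells x
#'   genes. Dimnames are taken from the metadata tables.
#' @param cell_meta A data frame with a `barcode` column (unique), one row per
#'   cell, in row order of `counts`.
#' @param gene_meta A data frame with `symbol` (unique) and logical `mito`
#'   columns, one row per gene, in column order of `counts`.
#' @return An object of class `count_matrix` with elements `counts`
#'   (`dgCMatrix`), `cell_meta` and `gene_meta` (tibbles).
#' @seealso [read_counts()], [write_counts()], [compute_cell_qc()]
#' @export
count_matrix <- function(counts, cell_meta, gene_meta) {
  cell_meta <- tibble::as_tibble(cell_meta)
  gene_meta <- tibble::as_tibble(gene_meta)
  assert_that("barcode" %in% names(cell_meta), "cell_meta needs a 'barcode' column")
  assert_that(all(c("symbol", "mito") %in% names(gene_meta)),
              "gene_meta needs 'symbol' and 'mito' columns")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                        "generalMatrix")
  assert_that(nrow(counts) == nrow(cell_meta),
              sprintf("counts has %d rows but cell_meta %d", nrow(counts), nrow(cell_meta)),
              class = "xenosig_format_error")
  assert_that(ncol(counts) == nrow(gene_meta),
              sprintf("counts has %d columns but gene_meta %d", ncol(counts), nrow(gene_meta)),
              class = "xenosig_format_error")
  assert_that(!anyDuplicated(cell_meta$barcode), "cell barcodes must be unique")
  assert_that(!anyDuplicated(gene_meta$symbol), "gene symbols must be unique")
  assert_that(min(counts@x %||% 0, 0) >= 0, "counts must be non-negative")
  dimnames(counts) <- list(cell_meta$barcode, gene_meta$symbol)
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes (%d mito genes, %.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_meta$mito),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells and/or genes
#'
#' @param x A [count_matrix()].
#' @param cells,genes Logical, integer, or character (barcode/symbol) index
#'   vectors; `NULL` keeps everything.
#' @return A `count_matrix` with metadata subset consistently.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  ci <- if (is.null(cells)) seq_len(nrow(x$counts)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(x$counts)) else genes
  if (is.character(ci)) ci <- match(ci, x$cell_meta$barcode)
  if (is.character(gi)) gi <- match(gi, x$gene_meta$symbol)
  count_matrix(x$counts[ci, gi, drop = FALSE],
               x$cell_meta[ci, , drop = FALSE],
               x$gene_meta[gi, , drop = FALSE])
}

#' Write a count matrix as Matrix Market plus TSV metadata
#'
#' Writes `matrix.mtx` (1-indexed Matrix Market coordinates, cells as rows as
#' declared in `manifest.json`), `cells.tsv`, `genes.tsv`, and a small JSON
#' manifest recording the orientation and dimensions. The round trip through
#' [read_counts()] is lossless.
#'
#' @param x A [count_matrix()].
#' @param path Directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  utils::write.table(x$cell_meta, file.path(path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$gene_meta, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(format = "matrix-market", orientation = "cells_x_genes",
                   n_cells = nrow(x$counts), n_genes = ncol(x$counts))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path Directory containing `matrix.mtx`, `cells.tsv`, `genes.tsv` and
#'   `manifest.json`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"))
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))
  if (identical(man$orientation, "genes_x_cells")) m <- Matrix::t(m)
  cells <- utils::read.delim(file.path(path, "cells.tsv"), stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(path, "genes.tsv"), stringsAsFactors = FALSE)
  assert_that(nrow(m) == nrow(cells) && ncol(m) == nrow(genes),
              sprintf("matrix is %d x %d but metadata describe %d cells and %d genes",
                      nrow(m), ncol(m), nrow(cells), nrow(genes)),
              class = "xenosig_format_error")
  count_matrix(m, cells, genes)
}
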