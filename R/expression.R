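# Labeled single-cell expression container and MatrixMarket I/O.

#' Construct a labeled single-cell expression dataset
#'
#' Holds a sparse cells-by-genes UMI count matrix together with per-cell
#' metadata (cell-type label and sample of origin).
#'
#' @param counts cells-by-genes matrix of non-negative integer counts (dense
#'   or sparse; coerced to `dgCMatrix`). Row names are cell ids, column names
#'   gene symbols; alternatively supply `gene_ids` / `cell_ids`.
#' @param cell_type character vector (one label per cell) or named vector
#'   keyed by cell id.
#' @param sample sample id per cell, recycled if length 1.
#' @param gene_ids,cell_ids optional explicit index vectors.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, cell_type, sample = "s1",
                               gene_ids = NULL, cell_ids = NULL) {
  counts <- methods::as(methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (!is.null(cell_ids)) rownames(counts) <- cell_ids
  if (!is.null(gene_ids)) colnames(counts) <- gene_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must carry cell ids (rows) and gene ids (columns)")
  x <- counts@x
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    abort("counts must be finite non-negative integers")
  n_cells <- nrow(counts)
  if (!is.null(names(cell_type))) {
    missing <- setdiff(rownames(counts), names(cell_type))
    if (length(missing) > 0)
      abort(paste0("no cell-type label for cell(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    cell_type <- unname(cell_type[rownames(counts)])
  }
  if (length(cell_type) != n_cells)
    abort("cell_type must provide exactly one label per cell")
  if (any(is.na(cell_type))) abort("cell-type labels must not be NA")
  if (length(sample) == 1) sample <- rep(sample, n_cells)
  if (!is.null(names(sample))) sample <- unname(sample[rownames(counts)])
  if (length(sample) != n_cells)
    abort("sample must provide exactly one id per cell")
  structure(
    list(
      counts = counts,
      gene_ids = colnames(counts),
      cell_ids = rownames(counts),
      meta = tibble(cell_id = rownames(counts),
                    cell_type = as.character(cell_type),
                    sample = as.character(sample))
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$meta$cell_type)
  cat("<expression_dataset> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes; cell types: ",
      paste(names(tab), " (", as.integer(tab), ")", sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of cells per cell type
#' @param expr an `expression_dataset`.
#' @return named integer vector.
#' @export
cells_per_type <- function(expr) {
  stopifnot(inherits(expr, "expression_dataset"))
  tab <- table(expr$meta$cell_type)
  setNames(as.integer(tab), names(tab))
}

#' Read single-cell expression from MatrixMarket triplet files
#'
#' @param mtx_path MatrixMarket coordinate file, cells as rows and genes as
#'   columns.
#' @param genes_path,cells_path plain-text index files, one id per line,
#'   matching the matrix columns and rows respectively.
#' @param metadata_path TSV with header `cell_id  cell_type  sample`.
#' @return an [expression_dataset].
#' @export
read_expression <- function(mtx_path, genes_path, cells_path, metadata_path) {
  m <- as(readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(cells) || ncol(m) != length(genes))
    abort(paste0("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
                 " but indices give ", length(cells), " cells and ",
                 length(genes), " genes"))
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character")
  need <- c("cell_id", "cell_type", "sample")
  if (!all(need %in% names(meta)))
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  unknown <- setdiff(cells, meta$cell_id)
  if (length(unknown) > 0)
    abort(paste0("cell(s) present in matrix but absent from metadata: ",
                 paste(head(unknown, 5), collapse = ", ")))
  meta <- meta[match(cells, meta$cell_id), ]
  rownames(m) <- cells
  colnames(m) <- genes
  expression_dataset(m, cell_type = meta$cell_type, sample = meta$sample)
}

#' Write an expression dataset as MatrixMarket triplet plus index/metadata
#'
#' Produces `counts.mtx`, `genes.txt`, `cells.txt` and `metadata.tsv` under
#' `dir`, the layout [read_expression()] consumes.
#'
#' @param expr an `expression_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_expression <- function(expr, dir) {
  stopifnot(inherits(expr, "expression_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMM(expr$counts, file.path(dir, "counts.mtx"))
  writeLines(expr$gene_ids, file.path(dir, "genes.txt"))
  writeLines(expr$cell_ids, file.path(dir, "cells.txt"))
  utils::write.table(as.data.frame(expr$meta), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
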