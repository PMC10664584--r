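#' Construct an ExpressionMatrix
#'
#' The central container: a sparse cell x gene matrix of non-negative values
#' with unique cell and gene identifiers and an optional per-cell sample id.
#' Raw counts are integers; normalized matrices hold reals.
#'
#' @param counts matrix or sparse Matrix, cells as rows, genes as columns.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames of `counts`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   colnames of `counts`).
#' @param sample_of_cell per-cell sample identifier; recycled if length 1.
#'   `NA` allowed until abundance counting.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, cell_ids = rownames(counts),
                              gene_ids = colnames(counts),
                              sample_of_cell = NA_character_) {
  counts <- to_sparse_general(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (length(counts@x) && min(counts@x) < 0)
    stop("negative entries are not allowed in an expression matrix",
         call. = FALSE)
  dimnames(counts) <- list(cell_ids, gene_ids)
  sample_of_cell <- rep_len(as.character(sample_of_cell), nrow(counts))
  structure(list(counts = counts, sample_of_cell = sample_of_cell),
            class = "ExpressionMatrix")
}

# Any matrix-like input -> dgCMatrix (general, column-compressed).
to_sparse_general <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  as(as(as(x, "CsparseMatrix"), "generalMatrix"), "dMatrix")
}

#' @exportS3Method base::dim
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%d stored entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Cell identifiers of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector.
#' @export
cell_ids <- function(m) rownames(m$counts)

#' Gene identifiers of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector.
#' @export
gene_ids <- function(m) colnames(m$counts)

#' Subset cells of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @param idx integer, logical or character index into the cells.
#' @return an `ExpressionMatrix` with the selected cells, gene set unchanged.
#' @export
subset_cells <- function(m, idx) {
  expression_matrix(m$counts[idx, , drop = FALSE],
                    sample_of_cell = m$sample_of_cell[
                      if (is.character(idx)) match(idx, cell_ids(m)) else idx])
}

#' Read a Matrix Market count matrix with barcode/feature annotations
#'
#' Reads the standard triplet of files written by droplet pipelines:
#' a coordinate-format `.mtx` matrix plus one-identifier-per-line barcode
#' (cell) and feature (gene) files. CellRanger writes genes as rows, which is
#' the default orientation; the result always has cells as rows.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param barcodes_path path to the barcodes file (first column used).
#' @param features_path path to the features file (first column used).
#' @param orientation `"genes_as_rows"` (default, CellRanger convention;
#'   matrix is transposed on read) or `"cells_as_rows"`.
#' @param sample_of_cell optional per-cell sample identifiers.
#' @return an `ExpressionMatrix`.
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path,
                     orientation = c("genes_as_rows", "cells_as_rows"),
                     sample_of_cell = NA_character_) {
  orientation <- match.arg(orientation)
  for (f in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  mm <- to_sparse_general(Matrix::readMM(matrix_path))
  barcodes <- read_id_column(barcodes_path)
  features <- read_id_column(features_path)
  if (orientation == "genes_as_rows") mm <- Matrix::t(mm)
  if (nrow(mm) != length(barcodes) || ncol(mm) != length(features))
    stop(sprintf(
      "dimension mismatch: matrix is %d cells x %d genes but %d barcodes and %d features were read",
      nrow(mm), ncol(mm), length(barcodes), length(features)), call. = FALSE)
  if (length(mm@x) && min(mm@x) < 0)
    stop("negative entries are not allowed in a count matrix", call. = FALSE)
  expression_matrix(mm, cell_ids = barcodes, gene_ids = features,
                    sample_of_cell = sample_of_cell)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write an ExpressionMatrix as Matrix Market triplet files
#'
#' @param m an `ExpressionMatrix`.
#' @param dir output directory (created if missing).
#' @param orientation on-disk orientation, see [read_mtx()].
#' @return the directory, invisibly.
#' @export
write_mtx <- function(m, dir, orientation = c("genes_as_rows", "cells_as_rows")) {
  orientation <- match.arg(orientation)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- if (orientation == "genes_as_rows") Matrix::t(m$counts) else m$counts
  Matrix::writeMM(mm, file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  writeLines(gene_ids(m), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a dense delimited count table
#'
#' Expects a rectangular numeric table with a header row and a first column
#' of identifiers.
#'
#' @param path path to the table.
#' @param delimiter field separator (default `","`).
#' @param orientation `"cells_as_rows"` (default) or `"genes_as_rows"`.
#' @param sample_of_cell optional per-cell sample identifiers.
#' @return an `ExpressionMatrix` with cells as rows.
#' @export
read_dense <- function(path, delimiter = ",",
                       orientation = c("cells_as_rows", "genes_as_rows"),
                       sample_of_cell = NA_character_) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, sep = delimiter, header = TRUE, row.names = 1,
               check.names = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("parse error: non-numeric entries in ", path, call. = FALSE)
  mat <- as.matrix(df)
  if (orientation == "genes_as_rows") mat <- t(mat)
  expression_matrix(mat, sample_of_cell = sample_of_cell)
}
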