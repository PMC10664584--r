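#' Compute the pairwise cell dissimilarity matrix
#'
#' Computes all `n(n-1)/2` pairwise dissimilarities between the rows (cells)
#' of an expression matrix into packed strict-lower-triangular storage.
#' Three dissimilarities are available: Manhattan (`L1`), Euclidean (`L2`)
#' and `Pearson`, defined as one minus the absolute value of the Pearson
#' correlation coefficient (so perfectly correlated and perfectly
#' anti-correlated cells both have dissimilarity 0, and values lie in
#' \[0, 1\]).
#'
#' The sparse kernel bypasses components that are zero in both cells; since a
#' zero-zero component contributes an exact 0.0 to every metric's
#' accumulator and components are visited in ascending gene order, the
#' result is bit-identical to the dense reference loop (`engine = "dense"`).
#' Work is divided into `workers` contiguous, equal-size (+-1) chunks of the
#' linearized pair index; each pair is computed independently in double
#' precision, so results are identical for any worker count. With
#' `precision = "single"` each finished entry is rounded to the nearest IEEE
#' single-precision value before storage, halving memory.
#'
#' Cells with constant expression have no defined Pearson correlation; such
#' pairs get dissimilarity 1 (or 0 against an identical constant cell) with a
#' warning.
#'
#' @param m an `ExpressionMatrix`, or a plain (sparse) matrix with cells as
#'   rows.
#' @param metric `"L1"`, `"L2"` or `"Pearson"`.
#' @param precision storage precision, `"double"` (default) or `"single"`.
#' @param workers number of work chunks / threads (>= 1).
#' @param engine `"sparse"` (default) or the `"dense"` reference kernel.
#' @return a `DissimilarityMatrix`.
#' @export
compute_dissimilarity <- function(m, metric = c("L1", "L2", "Pearson"),
                                  precision = c("double", "single"),
                                  workers = 1L,
                                  engine = c("sparse", "dense")) {
  metric <- match.arg(metric)
  precision <- match.arg(precision)
  engine <- match.arg(engine)
  if (inherits(m, "ExpressionMatrix")) {
    ids <- cell_ids(m)
    counts <- m$counts
  } else {
    ids <- rownames(m)
    counts <- to_sparse_general(m)
  }
  n <- nrow(counts)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  tm <- as(Matrix::t(counts), "CsparseMatrix") # genes x cells: cell = column
  res <- cpp_dissimilarity(tm@p, tm@i, tm@x, n_genes = nrow(tm), n_cells = n,
                           metric = match(metric, c("L1", "L2", "Pearson")) - 1L,
                           precision = if (precision == "single") 4L else 8L,
                           workers = as.integer(workers),
                           dense = engine == "dense")
  if (metric == "Pearson" && res$n_constant_pairs > 0)
    warning(res$n_constant_pairs,
            " pair(s) involved a constant cell; Pearson dissimilarity set to",
            " 1 (0 for identical constant cells)")
  dissimilarity_matrix(res$data, n = n, metric = metric,
                       precision = precision, ids = ids)
}
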