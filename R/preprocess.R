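#' Quality-control filtering of cells
#'
#' Keeps cells with at least `min_counts` total counts, at least `min_genes`
#' detected (nonzero) genes, and a mitochondrial count fraction of at most
#' `max_mito_frac`. Defaults follow the common droplet QC convention
#' (>= 2500 counts, >= 750 genes, <= 25% mitochondrial reads). The gene set
#' is never changed. A per-criterion removal report is attached as the
#' `"qc_report"` attribute.
#'
#' @param m an `ExpressionMatrix` of raw counts.
#' @param min_counts minimum total counts per cell.
#' @param min_genes minimum number of detected genes per cell.
#' @param max_mito_frac maximum mitochondrial fraction of total counts.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes,
#'   matched case-insensitively.
#' @return the filtered `ExpressionMatrix`.
#' @export
qc_filter <- function(m, min_counts = 2500, min_genes = 750,
                      max_mito_frac = 0.25, mito_prefix = "MT-") {
  counts <- m$counts
  totals <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito_genes <- startsWith(toupper(gene_ids(m)), toupper(mito_prefix))
  if (!any(mito_genes)) {
    warning("no mitochondrial genes found with prefix '", mito_prefix,
            "'; mitochondrial criterion passes vacuously")
    mito_frac <- rep(0, nrow(counts))
  } else {
    mito_frac <- Matrix::rowSums(counts[, mito_genes, drop = FALSE]) /
      pmax(totals, 1)
  }
  pass_counts <- totals >= min_counts
  pass_genes <- detected >= min_genes
  pass_mito <- mito_frac <= max_mito_frac
  keep <- pass_counts & pass_genes & pass_mito
  out <- subset_cells(m, which(keep))
  attr(out, "qc_report") <- c(low_counts = sum(!pass_counts),
                              low_genes = sum(!pass_genes),
                              high_mito = sum(!pass_mito),
                              removed = sum(!keep))
  out
}

row_normalize <- function(mat, transform_log = FALSE, ids) {
  if (transform_log) mat@x <- log1p(mat@x)
  totals <- Matrix::rowSums(mat)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(ids[totals == 0], collapse = ", "), call. = FALSE)
  Matrix::Diagonal(x = 1 / totals) %*% mat
}

#' Per-cell normalizations
#'
#' `normalize_rawn` divides each count by the cell's total, so every row sums
#' to 1. `normalize_log1n` first maps each count to `log(1 + count)` (natural
#' logarithm) and then divides by the cell's total of transformed values, so
#' rows again sum to 1. Both preserve the sparsity pattern.
#'
#' @param m an `ExpressionMatrix` with positive per-cell totals.
#' @return a normalized `ExpressionMatrix`.
#' @export
normalize_rawn <- function(m) {
  expression_matrix(row_normalize(m$counts, FALSE, cell_ids(m)),
                    cell_ids = cell_ids(m), gene_ids = gene_ids(m),
                    sample_of_cell = m$sample_of_cell)
}

#' @rdname normalize_rawn
#' @export
normalize_log1n <- function(m) {
  expression_matrix(row_normalize(m$counts, TRUE, cell_ids(m)),
                    cell_ids = cell_ids(m), gene_ids = gene_ids(m),
                    sample_of_cell = m$sample_of_cell)
}

#' Select highly variable genes (vst-style standardized variance)
#'
#' Ranks genes by the variance of their standardized expression: each gene's
#' expected standard deviation is taken from a loess trend of
#' `log10(variance)` on `log10(mean)` over genes with positive variance,
#' values are standardized as `(x - mean) / sd_expected` and clipped above at
#' `sqrt(n_cells)`, and the variance of the clipped values is the ranking
#' statistic. Deterministic for a fixed span; ties broken by gene order.
#'
#' @param m an `ExpressionMatrix` of raw counts.
#' @param n_hvg number of genes to return (`<=` number of genes).
#' @param span loess span of the mean-variance trend fit.
#' @return character vector of `n_hvg` gene ids, most variable first.
#' @export
select_hvg <- function(m, n_hvg, span = 0.3) {
  counts <- m$counts
  p <- ncol(counts)
  if (n_hvg > p) stop("n_hvg exceeds the number of genes", call. = FALSE)
  n <- nrow(counts)
  mu <- Matrix::colMeans(counts)
  ssq <- Matrix::colSums(counts^2)
  v <- (ssq - n * mu^2) / (n - 1)
  std_var <- numeric(p)
  fit_ok <- v > 0 & mu > 0
  if (sum(fit_ok) >= 4) {
    # the span must cover enough genes for a local quadratic; widen it on
    # small panels so the trend fit stays well-conditioned
    span <- max(span, min(1, 15 / sum(fit_ok)))
    fit <- loess(log10(v[fit_ok]) ~ log10(mu[fit_ok]), span = span, degree = 2)
    sd_exp <- sqrt(10^predict(fit))
    clip <- sqrt(n)
    idx_fit <- which(fit_ok)
    for (s in seq_along(idx_fit)) {
      g <- idx_fit[s]
      col <- counts[, g]
      z <- (as.numeric(col) - mu[g]) / sd_exp[s]
      z <- pmin(z, clip)
      std_var[g] <- sum(z^2) / (n - 1)
    }
  }
  ord <- order(-std_var, seq_len(p))
  gene_ids(m)[ord[seq_len(n_hvg)]]
}

#' Subset an ExpressionMatrix to a gene list
#'
#' @param m an `ExpressionMatrix`.
#' @param keep gene ids to retain; the output columns follow this order.
#' @return an `ExpressionMatrix` with `length(keep)` genes.
#' @export
filter_genes <- function(m, keep) {
  keep <- as.character(keep)
  unknown <- setdiff(keep, gene_ids(m))
  if (length(unknown))
    stop("unknown gene ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  expression_matrix(m$counts[, keep, drop = FALSE],
                    cell_ids = cell_ids(m), gene_ids = keep,
                    sample_of_cell = m$sample_of_cell)
}

#' Read a plain-text gene list (one id per line)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  trimws(lines[nzchar(trimws(lines))])
}
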