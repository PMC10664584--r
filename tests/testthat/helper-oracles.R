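# Independent reference implementations used as oracles. All are written as
# plain, naive R so they share no code path with the package internals.

# Dense O(n^2 p) pairwise dissimilarities, packed in the same strict
# lower-triangle row-major order the package uses.
ref_dissimilarity <- function(mat, metric) {
  n <- nrow(mat)
  out <- numeric(n * (n - 1) / 2)
  t <- 1
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      x <- mat[i, ]
      y <- mat[j, ]
      out[t] <- switch(metric,
        L1 = sum(abs(x - y)),
        L2 = sqrt(sum((x - y)^2)),
        Pearson = 1 - abs(stats::cor(x, y)))
      t <- t + 1
    }
  }
  out
}

# Full symmetric matrix from a DissimilarityMatrix, via the accessor only.
full_diss <- function(D) {
  n <- D$n
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) m[i, j] <- diss(D, i, j)
  m
}

# Random packed dissimilarity matrix (uniform entries; PAM and silhouette
# require no metric axioms).
rand_diss <- function(n, seed) {
  set.seed(seed)
  dissimilarity_matrix(runif(n * (n - 1) / 2), n = n, metric = "L1")
}

# Pack a full symmetric matrix into the row-major strict lower triangle.
pack_full <- function(dm) {
  n <- nrow(dm)
  out <- numeric(n * (n - 1) / 2)
  t <- 1
  for (i in 2:n) for (j in 1:(i - 1)) { out[t] <- dm[i, j]; t <- t + 1 }
  out
}

# Packed matrix from points on a line, L1.
line_diss <- function(x) {
  dm <- as.matrix(dist(x, method = "manhattan"))
  dissimilarity_matrix(pack_full(dm), n = length(x), metric = "L1")
}

ref_td <- function(dm, medoids) {
  sum(apply(dm[, medoids, drop = FALSE], 1, min))
}

# Naive greedy BUILD on the full matrix; same lowest-index tie rule.
ref_build_greedy <- function(dm, k) {
  n <- nrow(dm)
  med <- which.min(rowSums(dm))
  for (step in seq_len(k - 1)) {
    dnear <- apply(dm[, med, drop = FALSE], 1, min)
    red <- rep(-Inf, n)
    for (c in setdiff(seq_len(n), med))
      red[c] <- sum(pmax(dnear - dm[, c], 0))
    med <- c(med, which.max(red))
  }
  med
}

# Naive O(n^2) silhouette on the full matrix.
ref_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  f <- as.integer(factor(labels))
  sizes <- tabulate(f)
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[f[i]] == 1) { s[i] <- 0; next }
    a <- sum(dm[i, f == f[i]]) / (sizes[f[i]] - 1)
    b <- Inf
    for (J in seq_along(sizes)) {
      if (J == f[i] || sizes[J] == 0) next
      b <- min(b, mean(dm[i, f == J]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# Pair-counting ARI: classify all C(n,2) pairs as together/apart in each
# partition; ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)).
ref_ari_paircount <- function(p, q) {
  n <- length(p)
  a <- b <- cc <- d <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sp <- p[i] == p[j]
      sq <- q[i] == q[j]
      if (sp && sq) a <- a + 1
      else if (sp && !sq) b <- b + 1
      else if (!sp && sq) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# Small random sparse count fixture as an ExpressionMatrix.
rand_expression <- function(n_cells, n_genes, seed, density = 0.4,
                            max_count = 20) {
  set.seed(seed)
  counts <- matrix(0, n_cells, n_genes)
  nz <- matrix(runif(n_cells * n_genes) < density, n_cells, n_genes)
  counts[nz] <- sample.int(max_count, sum(nz), replace = TRUE)
  # guarantee no all-zero cell
  for (i in which(rowSums(counts) == 0)) counts[i, 1] <- 1
  expression_matrix(counts,
                    cell_ids = sprintf("c%03d", seq_len(n_cells)),
                    gene_ids = sprintf("g%03d", seq_len(n_genes)))
}
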