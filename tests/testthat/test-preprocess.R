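make_qc_fixture <- function() {
  # 5 cells x 1000 genes incl. one mitochondrial gene; engineered totals
  genes <- c("MT-CO1", sprintf("g%03d", 1:999))
  counts <- matrix(0, 5, 1000, dimnames = list(sprintf("cell%d", 1:5), genes))
  fill <- function(i, n_genes, total, mito) {
    per <- (total - mito) %/% n_genes
    extra <- (total - mito) %% n_genes
    counts[i, 2:(n_genes + 1)] <- per
    counts[i, 2] <- counts[i, 2] + extra
    counts[i, 1] <- mito
    counts
  }
  counts <- fill(1, 800, 2499, 0)   # fails the count threshold by 1
  counts <- fill(2, 800, 3000, 0)   # passes everything
  counts <- fill(3, 700, 3000, 0)   # fails detected-gene threshold
  counts <- fill(4, 800, 4000, 1200) # mito fraction 0.30 > 0.25
  counts <- fill(5, 900, 5000, 1000) # mito fraction 0.20, passes
  expression_matrix(counts)
}

test_that("qc_filter applies the count, gene and mitochondrial thresholds", {
  m <- make_qc_fixture()
  out <- qc_filter(m)
  # independent per-cell recomputation of the three criteria
  cm <- as.matrix(m$counts)
  totals <- rowSums(cm)
  detected <- rowSums(cm > 0)
  mito <- cm[, "MT-CO1"] / totals
  expected <- names(which(totals >= 2500 & detected >= 750 & mito <= 0.25))
  expect_identical(cell_ids(out), expected)
  expect_identical(cell_ids(out), c("cell2", "cell5"))
  expect_identical(gene_ids(out), gene_ids(m)) # gene set unchanged

  rep <- attr(out, "qc_report")
  expect_equal(unname(rep["removed"]), 3)
  expect_equal(unname(rep["low_counts"]), 1)

  # the boundary cell: total 2499 is removed, 2500 would be kept
  expect_false("cell1" %in% cell_ids(out))
})

test_that("qc_filter passes a clean matrix through unchanged and is idempotent", {
  m <- make_qc_fixture()
  clean <- subset_cells(m, c(2, 5))
  out <- qc_filter(clean)
  expect_identical(cell_ids(out), cell_ids(clean))
  expect_true(all(attr(out, "qc_report") == 0))

  once <- qc_filter(m)
  twice <- qc_filter(once)
  expect_identical(cell_ids(twice), cell_ids(once))
  expect_equal(as.matrix(twice$counts), as.matrix(once$counts))
})

test_that("qc_filter warns when no mitochondrial genes are present", {
  m <- rand_expression(4, 6, seed = 1)
  expect_warning(qc_filter(m, min_counts = 1, min_genes = 1),
                 "no mitochondrial genes")
})

test_that("rawn normalization divides by the cell total", {
  m <- expression_matrix(matrix(c(2, 3, 5), 1, dimnames = list("c1", NULL)))
  expect_equal(as.numeric(normalize_rawn(m)$counts), c(0.2, 0.3, 0.5))

  one_gene <- expression_matrix(matrix(c(3, 7, 11), 3, 1))
  expect_equal(as.numeric(normalize_rawn(one_gene)$counts), c(1, 1, 1))

  m <- rand_expression(20, 15, seed = 4)
  norm <- normalize_rawn(m)
  expect_true(all(abs(Matrix::rowSums(norm$counts) - 1) < 1e-12))
  # sparsity pattern preserved
  expect_identical(norm$counts@i, m$counts@i)

  zero <- expression_matrix(matrix(c(1, 0), 2, 1,
                                   dimnames = list(c("ok", "empty"), NULL)))
  expect_error(normalize_rawn(zero), "empty")
})

test_that("log1n normalization transforms then divides by the logged total", {
  m <- expression_matrix(matrix(c(0, exp(1) - 1), 1,
                                dimnames = list("c1", NULL)))
  expect_equal(as.numeric(as.matrix(normalize_log1n(m)$counts)), c(0, 1),
               tolerance = 1e-12)

  equal <- expression_matrix(matrix(5, 1, 4))
  expect_equal(as.numeric(normalize_log1n(equal)$counts), rep(0.25, 4))

  m <- rand_expression(10, 8, seed = 5)
  norm <- as.matrix(normalize_log1n(m)$counts)
  raw <- as.matrix(m$counts)
  manual <- t(apply(raw, 1, function(r) log1p(r) / sum(log1p(r))))
  expect_equal(norm, manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalizations commute with gene order permutation", {
  m <- rand_expression(12, 9, seed = 6)
  perm <- sample(gene_ids(m))
  for (fn in list(normalize_rawn, normalize_log1n)) {
    a <- filter_genes(fn(m), perm)
    b <- fn(filter_genes(m, perm))
    expect_equal(as.matrix(a$counts), as.matrix(b$counts), tolerance = 1e-14)
  }
})

test_that("select_hvg ranks a bimodal gene first and respects the contract", {
  set.seed(7)
  n <- 60
  # noise genes with distinct means and mild variation; one bimodal gene
  counts <- sapply(1:11, function(g) rep(c(g + 3L, g + 4L, g + 6L),
                                         length.out = n))
  counts[, 1] <- rep(c(0L, 40L), each = n / 2) # bimodal across two groups
  m <- expression_matrix(counts)
  expect_identical(select_hvg(m, 1), gene_ids(m)[1])

  expect_setequal(select_hvg(m, 11), gene_ids(m))
  expect_error(select_hvg(m, 12), "exceeds")

  const <- expression_matrix(matrix(3, 10, 5))
  expect_length(select_hvg(const, 3), 3)

  # deterministic for a fixed configuration
  expect_identical(select_hvg(m, 5), select_hvg(m, 5))
})

test_that("filter_genes subsets columns in the requested order", {
  m <- rand_expression(6, 5, seed = 8)
  expect_equal(as.matrix(filter_genes(m, gene_ids(m))$counts),
               as.matrix(m$counts))
  single <- filter_genes(m, "g002")
  expect_equal(dim(single), c(6L, 1L))
  rev_order <- filter_genes(m, rev(gene_ids(m)))
  expect_identical(gene_ids(rev_order), rev(gene_ids(m)))
  expect_error(filter_genes(m, c("g001", "gTYPO")), "gTYPO")
})
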