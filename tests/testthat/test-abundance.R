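meta2 <- sample_metadata(c("A", "B"), day = c(18, 24), phase = c(4, 5))

test_that("cluster_sample_counts tabulates cells per cluster and sample", {
  tab <- cluster_sample_counts(c(0, 0, 1, 1), c("A", "A", "A", "B"), meta2)
  expect_equal(unname(tab$counts), rbind(c(2L, 0L), c(1L, 1L)))
  expect_identical(colnames(tab$counts), c("A", "B"))
  expect_error(cluster_sample_counts(integer(0), character(0), meta2),
               "empty label")
  expect_error(cluster_sample_counts(1, "Z", meta2), "unknown sample")
})

test_that("column sums equal independent per-sample tallies", {
  set.seed(41)
  meta <- sample_metadata(sprintf("S%d", 1:6), day = c(15, 16, 17, 22, 23, 24))
  samples <- sample(meta$sample_id, 500, replace = TRUE)
  labels <- sample(1:7, 500, replace = TRUE)
  tab <- cluster_sample_counts(labels, samples, meta)
  expect_equal(colSums(tab$counts), table(factor(samples, meta$sample_id))[],
               ignore_attr = TRUE)
  expect_equal(sum(tab$counts), 500)
})

test_that("sample metadata derives time2 from the day-20 split", {
  meta <- sample_metadata(c("a", "b", "c"), day = c(20, 21, 15))
  expect_equal(meta$time2, c(0L, 1L, 0L))
  expect_error(sample_metadata(c("a", "a")), "duplicate")
})

sim_tab <- function(effect, seed, k = 10, spc = 8, cps = 2000, ...) {
  e <- rep(0, k)
  e[1] <- effect
  simulate_abundance(n_clusters = k, samples_per_condition = spc,
                     cells_per_sample = cps, effect = e, seed = seed, ...)
}

test_that("testing an empty coefficient set gives statistic 0 and p 1", {
  tab <- sim_tab(0, seed = 42)
  for (fn in list(nb_glm_lrt, nb_glm_ql)) {
    res <- fn(tab, "time2", coef = integer(0))
    expect_true(all(res$stat == 0))
    expect_true(all(res$p == 1))
  }
})

test_that("an all-zero cluster row is flagged with p = 1", {
  tab <- sim_tab(0, seed = 43)
  tab$counts[3, ] <- 0L
  res <- nb_glm_lrt(tab, "time2")
  expect_true(res$all_zero[3])
  expect_equal(res$p[3], 1)
  expect_true(all(res$q >= res$p | abs(res$q - res$p) < 1e-12))
})

test_that("q-values are a monotone BH transform of p-values", {
  tab <- sim_tab(log(2), seed = 44)
  res <- nb_glm_lrt(tab, "time2")
  expect_equal(res$q, p.adjust(res$p, "BH"))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("the LRT statistic is invariant to rescaling the offset", {
  tab <- sim_tab(log(3), seed = 45)
  base <- nb_glm_lrt(tab, "time2")
  scaled <- nb_glm_lrt(tab, "time2", lib_size = 7 * colSums(tab$counts))
  # invariance is exact at fixed dispersion; the common-dispersion
  # estimate itself moves by O(1e-4), hence the loose comparison
  expect_equal(scaled$stat, base$stat, tolerance = 1e-3)
  expect_equal(scaled$p, base$p, tolerance = 1e-3)
})

test_that("results are permutation-equivariant in cluster order", {
  tab <- sim_tab(log(3), seed = 46)
  res <- nb_glm_lrt(tab, "time2")
  perm <- sample(nrow(tab$counts))
  tab2 <- tab
  tab2$counts <- tab$counts[perm, , drop = FALSE]
  res2 <- nb_glm_lrt(tab2, "time2")
  expect_equal(res2$stat, res$stat[perm], tolerance = 1e-8)
  expect_equal(res2$p, res$p[perm], tolerance = 1e-8)
})

test_that("QL needs a residual degree of freedom", {
  tab <- sim_tab(0, seed = 47, spc = 1) # 2 samples, 2-column design
  expect_error(nb_glm_ql(tab, "time2"), "residual df")
})

test_that("phase contrasts cover each level pair and match 1-df joint tests", {
  tab <- sim_tab(log(2), seed = 48)
  # metadata phases are 3/4 in condition 0 and 5 in condition 1
  pcs <- phase_contrasts(tab)
  expect_length(pcs, 3)
  expect_setequal(names(pcs), c("3_vs_4", "3_vs_5", "4_vs_5"))

  # with exactly 2 observed levels the pairwise test IS the joint test
  tab2 <- tab
  tab2$metadata$phase <- factor(ifelse(tab2$metadata$time2 == 1, 5, 4))
  joint <- nb_glm_lrt(tab2, "phase")
  pair <- phase_contrasts(tab2)
  expect_length(pair, 1)
  expect_equal(pair[[1]]$p, joint$p, tolerance = 1e-8)
})

test_that("the largest gap between phases 4 and 5 surfaces in the (4,5) contrast", {
  # cluster 1 proportion rises from phase 4 through 3 to 5, with the full
  # 3-fold jump sitting between phases 4 and 5
  set.seed(49)
  meta <- sample_metadata(sprintf("S%d", 1:12),
                          day = rep(c(16, 19, 23), each = 4),
                          phase = rep(c(3, 4, 5), each = 4))
  k <- 6
  prop_for <- function(shift) {
    p <- rep(1 / k, k) * exp(c(shift, rep(0, k - 1)))
    p / sum(p)
  }
  shift_of <- c("3" = log(3) / 2, "4" = 0, "5" = log(3))
  counts <- sapply(seq_len(12), function(s)
    rmultinom(1, 2000, prop_for(shift_of[[as.character(meta$phase[s])]])))
  dimnames(counts) <- list(1:k, meta$sample_id)
  tab <- structure(list(counts = counts, metadata = meta),
                   class = "AbundanceTable")
  pcs <- phase_contrasts(tab)
  p_for_cluster1 <- vapply(pcs, function(r) r$p[1], numeric(1))
  expect_equal(names(which.min(p_for_cluster1)), "4_vs_5")
  expect_lt(pcs[["4_vs_5"]]$q[1], 0.05)
})

test_that("QL flags no more clusters than LRT on shifted data", {
  n_lrt <- n_ql <- 0
  for (seed in 1:10) {
    tab <- sim_tab(log(3), seed = 700 + seed)
    n_lrt <- n_lrt + sum(nb_glm_lrt(tab, "time2")$q < 0.05)
    n_ql <- n_ql + sum(nb_glm_ql(tab, "time2")$q < 0.05)
  }
  expect_lte(n_ql, n_lrt)
})

test_that("declared phase levels without samples are skipped with a warning", {
  tab <- sim_tab(0, seed = 50)
  tab$metadata$phase <- factor(as.character(tab$metadata$phase),
                               levels = c("3", "4", "5", "9"))
  expect_warning(pcs <- phase_contrasts(tab), "9")
  expect_length(pcs, 3)
})
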