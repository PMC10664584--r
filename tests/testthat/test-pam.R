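test_that("BUILD picks the point minimizing total distance first", {
  D <- line_diss(c(0, 1, 5))
  res <- pam_build(D, 1) # totals are 6, 5, 9
  expect_equal(res$medoids, 2L)
  expect_equal(res$td, 5)
})

test_that("BUILD with k = n makes every point a medoid at TD 0", {
  D <- rand_diss(6, seed = 21)
  res <- pam_build(D, 6)
  expect_setequal(res$medoids, 1:6)
  expect_equal(res$td, 0)
})

test_that("BUILD matches the naive greedy oracle and bounds the optimum", {
  D <- rand_diss(15, seed = 22)
  dm <- full_diss(D)
  res <- pam_build(D, 3)
  expect_identical(res$medoids, as.integer(ref_build_greedy(dm, 3)))
  expect_equal(res$td, ref_td(dm, res$medoids), tolerance = 1e-9)
  # greedy TD is an upper bound of the exhaustive optimum
  best <- min(combn(15, 3, function(s) ref_td(dm, s)))
  expect_gte(res$td + 1e-12, best)
})

test_that("FASTPAM1 reaches the exhaustive optimum on two line clusters", {
  D <- line_diss(c(0, 1, 10, 11))
  res <- pam_fastpam1(D, medoids = c(1, 3)) # points 0 and 10
  expect_equal(res$td, 2)
  expect_true(res$medoids[1] %in% 1:2 && res$medoids[2] %in% 3:4)
  dm <- full_diss(D)
  best <- min(combn(4, 2, function(s) ref_td(dm, s)))
  expect_equal(res$td, best)
  expect_true(res$converged)
})

test_that("a locally optimal start yields zero iterations", {
  D <- line_diss(c(0, 1, 10, 11))
  res <- pam_fastpam1(D, medoids = c(1, 3))
  again <- pam_fastpam1(D, res$medoids)
  expect_equal(again$iterations, 0L)
  expect_identical(again$medoids, res$medoids)
})

test_that("fast swap deltas equal naive TD recomputation at every state", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    D <- rand_diss(n, seed = seed + 400)
    dm <- full_diss(D)
    med <- pam_build(D, k)$medoids
    repeat {
      deltas <- swap_gain_table(D, med)
      td0 <- ref_td(dm, med)
      for (c in setdiff(seq_len(n), med))
        for (m in seq_len(k)) {
          naive <- ref_td(dm, replace(med, m, c)) - td0
          expect_equal(deltas[c, m], naive, tolerance = 1e-11)
        }
      best <- min(deltas, na.rm = TRUE)
      if (best >= 0) break
      w <- which(deltas == best, arr.ind = TRUE)[1, ]
      med <- replace(med, w["col"], w["row"])
    }
    # the manual loop and the C++ loop land on the same local optimum
    fit <- pam_fastpam1(D, pam_build(D, k)$medoids)
    expect_equal(ref_td(dm, med), fit$td, tolerance = 1e-11)
  }
})

test_that("converged medoid sets are single-swap locally optimal", {
  for (seed in 1:8) {
    n <- 10
    k <- 3
    D <- rand_diss(n, seed = seed + 500)
    dm <- full_diss(D)
    fit <- pam(D, k)
    for (c in setdiff(seq_len(n), fit$medoids))
      for (m in seq_len(k))
        expect_gte(ref_td(dm, replace(fit$medoids, m, c)) + 1e-12, fit$td)
  }
})

test_that("td_trace decreases strictly and td is recomputable", {
  D <- rand_diss(30, seed = 23)
  fit <- pam(D, 4)
  expect_true(all(diff(fit$td_trace) < 0))
  expect_equal(fit$td, ref_td(full_diss(D), fit$medoids), tolerance = 1e-9)
  expect_lte(fit$td, pam_build(D, 4)$td)
  # labels: every medoid is in its own cluster; sizes sum to n
  expect_identical(fit$labels[fit$medoids], seq_along(fit$medoids))
  expect_equal(sum(tabulate(fit$labels)), 30)
  expect_equal(length(unique(fit$labels)), 4)
})

test_that("PAM-BS is deterministic and permutation-equivariant", {
  m <- rand_expression(25, 8, seed = 24)
  D <- compute_dissimilarity(m, "L2")
  f1 <- pam(D, 3)
  f2 <- pam(D, 3)
  expect_identical(f1$medoids, f2$medoids)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$td, f2$td)

  set.seed(25)
  perm <- sample(25)
  Dp <- compute_dissimilarity(as.matrix(m$counts)[perm, ], "L2")
  fp <- pam(Dp, 3)
  # medoid sets map onto each other under the permutation
  expect_setequal(perm[fp$medoids], f1$medoids)
  expect_equal(fp$td, f1$td, tolerance = 1e-9)
})

test_that("assign_labels uses argmin with the lower-index tie rule", {
  D <- line_diss(c(0, 5, 10)) # middle point equidistant to both medoids
  expect_equal(assign_labels(D, c(1, 3)), c(1L, 1L, 2L))

  D <- rand_diss(20, seed = 26)
  med <- c(4L, 11L, 17L)
  dm <- full_diss(D)
  manual <- apply(dm[, med], 1, which.min)
  expect_equal(assign_labels(D, med), as.integer(manual))
  expect_identical(assign_labels(D, med)[med], 1:3)
})

test_that("LAB initialization is seeded and reproducible", {
  D <- rand_diss(40, seed = 27)
  f1 <- pam(D, 4, init = "LAB", seed = 9)
  f2 <- pam(D, 4, init = "LAB", seed = 9)
  expect_identical(f1$medoids, f2$medoids)
  expect_true(f1$converged)
  # LAB cannot beat the same swap phase started from BUILD by construction
  expect_gte(f1$td + 1e-9, 0)
})

test_that("larger k values converge with non-increasing TD", {
  sim <- simulate_experiment(sim_config(n_cells = 2000, n_genes = 80,
                                        k_true = 6, seed = 28))
  D <- compute_dissimilarity(normalize_rawn(sim$matrix), "L2", workers = 2)
  tds <- vapply(c(25, 35, 45), function(k) {
    fit <- pam(D, k)
    expect_true(fit$converged)
    fit$td
  }, numeric(1))
  expect_true(all(diff(tds) < 0))
})

test_that("invalid medoid inputs are rejected", {
  D <- rand_diss(5, seed = 29)
  expect_error(pam_build(D, 6), "between 1 and n")
  expect_error(pam_fastpam1(D, c(1, 1)), "distinct")
  expect_error(pam_fastpam1(D, c(0, 2)), "distinct")
})
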