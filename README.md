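# pamcell

Memory-efficient **PAM (k-medoids) clustering** for single-cell RNA-seq and
**differential cell abundance** testing of the resulting clusters.

## The problem

Differential-abundance analysis of scRNA-seq data asks whether the *sizes* of
cell populations change with a phenotype (here: the day/phase of the
menstrual cycle in human endometrium). It needs three things:

1. a clustering of all cells that is deterministic and interpretable — PAM
   (Partitioning Around Medoids) minimizes
   `TD = Σᵢ d(xᵢ, x_mᵢ)`, the total dissimilarity of every cell to its
   nearest medoid, and the cluster centers are *actual cells*;
2. a way to make PAM feasible at 10⁴–10⁵ cells — the bottleneck is the
   pairwise dissimilarity matrix, which `pamcell` stores as a packed strict
   lower triangle (`n(n−1)/2` entries) with selectable single/double
   precision (single halves the memory: 6.7 GiB instead of 13.4 GiB at
   n = 60,000), computed by sparse-aware kernels that skip zero-zero
   components;
3. a count model for cluster-by-sample cell numbers — negative binomial GLMs
   with a log(total cells per sample) offset, tested by likelihood-ratio
   (chi-square) or quasi-likelihood (F) tests with Benjamini-Hochberg FDR
   control across clusters.

The clustering core is the deterministic **PAM-BS** combination: greedy
BUILD initialization followed by the FASTPAM1 swap phase, which scores every
(candidate, medoid) exchange in one pass over the cells using cached
nearest/second-nearest medoid distances and always applies the single best
swap. Cluster quality is assessed with silhouette widths
`s(i) = (b(i) − a(i)) / max(a(i), b(i))`, and an iterative filter can drop
the 15% lowest-silhouette cells per round until at least 60% of the
remaining cells have `s > 0.7`. Partition agreement is measured with the
Adjusted Rand Index.

## Worked example

Simulate a three-population tissue in which population 1 triples its
abundance after cycle day 20, cluster it, and test for the shift:

```r
library(pamcell)

sim <- simulate_experiment(sim_config(n_cells = 600, k_true = 3,
                                      condition_effect = c(log(3), 0, 0),
                                      seed = 42))
m   <- normalize_rawn(sim$matrix)                  # per-cell normalization
D   <- compute_dissimilarity(m, metric = "Pearson",
                             precision = "single", workers = 4)
fit <- pam(D, k = 3)                               # PAM-BS: BUILD + FASTPAM1
adjusted_rand_index(fit$labels, sim$labels)

tab <- cluster_sample_counts(fit$labels, sim$matrix$sample_of_cell,
                             sim$metadata)
nb_glm_lrt(tab, design = "time2")
```

Output:

```
ExpressionMatrix: 661 cells x 120 genes (48929 stored entries)
DissimilarityMatrix: n = 661, metric = Pearson, precision = single (218,130 packed entries)
PamResult: k = 3, n = 661, TD = 131.227, 1 swap iteration(s)
ARI vs ground truth: 1
SilhouetteResult: 661 cells, 3 clusters, mean s = 0.6913
AbundanceTable: 3 clusters x 8 samples (661 cells)
  cluster   estimate   dispersion     stat df            p            q
1       1  0.6906053 3.807124e-08 36.52243  1 1.509194e-09 4.527582e-09
2       2 -0.6222502 3.807124e-08 16.68036  1 4.423655e-05 4.423655e-05
3       3 -0.6887955 3.807124e-08 18.10090  1 2.095020e-05 3.142530e-05
```

Reading it: the clustering recovers the simulated populations exactly
(ARI = 1). Cluster 1's `estimate` is the natural-log fold change of its
*proportion* after day 20: with three equal clusters, tripling one shifts
its share from 1/3 to 3/5, so the estimand is `log(1.8) ≈ 0.59`; the fitted
0.69 is about one standard error away at this cell count, and the
complementary clusters shrink. All three q-values fall below the 0.05 FDR
threshold — with k = 3 every population's share changes, a consequence of
compositionality.

A command-line front end covering each stage
(`simulate qc normalize hvg dist pam silhouette filter counts da ari run`)
is installed at `inst/cli/pamcell`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pamcell", package = "pamcell"))')" run --out out/
```

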