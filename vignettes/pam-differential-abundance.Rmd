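---
title: "PAM clustering and differential cell abundance with pamcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAM clustering and differential cell abundance with pamcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamcell)
```

## The model

`pamcell` implements a complete differential-cell-abundance workflow for
single-cell RNA-seq, in three statistical layers.

**Clustering.** Given $n$ cells with expression profiles $x_1,\dots,x_n$ and
a dissimilarity $d$, PAM (k-medoids) selects $k$ cells as medoids
$M = \{x_{m_1},\dots,x_{m_k}\}$ minimizing the objective
$$TD = \sum_{i=1}^{n} d(x_i, x_{m_i}),$$
where $x_{m_i}$ is the medoid nearest to $x_i$. Unlike k-means, the cluster
representatives are actual cells, so a medoid can be inspected, annotated and
plotted like any other cell, and the method works from the dissimilarity
matrix alone — any of the three supported dissimilarities (Manhattan $L_1$,
Euclidean $L_2$, and the Pearson dissimilarity $1 - |r|$) can be plugged in
without touching the optimizer. The Pearson form deliberately folds perfect
anti-correlation onto 0: two cells with mirrored profiles measure the same
program and belong together for this purpose.

**Cluster assessment.** The silhouette width of cell $i$ in cluster $I$ is
$$s(i) = \frac{b(i) - a(i)}{\max\{a(i), b(i)\}} \quad (|C_I| > 1;\ s(i)=0
\text{ for singletons}),$$
with $a(i)$ the mean dissimilarity to the other members of $I$ and $b(i)$
the minimum over other clusters $J$ of the mean dissimilarity to the members
of $J$. Values near $+1$ indicate a cell well inside its cluster; values
near 0 a border case. The global mean silhouette guides the choice of
normalization, dissimilarity and $k$ (`silhouette_by_k()`); per-cell values
drive the iterative low-silhouette filter.

**Abundance.** After clustering, the cluster-by-sample table of cell counts
$y_{cs}$ is modeled as negative binomial with log link,
$$\log \mu_{cs} = \beta_{c0} + x_s^\top \beta_c + \log N_s,$$
where $N_s$ is the total number of clustered cells of sample $s$. The offset
makes the coefficients log fold changes of cluster *proportions* — cluster
counts are compositional within a sample, so the sample's cell total is the
natural exposure and no further normalization factors are applied. Supported
designs are a numeric day-of-cycle covariate (`time`), the binary split at
day 20 (`time2`, 0 for day ≤ 20), and a treatment-coded categorical `phase`
with the lowest level as reference (tested jointly on its two dummy
coefficients and, via `phase_contrasts()`, pairwise). Inference is by
likelihood-ratio chi-square or quasi-likelihood F tests with
Benjamini–Hochberg adjustment across clusters and a q < 0.05 significance
convention; fitting and dispersion estimation are delegated to edgeR, whose
likelihood and quasi-likelihood machinery is exactly the procedure this
workflow calls for, with the common Cox–Reid dispersion as the default and
tagwise shrinkage as an option. The QL test additionally accounts for
dispersion-estimation uncertainty and is the more conservative of the two;
expect it to flag a subset of the LRT's clusters.

## Algorithms

**BUILD** chooses the initial medoids greedily: the first is the cell with
the smallest total dissimilarity to all cells; each later one maximizes the
reduction of $TD$ given the current nearest-medoid distances. It is
deterministic and, in exchange for $O(kn^2)$ work, starts the swap phase
close to a good optimum.

**FASTPAM1** then improves the set one exchange at a time. Caching each
cell's distance to its nearest ($d_{nearest}$) and second-nearest
($d_{second}$) medoid lets a single $O(n)$ pass over the cells score the
swap of a candidate $x_c$ against *all* $k$ medoids simultaneously: a cell
re-attaches to $x_c$ whenever $d(x_c, \cdot)$ beats its current nearest, and
only the removal of its own medoid forces it to $\min(d(x_c,\cdot),
d_{second})$. Each iteration applies the single swap with the largest strict
$TD$ reduction and stops when none remains, so the trace of $TD$ values is
strictly decreasing and the result is a single-swap local optimum. The
combination (PAM-BS) is fully deterministic.

**LAB** is the optional fast initialization: each medoid is picked greedily
from a fresh random subsample of $10 + \lceil\sqrt{n}\rceil$ cells, with the
reduction evaluated on the subsample. It consumes the seed; BUILD does not.

Numerical choices, made once and applied everywhere:

* **Tie-breaking** (nearest medoid, BUILD candidate, best swap) is by lowest
  cell index (then lowest medoid position for swaps). PAM's determinism
  claim needs *some* total order; the index order is reproducible across
  platforms and worker counts.
* **Convergence** is strict $\Delta TD < 0$ in double precision — no epsilon
  threshold. A `max_iter` cap (default 1000, far above the observed 8–41
  iterations at $10^5$-cell scale) guards pathological inputs; hitting it
  flags the result as non-converged.
* **Assignment invariant**: every reported $TD$ is recomputable from the
  matrix and the medoid set to within 1e-9 relative, and the tests enforce
  that the incremental swap deltas equal naive recomputation exhaustively at
  small $n$.

## The packed dissimilarity store

All $n(n-1)/2$ pairwise values are kept in a strict-lower-triangular,
row-major array: $d(i,j)$ with $i > j$ (zero-based) lives at offset
$i(i-1)/2 + j$. The diagonal is implicit and symmetry is by construction.
Two storage precisions are offered: `double`, and `single`, which rounds
each finished entry to the nearest IEEE single — *storage* is what dominates
memory at scale (6.7 GiB vs 13.4 GiB at $n = 60{,}000$), so accumulation
always runs in double and only the stored value is narrowed. The on-disk
format mirrors this: 8 magic bytes, a precision tag byte (4 or 8), $n$ as an
8-byte little-endian integer, then the packed payload; reading back is
bit-exact.

Sparse inputs are exploited by merging the two cells' nonzero component
lists in ascending gene order and skipping components that are zero in both.
Because adding an exact 0.0 to an IEEE accumulator is the identity and the
visit order is unchanged, the sparse kernel is bit-identical to the dense
reference loop (`engine = "dense"`), which the tests assert. Parallel work
division follows an equal-pairs contract: the linearized pair range is cut
into `workers` contiguous chunks of equal size (±1), so threads finish
together; since every pair is computed independently, results are
bit-identical for any worker count. The Pearson kernel precomputes per-cell
sums and centered sums of squares so the zero-zero bypass also applies to a
centered statistic; cells with constant expression have no defined
correlation and get $d = 1$ (or 0 against an identical constant cell) with a
warning.

## Preprocessing

QC keeps cells with ≥ 2500 total counts, ≥ 750 detected genes and ≤ 25%
mitochondrial counts (prefix `MT-`, case-insensitive, configurable) — the
conventional droplet thresholds; the filter is idempotent and reports
removals per criterion. Two per-cell normalizations are provided: `rawn`
divides each count by the cell total, `log1n` divides $\log(1+x)$ by the
cell's total of logged values (natural logarithm); both produce rows summing
to 1 and preserve sparsity. The `log1n` reading — renormalize *after* the
log transform — parallels `rawn` exactly; the alternative reading (log of
the `rawn` values) would break row-sum normalization and was rejected.
HVG selection ranks genes by vst-style standardized variance: a loess trend
(span 0.3, degree 2) of $\log_{10}$ variance on $\log_{10}$ mean gives each
gene an expected standard deviation; values are standardized, clipped above
at $\sqrt{n}$, and the variance of the clipped values is the rank statistic.
Externally computed HVG lists can be supplied as plain text instead, which
is the contract-safe path when exact agreement with another tool matters.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates discrete cell populations with private
marker genes (negative binomial counts, variance $\mu + \phi\mu^2$,
multiplicative marker effects, default $e^{3}\approx 20$-fold on 10 markers
per population over a base mean of 1), log-normal per-sample cell numbers
around the target, and condition-dependent cluster probabilities via a
softmax shift on the binary `time2` phenotype. Defaults (600 cells, 120
genes, 3 populations, 4 samples per condition) describe a small,
well-separated tissue: strong enough structure that an end-to-end run should
recover the truth (ARI ≥ 0.9), small enough to keep the full suite fast.
`simulate_abundance()` generates the count table directly — multinomial
per sample (the same abundance model), or negative binomial with
extra-multinomial noise — and records the *realized* per-cluster proportion
log-ratios as `true_beta`: under a softmax shift of $\delta$ on one of $k$
clusters the estimand of the offset model is
$\log\!\big(e^{\delta}/(1 + (e^{\delta}-1)/k)\big)$, not $\delta$ itself,
because the remaining proportions renormalize. Parameter-recovery tests
compare against `true_beta` for exactly this reason.

None of the generators model ambient RNA, doublets, batch effects, library
QC failures or continuous (trajectory-like) states. Passing tests therefore
demonstrate algorithmic correctness under clean compositional shifts, not
robustness to real-data artifacts; on real data the QC filter, HVG choice,
normalization and dissimilarity all materially affect the clustering, and
the silhouette scan is the built-in guide for those choices.

## Simulation sizes used by the test suite

The statistical acceptance checks run at a deliberately modest scale chosen
to keep the full suite under a minute of NB fitting: the null calibration
uses 200 replicates of 10 clusters × 16 samples × 2000 cells (pooled raw
p < 0.05 fraction must fall in [0.01, 0.10]); the power check uses 100
replicates of a 3-fold shift in 1 of 10 clusters (top-ranked with q < 0.05
in ≥ 90%); coefficient recovery uses 100 replicates at 8 + 8 samples
(|bias| < 0.05) plus RMSE comparisons at 6 and 24 samples per arm. The
swap-phase oracle checks are exhaustive at $n \le 12$, $k \le 3$ over 100
seeded draws; BUILD is checked against a naive greedy oracle at $n \le 50$.

## Known limitations

* The phase model requires at least two observed levels and skips declared
  levels with no samples; heavily unbalanced phases can make the joint test
  and the pairwise contrasts disagree, which is a property of the design,
  not of the implementation.
* With few clusters the compositional offset makes "one cluster shifted"
  indistinguishable from "all clusters shifted" — see the worked example in
  the README, where k = 3 renders every proportion significant.
* FASTPAM1 finds a single-swap local optimum, not the global one; BUILD
  starts it well, but distinct dissimilarities or normalizations can land in
  different optima. The eager-swapping FASTPAM variant and subsampled PAM
  (CLARA-style) are out of scope, as is automatic selection of $k$.
* Single-precision storage is an accuracy trade: entries are exact to ~7
  significant digits, which leaves well-separated medoid sets unchanged (the
  tests assert this) but can perturb near-ties.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_experiment(sim_config(seed = 42,
                                      condition_effect = c(log(3), 0, 0)))
m   <- normalize_rawn(sim$matrix)
D   <- compute_dissimilarity(m, metric = "Pearson", workers = 4)
fit <- pam(D, k = 3)
adjusted_rand_index(fit$labels, sim$labels)

sil <- silhouette(D, fit$labels)
tab <- cluster_sample_counts(fit$labels, sim$matrix$sample_of_cell,
                             sim$metadata)
nb_glm_lrt(tab, design = "time2")
```

The README shows this run's actual output and how to read it.
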