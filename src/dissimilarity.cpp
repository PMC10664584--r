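#include <Rcpp.h>
#include <cmath>
#include <climits>
#include <algorithm>
#include <vector>
#include "packed.h"

#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

// Metric codes shared with the R wrapper.
enum { METRIC_L1 = 0, METRIC_L2 = 1, METRIC_PEARSON = 2 };

// Per-cell summary statistics used by the Pearson kernel. Sums are taken in
// ascending gene order so the sparse and dense paths accumulate identically.
struct CellStats {
    double sum;    // sum of components
    double css;    // centered sum of squares: sum(x^2) - sum(x)^2 / p
    bool   is_const;
    double const_val;
};

static void cell_stats(const int *pp, const int *ii, const double *xx,
                       int p_genes, int cell, CellStats &st) {
    double s = 0.0, sq = 0.0;
    int nnz = pp[cell + 1] - pp[cell];
    double mn = R_PosInf, mx = R_NegInf;
    for (int k = pp[cell]; k < pp[cell + 1]; ++k) {
        double v = xx[k];
        s += v;
        sq += v * v;
        if (v < mn) mn = v;
        if (v > mx) mx = v;
    }
    st.sum = s;
    st.css = sq - s * s / (double)p_genes;
    if (nnz == 0) {
        st.is_const = true;  st.const_val = 0.0;
    } else if (nnz == p_genes && mn == mx) {
        st.is_const = true;  st.const_val = mn;
    } else {
        st.is_const = false; st.const_val = NA_REAL;
    }
}

// One pair, sparse columns merged in ascending gene order. Components that
// are zero in both cells contribute an exact 0.0 under every metric, so
// skipping them leaves each partial sum bit-identical to the dense loop.
static double pair_kernel_sparse(const int *pp, const int *ii, const double *xx,
                                 int a, int b, int metric) {
    int ka = pp[a], ea = pp[a + 1];
    int kb = pp[b], eb = pp[b + 1];
    double acc = 0.0;
    while (ka < ea || kb < eb) {
        int ra = (ka < ea) ? ii[ka] : INT_MAX;
        int rb = (kb < eb) ? ii[kb] : INT_MAX;
        double va, vb;
        if (ra < rb)      { va = xx[ka++]; vb = 0.0; }
        else if (rb < ra) { va = 0.0;      vb = xx[kb++]; }
        else              { va = xx[ka++]; vb = xx[kb++]; }
        if (metric == METRIC_L1)      acc += std::fabs(va - vb);
        else if (metric == METRIC_L2) acc += (va - vb) * (va - vb);
        else                          acc += va * vb; // Pearson dot product
    }
    return acc;
}

// Dense reference path: visits every component, including zero-zero ones.
static double pair_kernel_dense(const std::vector<double> &col_a,
                                const std::vector<double> &col_b,
                                int p_genes, int metric) {
    double acc = 0.0;
    for (int g = 0; g < p_genes; ++g) {
        double va = col_a[g], vb = col_b[g];
        if (metric == METRIC_L1)      acc += std::fabs(va - vb);
        else if (metric == METRIC_L2) acc += (va - vb) * (va - vb);
        else                          acc += va * vb;
    }
    return acc;
}

static double finalize_pair(double acc, int i, int j, int metric, int p_genes,
                            const std::vector<CellStats> &st, int *const_hits) {
    if (metric == METRIC_L1) return acc;
    if (metric == METRIC_L2) return std::sqrt(acc);
    // Pearson: d = 1 - |r|
    const CellStats &si = st[i], &sj = st[j];
    if (si.is_const || sj.is_const) {
        ++(*const_hits);
        if (si.is_const && sj.is_const && si.const_val == sj.const_val)
            return 0.0;
        return 1.0;
    }
    double num = acc - si.sum * sj.sum / (double)p_genes;
    double den = std::sqrt(si.css * sj.css);
    double r = num / den;
    double d = 1.0 - std::fabs(r);
    if (d < 0.0) d = 0.0;
    if (d > 1.0) d = 1.0;
    return d;
}

// Counts (genes) x cells CSC matrix: each cell is one sparse column.
// Returns the packed strict lower triangle d(i, j), i > j, row-major.
// `workers` splits the linearized pair range into contiguous equal chunks
// (+-1 pair); every pair is computed independently in double precision, so
// the result is identical for any worker count. With `precision == 4` each
// finished entry is rounded to the nearest IEEE single before storage.
// [[Rcpp::export]]
List cpp_dissimilarity(IntegerVector p, IntegerVector i, NumericVector x,
                       int n_genes, int n_cells, int metric, int precision,
                       int workers, bool dense) {
    if (n_cells < 2) stop("need at least 2 cells");
    const int *pp = INTEGER(p);
    const int *ii = INTEGER(i);
    const double *xx = REAL(x);

    std::vector<CellStats> st(n_cells);
    if (metric == METRIC_PEARSON)
        for (int c = 0; c < n_cells; ++c) cell_stats(pp, ii, xx, n_genes, c, st[c]);

    // Dense reference columns are materialized only on request.
    std::vector< std::vector<double> > cols;
    if (dense) {
        cols.assign(n_cells, std::vector<double>(n_genes, 0.0));
        for (int c = 0; c < n_cells; ++c)
            for (int k = pp[c]; k < pp[c + 1]; ++k)
                cols[c][ii[k]] = xx[k];
    }

    const std::size_t npairs = (std::size_t)n_cells * (n_cells - 1) / 2;
    NumericVector out((R_xlen_t)npairs);
    double *od = REAL(out);

    if (workers < 1) workers = 1;
    if ((std::size_t)workers > npairs) workers = (int)npairs;
    std::vector<int> const_hits_by_chunk(workers, 0);

    // Chunk c covers packed indices [c*q + min(c,r), ...) of size q(+1),
    // q = npairs / workers, r = npairs % workers: equal pairs per worker.
    std::size_t q = npairs / workers, r = npairs % workers;

#ifdef _OPENMP
#pragma omp parallel for schedule(static) num_threads(workers)
#endif
    for (int c = 0; c < workers; ++c) {
        std::size_t beg = (std::size_t)c * q + std::min((std::size_t)c, r);
        std::size_t end = beg + q + ((std::size_t)c < r ? 1 : 0);
        // Recover (row, col) of the first pair of the chunk.
        std::size_t t = beg;
        int row = (int)((1.0 + std::sqrt(1.0 + 8.0 * (double)t)) / 2.0);
        while (packed_offset((std::size_t)row, 0) > t) --row;
        while (packed_offset((std::size_t)row + 1, 0) <= t) ++row;
        int col = (int)(t - packed_offset((std::size_t)row, 0));
        for (; t < end; ++t) {
            double acc = dense
                ? pair_kernel_dense(cols[row], cols[col], n_genes, metric)
                : pair_kernel_sparse(pp, ii, xx, row, col, metric);
            double d = finalize_pair(acc, row, col, metric, n_genes, st,
                                     &const_hits_by_chunk[c]);
            od[t] = (precision == 4) ? (double)(float)d : d;
            if (++col == row) { ++row; col = 0; }
        }
    }

    int const_hits = 0;
    for (int c = 0; c < workers; ++c) const_hits += const_hits_by_chunk[c];
    return List::create(_["data"] = out, _["n_constant_pairs"] = const_hits);
}

// [[Rcpp::export]]
NumericVector cpp_subset_packed(NumericVector d, int n, IntegerVector idx) {
    int m = idx.size();
    const double *dd = REAL(d);
    NumericVector out((R_xlen_t)m * (m - 1) / 2);
    double *od = REAL(out);
    std::size_t t = 0;
    for (int a = 1; a < m; ++a)
        for (int b = 0; b < a; ++b)
            od[t++] = packed_get(dd, idx[a], idx[b]);
    return out;
}

// Row i of the full symmetric matrix (zero diagonal), for R-side helpers.
// [[Rcpp::export]]
NumericVector cpp_diss_row(NumericVector d, int n, int i) {
    const double *dd = REAL(d);
    NumericVector out(n);
    for (int j = 0; j < n; ++j) out[j] = packed_get(dd, i, j);
    return out;
}
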