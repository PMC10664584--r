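#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "packed.h"

using namespace Rcpp;

// Nearest / second-nearest medoid cache. Ties on distance go to the medoid
// with the lower cell index, which fixes the assignment deterministically.
static void update_cache(const double *d, int n, const std::vector<int> &med,
                         std::vector<double> &dnear, std::vector<double> &dsec,
                         std::vector<int> &nearest) {
    int k = (int)med.size();
    for (int j = 0; j < n; ++j) {
        double b1 = R_PosInf, b2 = R_PosInf;
        int p1 = -1, p2 = -1;
        for (int m = 0; m < k; ++m) {
            double dist = packed_get(d, j, med[m]);
            bool better = dist < b1 || (dist == b1 && (p1 < 0 || med[m] < med[p1]));
            if (better) {
                b2 = b1; p2 = p1;
                b1 = dist; p1 = m;
            } else if (dist < b2 || (dist == b2 && (p2 < 0 || med[m] < med[p2]))) {
                b2 = dist; p2 = m;
            }
        }
        dnear[j] = b1; dsec[j] = b2; nearest[j] = p1;
    }
}

// BUILD (greedy initialization): the first medoid minimizes the sum of
// distances to all points; each later medoid maximizes the TD reduction
// given the current nearest-medoid distances. Ties -> lowest cell index.
// [[Rcpp::export]]
List cpp_pam_build(NumericVector dpacked, int n, int k) {
    const double *d = REAL(dpacked);
    std::vector<int> med;
    med.reserve(k);
    std::vector<double> dnear(n, R_PosInf);
    std::vector<double> td_trace;

    // first medoid
    double best = R_PosInf;
    int bi = -1;
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) s += packed_get(d, i, j);
        if (s < best) { best = s; bi = i; }
    }
    med.push_back(bi);
    double td = 0.0;
    for (int j = 0; j < n; ++j) {
        dnear[j] = packed_get(d, j, bi);
        td += dnear[j];
    }
    td_trace.push_back(td);

    while ((int)med.size() < k) {
        double best_red = R_NegInf;
        int bc = -1;
        for (int c = 0; c < n; ++c) {
            bool is_med = false;
            for (size_t m = 0; m < med.size(); ++m)
                if (med[m] == c) { is_med = true; break; }
            if (is_med) continue;
            double red = 0.0;
            for (int j = 0; j < n; ++j) {
                double delta = dnear[j] - packed_get(d, c, j);
                if (delta > 0.0) red += delta;
            }
            if (red > best_red) { best_red = red; bc = c; }
        }
        med.push_back(bc);
        for (int j = 0; j < n; ++j) {
            double dj = packed_get(d, bc, j);
            if (dj < dnear[j]) dnear[j] = dj;
        }
        td -= best_red;
        td_trace.push_back(td);
    }

    // report TD recomputed from the cache (identical up to fp order)
    double td_exact = 0.0;
    for (int j = 0; j < n; ++j) td_exact += dnear[j];

    return List::create(_["medoids"] = wrap(med), _["d_nearest"] = wrap(dnear),
                        _["td"] = td_exact, _["td_trace"] = wrap(td_trace));
}

// Swap gain table used by FASTPAM1: delta_td[c][m] is the TD change of
// swapping candidate point c in for medoid med[m], computed in one pass
// over all points from the d_nearest / d_second cache.
static void swap_deltas_for_candidate(const double *d, int n, int c,
                                      const std::vector<int> &med,
                                      const std::vector<double> &dnear,
                                      const std::vector<double> &dsec,
                                      const std::vector<int> &nearest,
                                      std::vector<double> &delta) {
    int k = (int)med.size();
    double acc = 0.0;
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int j = 0; j < n; ++j) {
        double djc = packed_get(d, j, c);
        if (djc < dnear[j]) {
            // point j re-attaches to c no matter which medoid leaves
            acc += djc - dnear[j];
        } else {
            // only losing its own medoid matters
            double repl = (djc < dsec[j]) ? djc : dsec[j];
            delta[nearest[j]] += repl - dnear[j];
        }
    }
    for (int m = 0; m < k; ++m) delta[m] += acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_swap_deltas(NumericVector dpacked, int n, IntegerVector medoids) {
    const double *d = REAL(dpacked);
    std::vector<int> med(medoids.begin(), medoids.end());
    int k = (int)med.size();
    std::vector<double> dnear(n), dsec(n);
    std::vector<int> nearest(n);
    update_cache(d, n, med, dnear, dsec, nearest);

    NumericMatrix out(n, k);
    std::fill(out.begin(), out.end(), NA_REAL);
    std::vector<double> delta(k);
    for (int c = 0; c < n; ++c) {
        bool is_med = false;
        for (int m = 0; m < k; ++m) if (med[m] == c) { is_med = true; break; }
        if (is_med) continue;
        swap_deltas_for_candidate(d, n, c, med, dnear, dsec, nearest, delta);
        for (int m = 0; m < k; ++m) out(c, m) = delta[m];
    }
    return out;
}

// FASTPAM1: at each iteration evaluate every (candidate, medoid) swap via
// the cached d_nearest / d_second arrays and apply the single swap with the
// largest strict TD reduction. Ties -> lowest candidate cell index, then
// lowest medoid position. Stops when no swap has delta < 0.
// [[Rcpp::export]]
List cpp_fastpam1(NumericVector dpacked, int n, IntegerVector medoids0,
                  int max_iter) {
    const double *d = REAL(dpacked);
    std::vector<int> med(medoids0.begin(), medoids0.end());
    int k = (int)med.size();
    std::vector<double> dnear(n), dsec(n);
    std::vector<int> nearest(n);
    update_cache(d, n, med, dnear, dsec, nearest);

    double td = 0.0;
    for (int j = 0; j < n; ++j) td += dnear[j];
    std::vector<double> td_trace;
    td_trace.push_back(td);

    int iter = 0;
    bool converged = false;
    std::vector<double> delta(k);
    while (iter < max_iter) {
        double best_delta = 0.0;
        int bc = -1, bm = -1;
        for (int c = 0; c < n; ++c) {
            bool is_med = false;
            for (int m = 0; m < k; ++m) if (med[m] == c) { is_med = true; break; }
            if (is_med) continue;
            swap_deltas_for_candidate(d, n, c, med, dnear, dsec, nearest, delta);
            for (int m = 0; m < k; ++m) {
                if (delta[m] < best_delta) {
                    best_delta = delta[m];
                    bc = c; bm = m;
                }
            }
        }
        if (bc < 0) { converged = true; break; }
        med[bm] = bc;
        update_cache(d, n, med, dnear, dsec, nearest);
        td = 0.0;
        for (int j = 0; j < n; ++j) td += dnear[j];
        td_trace.push_back(td);
        ++iter;
    }
    if (iter >= max_iter && !converged) {
        // check once more whether the cap happened to land on a local optimum
        double best_delta = 0.0;
        for (int c = 0; c < n && best_delta >= 0.0; ++c) {
            bool is_med = false;
            for (int m = 0; m < k; ++m) if (med[m] == c) { is_med = true; break; }
            if (is_med) continue;
            swap_deltas_for_candidate(d, n, c, med, dnear, dsec, nearest, delta);
            for (int m = 0; m < k; ++m)
                if (delta[m] < best_delta) best_delta = delta[m];
        }
        converged = best_delta >= 0.0;
    }

    return List::create(_["medoids"] = wrap(med), _["td"] = td,
                        _["iterations"] = iter, _["td_trace"] = wrap(td_trace),
                        _["converged"] = converged);
}

// Nearest-medoid assignment; ties go to the medoid with the lower cell index.
// Returns 0-based positions into the medoid vector.
// [[Rcpp::export]]
IntegerVector cpp_assign(NumericVector dpacked, int n, IntegerVector medoids) {
    const double *d = REAL(dpacked);
    int k = medoids.size();
    IntegerVector labels(n);
    for (int j = 0; j < n; ++j) {
        double best = R_PosInf;
        int bp = -1;
        for (int m = 0; m < k; ++m) {
            double dist = packed_get(d, j, medoids[m]);
            if (dist < best || (dist == best && (bp < 0 || medoids[m] < medoids[bp]))) {
                best = dist; bp = m;
            }
        }
        labels[j] = bp;
    }
    return labels;
}
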