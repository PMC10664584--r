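#include <Rcpp.h>
#include <vector>
#include "packed.h"

using namespace Rcpp;

// Per-point silhouette width from the packed dissimilarity matrix.
// labels are 0-based cluster indices in [0, k). For point i in cluster I:
//   a(i) = mean d(i, j) over j in I, j != i        (0 if |I| == 1)
//   b(i) = min over J != I of mean d(i, j), j in J
//   s(i) = (b - a) / max(a, b), and 0 for singletons.
// [[Rcpp::export]]
NumericVector cpp_silhouette(NumericVector dpacked, int n, IntegerVector labels,
                             int k) {
    const double *d = REAL(dpacked);
    std::vector<int> size(k, 0);
    for (int j = 0; j < n; ++j) ++size[labels[j]];

    NumericVector s(n);
    std::vector<double> sums(k);
    for (int i = 0; i < n; ++i) {
        std::fill(sums.begin(), sums.end(), 0.0);
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            sums[labels[j]] += packed_get(d, i, j);
        }
        int li = labels[i];
        if (size[li] <= 1) { s[i] = 0.0; continue; }
        double a = sums[li] / (double)(size[li] - 1);
        double b = R_PosInf;
        for (int J = 0; J < k; ++J) {
            if (J == li || size[J] == 0) continue;
            double m = sums[J] / (double)size[J];
            if (m < b) b = m;
        }
        if (!R_FINITE(b)) { s[i] = 0.0; continue; } // single nonempty cluster
        double mx = (a > b) ? a : b;
        s[i] = (mx > 0.0) ? (b - a) / mx : 0.0;
    }
    return s;
}
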