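#ifndef PAMCELL_PACKED_H
#define PAMCELL_PACKED_H

#include <cstddef>

// Strict lower triangle, row-major: entry (i, j) with i > j lives at
// i*(i-1)/2 + j. Zero-based indices throughout the C++ layer.
inline std::size_t packed_offset(std::size_t i, std::size_t j) {
    return i * (i - 1) / 2 + j;
}

inline double packed_get(const double *d, int i, int j) {
    if (i == j) return 0.0;
    if (i < j) { int t = i; i = j; j = t; }
    return d[packed_offset((std::size_t)i, (std::size_t)j)];
}

#endif
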