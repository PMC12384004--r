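#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Index helpers for 3D arrays stored in R's column-major layout:
// linear = i + nx * (j + ny * k).

static inline int wrapIndex(int i, int n, int boundary) {
    if (i >= 0 && i < n) return i;
    if (boundary == 0) {                 // periodic
        i %= n;
        if (i < 0) i += n;
        return i;
    }
    // replicate (nearest edge)
    if (i < 0) return 0;
    return n - 1;
}

// Separable 1D filtering along one axis of a 3D volume.
// correlate = false: y[n] = sum_k taps[k] * x[n - (k - center)]
// correlate = true:  y[n] = sum_k taps[k] * x[n + (k - center)]
// boundary: 0 = periodic, 1 = replicate.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dim,
                            NumericVector taps, int axis, int center,
                            int boundary, bool correlate) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int L = taps.size();
    const int n[3] = {nx, ny, nz};
    const int na = n[axis];
    NumericVector out(x.size());
    const double *px = x.begin();
    double *pout = out.begin();

    // flip taps so that both modes reduce to a correlation with
    // offset range [lo, hi] around the output position
    std::vector<double> t(L);
    for (int k = 0; k < L; ++k)
        t[k] = correlate ? taps[k] : taps[L - 1 - k];
    const int lo = correlate ? -center : center - (L - 1);
    // y[n] = sum_k t[k] * x[n + lo + k]

    const int stride[3] = {1, nx, nx * ny};
    const int sa = stride[axis];
    // the two non-filtered axes
    const int axB = (axis == 0) ? 1 : 0;
    const int axC = (axis == 2) ? 1 : 2;
    const int nb = n[axB], nc = n[axC];
    const int sb = stride[axB], sc = stride[axC];

    std::vector<double> line(na + L);
    for (int c = 0; c < nc; ++c) {
        for (int b = 0; b < nb; ++b) {
            const int base = b * sb + c * sc;
            // gather the padded line: positions lo .. na-1+lo+L-1
            for (int p = 0; p < na + L; ++p) {
                const int src = wrapIndex(p + lo, na, boundary);
                line[p] = px[base + src * sa];
            }
            for (int pos = 0; pos < na; ++pos) {
                double acc = 0.0;
                const double *seg = &line[pos];
                for (int k = 0; k < L; ++k) acc += t[k] * seg[k];
                pout[base + pos * sa] = acc;
            }
        }
    }
    return out;
}

// Absolute (fixed bin width) discretization:
// level = floor(x/W) - floor(min_in_mask/W) + 1 inside the mask, else 0.
// [[Rcpp::export]]
List cpp_discretize(NumericVector x, LogicalVector mask, double W) {
    const R_xlen_t n = x.size();
    IntegerVector lev(n, 0);
    const double *px = x.begin();
    const int *pm = mask.begin();
    int *pl = lev.begin();
    double mn = R_PosInf;
    for (R_xlen_t s = 0; s < n; ++s)
        if (pm[s] && px[s] < mn) mn = px[s];
    if (!R_FINITE(mn)) stop("mask selects no voxels");
    const double off = std::floor(mn / W);
    int mx = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!pm[s]) continue;
        const int l = (int)(std::floor(px[s] / W) - off) + 1;
        pl[s] = l;
        if (l > mx) mx = l;
    }
    return List::create(_["levels"] = lev, _["nLevels"] = mx);
}

// Gray level co-occurrence counts, symmetrized, pooled over the given
// offsets. levels: 0 outside mask, 1..ng inside.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, IntegerVector dim,
                              int ng, IntegerMatrix offsets) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix counts(ng, ng);
    double *pc = counts.begin();
    const int *pl = levels.begin();
    const int nOff = offsets.nrow();
    for (int o = 0; o < nOff; ++o) {
        const int oi = offsets(o, 0), oj = offsets(o, 1), ok = offsets(o, 2);
        const int i0 = std::max(0, -oi), i1 = std::min(nx, nx - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(ny, ny - oj);
        const int k0 = std::max(0, -ok), k1 = std::min(nz, nz - ok);
        const int shift = oi + nx * (oj + ny * ok);
        for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
                const int rowBase = nx * (j + ny * k);
                for (int i = i0; i < i1; ++i) {
                    const int li = pl[rowBase + i];
                    if (li == 0) continue;
                    const int lj = pl[rowBase + i + shift];
                    if (lj == 0) continue;
                    pc[(li - 1) + ng * (lj - 1)] += 1.0;
                    pc[(lj - 1) + ng * (li - 1)] += 1.0;
                }
            }
        }
    }
    return counts;
}

// Gray level dependence counts: for every in-mask voxel of level i,
// dependence j = 1 + number of neighbours within Chebyshev distance
// <= dist whose level differs by at most alpha (out-of-mask neighbours
// are not dependent). Returns an ng x (maxNeighbours + 1) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dim,
                              int ng, int alpha, int dist) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int width = 2 * dist + 1;
    const int maxNb = width * width * width - 1;
    NumericMatrix counts(ng, maxNb + 1);
    const int *pl = levels.begin();
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const int li = pl[i + nx * (j + ny * k)];
                if (li == 0) continue;
                int dep = 0;
                const int kA = std::max(0, k - dist),
                          kB = std::min(nz - 1, k + dist);
                const int jA = std::max(0, j - dist),
                          jB = std::min(ny - 1, j + dist);
                const int iA = std::max(0, i - dist),
                          iB = std::min(nx - 1, i + dist);
                for (int kk = kA; kk <= kB; ++kk) {
                    for (int jj = jA; jj <= jB; ++jj) {
                        const int rb = nx * (jj + ny * kk);
                        for (int ii = iA; ii <= iB; ++ii) {
                            if (ii == i && jj == j && kk == k) continue;
                            const int lj = pl[rb + ii];
                            if (lj == 0) continue;
                            if (std::abs(lj - li) <= alpha) ++dep;
                        }
                    }
                }
                counts(li - 1, dep) += 1.0;
            }
        }
    }
    return counts;
}

// 26-connected labelling of equal-level zones inside the mask
// (levels == 0 marks background). Labels start at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_zones(IntegerVector levels, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int nvox = nx * ny * nz;
    IntegerVector lab(nvox, 0);
    int *pb = lab.begin();
    const int *pl = levels.begin();
    std::vector<int> stack;
    int next = 0;
    for (int s = 0; s < nvox; ++s) {
        if (pl[s] == 0 || pb[s] != 0) continue;
        ++next;
        const int lev = pl[s];
        pb[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            const int cur = stack.back();
            stack.pop_back();
            const int ci = cur % nx;
            const int cj = (cur / nx) % ny;
            const int ck = cur / (nx * ny);
            const int kA = std::max(0, ck - 1), kB = std::min(nz - 1, ck + 1);
            const int jA = std::max(0, cj - 1), jB = std::min(ny - 1, cj + 1);
            const int iA = std::max(0, ci - 1), iB = std::min(nx - 1, ci + 1);
            for (int kk = kA; kk <= kB; ++kk) {
                for (int jj = jA; jj <= jB; ++jj) {
                    const int rb = nx * (jj + ny * kk);
                    for (int ii = iA; ii <= iB; ++ii) {
                        const int nbv = rb + ii;
                        if (nbv != cur && pb[nbv] == 0 && pl[nbv] == lev) {
                            pb[nbv] = next;
                            stack.push_back(nbv);
                        }
                    }
                }
            }
        }
    }
    return lab;
}
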