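#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// index helpers for 3D arrays stored in R's column-major order
static inline int at(int i, int j, int k, const int* d) {
    return i + d[0] * (j + d[1] * k);
}

// mirror (reflect-with-edge-repeat) index: ... 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int refl(int i, int n) {
    while (i < 0 || i >= n) {
        if (i < 0) i = -1 - i;
        if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
}

// separable correlation along one axis (0,1,2) with mirror boundaries
// [[Rcpp::export]]
NumericVector conv_axis_mirror(NumericVector arr, NumericVector kernel, int axis) {
    IntegerVector dv = arr.attr("dim");
    int d[3] = {dv[0], dv[1], dv[2]};
    int n = d[axis];
    int kl = kernel.size();
    int r = (kl - 1) / 2;
    NumericVector out(arr.size());
    out.attr("dim") = dv;
    for (int k = 0; k < d[2]; ++k) {
        for (int j = 0; j < d[1]; ++j) {
            for (int i = 0; i < d[0]; ++i) {
                double s = 0.0;
                int idx[3] = {i, j, k};
                int base = idx[axis];
                for (int t = 0; t < kl; ++t) {
                    idx[axis] = refl(base + t - r, n);
                    s += kernel[t] * arr[at(idx[0], idx[1], idx[2], d)];
                }
                idx[axis] = base;
                out[at(idx[0], idx[1], idx[2], d)] = s;
            }
        }
    }
    return out;
}

// symmetric grey-level co-occurrence counts for one offset; bins: 3D int
// array with 0 = outside VOI, 1..nbins inside. Both voxels of a pair must
// be inside the VOI; each pair increments (a,b) and (b,a).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector bins, IntegerVector offset, int nbins) {
    IntegerVector dv = bins.attr("dim");
    int d[3] = {dv[0], dv[1], dv[2]};
    NumericMatrix m(nbins, nbins);
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                int a = bins[at(i, j, k, d)];
                if (a == 0) continue;
                int i2 = i + offset[0], j2 = j + offset[1], k2 = k + offset[2];
                if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
                    k2 < 0 || k2 >= d[2]) continue;
                int b = bins[at(i2, j2, k2, d)];
                if (b == 0) continue;
                m(a - 1, b - 1) += 1.0;
                m(b - 1, a - 1) += 1.0;
            }
    return m;
}

// histogram of absolute bin differences over in-VOI pairs for one offset
// [[Rcpp::export]]
NumericVector cpp_gldm(IntegerVector bins, IntegerVector offset, int nbins) {
    IntegerVector dv = bins.attr("dim");
    int d[3] = {dv[0], dv[1], dv[2]};
    NumericVector h(nbins); // differences 0 .. nbins-1
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                int a = bins[at(i, j, k, d)];
                if (a == 0) continue;
                int i2 = i + offset[0], j2 = j + offset[1], k2 = k + offset[2];
                if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
                    k2 < 0 || k2 >= d[2]) continue;
                int b = bins[at(i2, j2, k2, d)];
                if (b == 0) continue;
                h[std::abs(a - b)] += 1.0;
            }
    return h;
}

// run-length counts along one direction; a run is a maximal same-bin
// sequence of VOI voxels (a VOI gap or grid edge terminates it)
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector bins, IntegerVector dir, int nbins) {
    IntegerVector dv = bins.attr("dim");
    int d[3] = {dv[0], dv[1], dv[2]};
    int maxlen = std::max(std::max(d[0], d[1]), d[2]);
    NumericMatrix m(nbins, maxlen);
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                int a = bins[at(i, j, k, d)];
                if (a == 0) continue;
                // run start iff predecessor along dir is outside grid/VOI
                // or has a different bin
                int ip = i - dir[0], jp = j - dir[1], kp = k - dir[2];
                bool start = true;
                if (ip >= 0 && ip < d[0] && jp >= 0 && jp < d[1] &&
                    kp >= 0 && kp < d[2]) {
                    if (bins[at(ip, jp, kp, d)] == a) start = false;
                }
                if (!start) continue;
                int len = 1;
                int in = i + dir[0], jn = j + dir[1], kn = k + dir[2];
                while (in >= 0 && in < d[0] && jn >= 0 && jn < d[1] &&
                       kn >= 0 && kn < d[2] &&
                       bins[at(in, jn, kn, d)] == a) {
                    ++len;
                    in += dir[0]; jn += dir[1]; kn += dir[2];
                }
                m(a - 1, len - 1) += 1.0;
            }
    return m;
}

// 26-connected same-bin zones; returns a matrix with one row per zone:
// (grey level, zone size)
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector bins) {
    IntegerVector dv = bins.attr("dim");
    int d[3] = {dv[0], dv[1], dv[2]};
    int n = bins.size();
    std::vector<char> seen(n, 0);
    std::vector<int> lev, siz;
    std::vector<int> stack;
    for (int s0 = 0; s0 < n; ++s0) {
        if (seen[s0] || bins[s0] == 0) continue;
        int a = bins[s0];
        int size = 0;
        stack.clear();
        stack.push_back(s0);
        seen[s0] = 1;
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            ++size;
            int i = v % d[0];
            int j = (v / d[0]) % d[1];
            int k = v / (d[0] * d[1]);
            for (int dk = -1; dk <= 1; ++dk)
                for (int dj = -1; dj <= 1; ++dj)
                    for (int di = -1; di <= 1; ++di) {
                        if (di == 0 && dj == 0 && dk == 0) continue;
                        int i2 = i + di, j2 = j + dj, k2 = k + dk;
                        if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
                            k2 < 0 || k2 >= d[2]) continue;
                        int w = at(i2, j2, k2, d);
                        if (!seen[w] && bins[w] == a) {
                            seen[w] = 1;
                            stack.push_back(w);
                        }
                    }
        }
        lev.push_back(a);
        siz.push_back(size);
    }
    IntegerMatrix out(lev.size(), 2);
    for (size_t r = 0; r < lev.size(); ++r) {
        out(r, 0) = lev[r];
        out(r, 1) = siz[r];
    }
    return out;
}

// neighbourhood grey-tone difference table: per grey level, the voxel
// count n_i and summed |value - neighbourhood mean| s_i; neighbourhood
// is the 26 surrounding voxels intersected with the VOI; voxels with no
// valid neighbour are excluded
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector bins, int nbins) {
    IntegerVector dv = bins.attr("dim");
    int d[3] = {dv[0], dv[1], dv[2]};
    NumericMatrix out(nbins, 2); // columns: n_i, s_i
    for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
            for (int i = 0; i < d[0]; ++i) {
                int a = bins[at(i, j, k, d)];
                if (a == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dk = -1; dk <= 1; ++dk)
                    for (int dj = -1; dj <= 1; ++dj)
                        for (int di = -1; di <= 1; ++di) {
                            if (di == 0 && dj == 0 && dk == 0) continue;
                            int i2 = i + di, j2 = j + dj, k2 = k + dk;
                            if (i2 < 0 || i2 >= d[0] || j2 < 0 ||
                                j2 >= d[1] || k2 < 0 || k2 >= d[2]) continue;
                            int b = bins[at(i2, j2, k2, d)];
                            if (b == 0) continue;
                            sum += b;
                            ++cnt;
                        }
                if (cnt == 0) continue;
                out(a - 1, 0) += 1.0;
                out(a - 1, 1) += std::fabs((double)a - sum / cnt);
            }
    return out;
}
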