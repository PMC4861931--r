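#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Arrays are R 3D arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x).

static void conv_line(const double* in, double* out, int L, R_xlen_t stride,
                      const double* k, int kr, bool renorm) {
    for (int i = 0; i < L; ++i) {
        double acc = 0.0, wsum = 0.0;
        int jlo = std::max(-kr, -i), jhi = std::min(kr, L - 1 - i);
        for (int j = jlo; j <= jhi; ++j) {
            double w = k[j + kr];
            acc += w * in[(R_xlen_t)(i + j) * stride];
            wsum += w;
        }
        out[(R_xlen_t)i * stride] = (renorm && wsum > 0.0) ? acc / wsum : acc;
    }
}

// Convolve along the slowest axis of a block-structured array: the axis has
// length L, each position owning a contiguous block of `blocksz` doubles.
// Accumulating whole blocks keeps the memory access streaming.
static void conv_axis_outer(const double* in, double* out, int L,
                            R_xlen_t blocksz, const double* k, int kr,
                            bool renorm) {
    for (int i = 0; i < L; ++i) {
        double* o = out + (R_xlen_t)i * blocksz;
        std::fill(o, o + blocksz, 0.0);
        double wsum = 0.0;
        int jlo = std::max(-kr, -i), jhi = std::min(kr, L - 1 - i);
        for (int j = jlo; j <= jhi; ++j) {
            double w = k[j + kr];
            wsum += w;
            const double* p = in + (R_xlen_t)(i + j) * blocksz;
            for (R_xlen_t t = 0; t < blocksz; ++t) o[t] += w * p[t];
        }
        if (renorm && wsum > 0.0 && wsum != 1.0)
            for (R_xlen_t t = 0; t < blocksz; ++t) o[t] /= wsum;
    }
}

// Separable convolution along z, y, x with odd-length kernels.
// renorm = TRUE divides by the in-bounds kernel mass at the borders, so a
// kernel normalized to sum 1 maps a flat image to itself exactly.
// [[Rcpp::export]]
NumericVector conv3d_sep_cpp(NumericVector arr, IntegerVector dims,
                             NumericVector kz, NumericVector ky,
                             NumericVector kx, bool renorm) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    if ((R_xlen_t)nz * ny * nx != arr.size())
        stop("array length does not match dims");
    NumericVector cur = clone(arr);
    NumericVector tmp(arr.size());
    double* a = REAL(cur);
    double* b = REAL(tmp);

    // z axis: stride 1, lines indexed by (y, x)
    if (kz.size() > 1 || kz[0] != 1.0) {
        int kr = ((int)kz.size() - 1) / 2;
        for (int x = 0; x < nx; ++x)
            for (int y = 0; y < ny; ++y) {
                R_xlen_t start = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
                conv_line(a + start, b + start, nz, 1, REAL(kz), kr, renorm);
            }
        std::swap(a, b);
    }
    // y axis: within each contiguous x slab (nz * ny doubles), y is the
    // slowest index with blocks of nz
    if (ky.size() > 1 || ky[0] != 1.0) {
        int kr = ((int)ky.size() - 1) / 2;
        for (int x = 0; x < nx; ++x) {
            R_xlen_t off = (R_xlen_t)nz * ny * x;
            conv_axis_outer(a + off, b + off, ny, nz, REAL(ky), kr, renorm);
        }
        std::swap(a, b);
    }
    // x axis: slowest index overall, blocks of nz * ny
    if (kx.size() > 1 || kx[0] != 1.0) {
        int kr = ((int)kx.size() - 1) / 2;
        conv_axis_outer(a, b, nx, (R_xlen_t)nz * ny, REAL(kx), kr, renorm);
        std::swap(a, b);
    }
    NumericVector out = (a == REAL(cur)) ? cur : tmp;
    out.attr("dim") = dims;
    return out;
}

// 26-connected component labeling of a logical mask. Labels are assigned in
// raster order of each component's first-encountered voxel, starting at 1,
// so the labeling is deterministic.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (n != mask.size()) stop("mask length does not match dims");
    IntegerVector labels(n, 0);
    const int* m = LOGICAL(mask);
    int* lab = INTEGER(labels);
    std::vector<R_xlen_t> stack;
    int next = 0;

    for (R_xlen_t idx = 0; idx < n; ++idx) {
        if (m[idx] != 1 || lab[idx] != 0) continue;
        ++next;
        lab[idx] = next;
        stack.push_back(idx);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int z = (int)(cur % nz);
            int y = (int)((cur / nz) % ny);
            int x = (int)(cur / ((R_xlen_t)nz * ny));
            for (int dx = -1; dx <= 1; ++dx) {
                int xx = x + dx;
                if (xx < 0 || xx >= nx) continue;
                for (int dy = -1; dy <= 1; ++dy) {
                    int yy = y + dy;
                    if (yy < 0 || yy >= ny) continue;
                    for (int dz = -1; dz <= 1; ++dz) {
                        int zz = z + dz;
                        if (zz < 0 || zz >= nz) continue;
                        R_xlen_t nb = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                        if (m[nb] == 1 && lab[nb] == 0) {
                            lab[nb] = next;
                            stack.push_back(nb);
                        }
                    }
                }
            }
        }
    }
    labels.attr("dim") = dims;
    return labels;
}

// Per-label summaries in one pass: voxel count, intensity sum, and
// intensity-weighted centroid sums in voxel index units, plus bounding box.
// [[Rcpp::export]]
List label_stats_cpp(IntegerVector labels, NumericVector intensity,
                     IntegerVector dims, int nlab) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (n != labels.size() || n != intensity.size())
        stop("length mismatch");
    IntegerVector count(nlab, 0);
    NumericVector isum(nlab, 0.0), wz(nlab, 0.0), wy(nlab, 0.0), wx(nlab, 0.0);
    IntegerVector z0(nlab, NA_INTEGER), z1(nlab, NA_INTEGER),
        y0(nlab, NA_INTEGER), y1(nlab, NA_INTEGER),
        x0(nlab, NA_INTEGER), x1(nlab, NA_INTEGER);
    const int* lab = INTEGER(labels);
    const double* val = REAL(intensity);
    for (R_xlen_t idx = 0; idx < n; ++idx) {
        int l = lab[idx];
        if (l <= 0) continue;
        int i = l - 1;
        int z = (int)(idx % nz);
        int y = (int)((idx / nz) % ny);
        int x = (int)(idx / ((R_xlen_t)nz * ny));
        double v = val[idx];
        count[i] += 1;
        isum[i] += v;
        wz[i] += v * z;
        wy[i] += v * y;
        wx[i] += v * x;
        if (z0[i] == NA_INTEGER || z < z0[i]) z0[i] = z;
        if (z1[i] == NA_INTEGER || z > z1[i]) z1[i] = z;
        if (y0[i] == NA_INTEGER || y < y0[i]) y0[i] = y;
        if (y1[i] == NA_INTEGER || y > y1[i]) y1[i] = y;
        if (x0[i] == NA_INTEGER || x < x0[i]) x0[i] = x;
        if (x1[i] == NA_INTEGER || x > x1[i]) x1[i] = x;
    }
    return List::create(_["count"] = count, _["isum"] = isum,
                        _["wz"] = wz, _["wy"] = wy, _["wx"] = wx,
                        _["z0"] = z0, _["z1"] = z1, _["y0"] = y0,
                        _["y1"] = y1, _["x0"] = x0, _["x1"] = x1);
}
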