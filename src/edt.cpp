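#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic voxel grid
// (separable lower-envelope algorithm, one pass per axis). In addition to
// the squared distance we propagate, per voxel, the grid coordinates of the
// nearest feature voxel so that callers can apply a voxel-surface
// correction along each axis independently.

static const double DT_INF = 1e30;

// 1-D transform of f (squared distances) sampled at spacing sqrt(h2).
// arg[p] receives the index q minimising f[q] + h2*(p-q)^2.
static void dt1d(const std::vector<double>& f, int n, double h2,
                 std::vector<double>& d, std::vector<int>& arg) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -DT_INF;
    z[1] = DT_INF;
    for (int q = 1; q < n; ++q) {
        double s = 0.0;
        while (true) {
            s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
                (2.0 * h2 * (q - v[k]));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        if (s <= z[k] && k == 0) {
            // q dominates everywhere
            v[0] = q;
            z[0] = -DT_INF;
            z[1] = DT_INF;
        } else {
            ++k;
            v[k] = q;
            z[k] = s;
            z[k + 1] = DT_INF;
        }
    }
    k = 0;
    for (int p = 0; p < n; ++p) {
        while (z[k + 1] < p) ++k;
        d[p] = h2 * (double)(p - v[k]) * (p - v[k]) + f[v[k]];
        arg[p] = v[k];
    }
}

// [[Rcpp::export(name = ".edt_anisotropic")]]
List edt_anisotropic_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector voxel) {
    int nd = dims.size();
    if (nd < 1 || nd > 3) stop("mask must have 1 to 3 dimensions");
    int nx = dims[0];
    int ny = nd >= 2 ? dims[1] : 1;
    int nz = nd >= 3 ? dims[2] : 1;
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");

    std::vector<double> d2(n);
    std::vector<int> fx(n), fy(n), fz(n);

    // seed: feature voxels at squared distance zero
    for (R_xlen_t i = 0; i < n; ++i) {
        d2[i] = mask[i] ? 0.0 : DT_INF;
        int x = (int)(i % nx);
        int y = (int)((i / nx) % ny);
        int z = (int)(i / ((R_xlen_t)nx * ny));
        fx[i] = x; fy[i] = y; fz[i] = z;
    }

    std::vector<double> fline, dline;
    std::vector<int> aline;

    // pass along x
    if (nx > 1) {
        double h2 = voxel[0] * voxel[0];
        fline.resize(nx); dline.resize(nx); aline.resize(nx);
        for (int z = 0; z < nz; ++z) {
            for (int y = 0; y < ny; ++y) {
                R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
                for (int x = 0; x < nx; ++x) fline[x] = d2[base + x];
                dt1d(fline, nx, h2, dline, aline);
                for (int x = 0; x < nx; ++x) {
                    R_xlen_t i = base + x;
                    R_xlen_t j = base + aline[x];
                    d2[i] = dline[x];
                    fx[i] = fx[j];  // = aline[x]
                }
            }
        }
    }

    // pass along y: features in other axes inherited from the argmin source
    if (ny > 1) {
        double h2 = voxel.size() >= 2 ? voxel[1] * voxel[1] : 1.0;
        fline.resize(ny); dline.resize(ny); aline.resize(ny);
        std::vector<int> fxl(ny);
        for (int z = 0; z < nz; ++z) {
            for (int x = 0; x < nx; ++x) {
                R_xlen_t base = (R_xlen_t)z * nx * ny + x;
                for (int y = 0; y < ny; ++y) {
                    R_xlen_t i = base + (R_xlen_t)y * nx;
                    fline[y] = d2[i];
                    fxl[y] = fx[i];
                }
                dt1d(fline, ny, h2, dline, aline);
                for (int y = 0; y < ny; ++y) {
                    R_xlen_t i = base + (R_xlen_t)y * nx;
                    d2[i] = dline[y];
                    fx[i] = fxl[aline[y]];
                    fy[i] = aline[y];
                }
            }
        }
    }

    // pass along z
    if (nz > 1) {
        double h2 = voxel.size() >= 3 ? voxel[2] * voxel[2] : 1.0;
        fline.resize(nz); dline.resize(nz); aline.resize(nz);
        std::vector<int> fxl(nz), fyl(nz);
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) {
                R_xlen_t base = (R_xlen_t)y * nx + x;
                for (int z = 0; z < nz; ++z) {
                    R_xlen_t i = base + (R_xlen_t)z * nx * ny;
                    fline[z] = d2[i];
                    fxl[z] = fx[i];
                    fyl[z] = fy[i];
                }
                dt1d(fline, nz, h2, dline, aline);
                for (int z = 0; z < nz; ++z) {
                    R_xlen_t i = base + (R_xlen_t)z * nx * ny;
                    d2[i] = dline[z];
                    fx[i] = fxl[aline[z]];
                    fy[i] = fyl[aline[z]];
                    fz[i] = aline[z];
                }
            }
        }
    }

    NumericVector dist(n);
    IntegerVector FX(n), FY(n), FZ(n);
    bool any_feature = false;
    for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) { any_feature = true; break; }
    for (R_xlen_t i = 0; i < n; ++i) {
        dist[i] = any_feature ? std::sqrt(d2[i]) : R_PosInf;
        FX[i] = fx[i]; FY[i] = fy[i]; FZ[i] = fz[i];
    }
    return List::create(_["distance"] = dist, _["fx"] = FX, _["fy"] = FY,
                        _["fz"] = FZ);
}
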