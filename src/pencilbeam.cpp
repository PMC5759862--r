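#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear interpolation of a voxel-center-sampled volume at index-space
// coordinates (cx, cy, cz); values outside the volume contribute 0.
static inline double trilinear(const double *vol, const int *dim,
                               double cx, double cy, double cz) {
  int ix = (int)std::floor(cx), iy = (int)std::floor(cy),
      iz = (int)std::floor(cz);
  double fx = cx - ix, fy = cy - iy, fz = cz - iz;
  double out = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = ix + di;
    if (i < 0 || i >= dim[0]) continue;
    double wx = di ? fx : 1.0 - fx;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = iy + dj;
      if (j < 0 || j >= dim[1]) continue;
      double wy = dj ? fy : 1.0 - fy;
      for (int dk = 0; dk <= 1; ++dk) {
        int k = iz + dk;
        if (k < 0 || k >= dim[2]) continue;
        double wz = dk ? fz : 1.0 - fz;
        out += wx * wy * wz * vol[i + dim[0] * (j + (size_t)dim[1] * k)];
      }
    }
  }
  return out;
}

// Water-equivalent depth of every voxel center along beam direction `dir`:
// for each voxel, ray-march upstream (against `dir`) to the grid boundary,
// integrating trilinearly sampled stopping power at `step` mm intervals.
// [[Rcpp::export]]
NumericVector wed_grid_cpp(NumericVector rsp, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericVector dir, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *vol = rsp.begin();
  int d[3] = {nx, ny, nz};
  // bounding box in patient space (outer faces of boundary voxels)
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dim[a] - 0.5) * spacing[a];
  }
  size_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++v) {
        double px = origin[0] + i * spacing[0];
        // distance to box exit along -dir
        double tex = 1e30;
        double p[3] = {px, py, pz};
        for (int a = 0; a < 3; ++a) {
          double da = -dir[a];
          if (std::fabs(da) < 1e-12) continue;
          double t1 = (lo[a] - p[a]) / da, t2 = (hi[a] - p[a]) / da;
          double tmax = t1 > t2 ? t1 : t2;
          if (tmax < tex) tex = tmax;
        }
        if (tex <= 0) { out[v] = 0; continue; }
        int n = (int)std::ceil(tex / step);
        double h = tex / n;
        double acc = 0.0;
        for (int s = 0; s < n; ++s) {
          double t = (s + 0.5) * h;
          double cx = (px - t * dir[0] - origin[0]) / spacing[0];
          double cy = (py - t * dir[1] - origin[1]) / spacing[1];
          double cz = (pz - t * dir[2] - origin[2]) / spacing[2];
          acc += trilinear(vol, d, cx, cy, cz);
        }
        out[v] = acc * h;
      }
    }
  }
  return out;
}

static inline double interp_col(const double *col, int n, double step,
                                double x) {
  if (x <= 0) return col[0];
  double u = x / step;
  int i = (int)u;
  if (i >= n - 1) return col[n - 1];
  double f = u - i;
  return col[i] * (1.0 - f) + col[i + 1] * f;
}

// Sparse influence triplets for one field. For each spot (lateral position
// sv/sz in beam's-eye view, energy layer `slayer`), the dose to a voxel is
// depth-dose(WED) times a normalized 2-D lateral Gaussian evaluated at the
// voxel's off-axis distance with depth-dependent sigma. Entries beyond
// `cut_sigma` lateral sigmas or below `rel_cutoff` of the column maximum are
// dropped. Alongside physical dose D, LET-weighted (D*LET) and alpha-weighted
// (D * (1 + lambda*LET/abx_voxel)) entries are emitted on the same pattern.
// [[Rcpp::export]]
List spot_influence_cpp(NumericVector wed, NumericVector vlat,
                        NumericVector zlat, NumericVector abx,
                        NumericVector sv, NumericVector sz,
                        IntegerVector slayer, NumericMatrix dose_curves,
                        NumericMatrix let_curves, NumericMatrix sigma_curves,
                        NumericVector support, double dstep, double lambda,
                        double cut_sigma, double rel_cutoff) {
  const size_t nvox = wed.size();
  const int nspot = sv.size();
  const int nd = dose_curves.nrow();
  std::vector<int> oi, oj;
  std::vector<double> od, ol, oa;
  oi.reserve(1 << 22); oj.reserve(1 << 22);
  od.reserve(1 << 22); ol.reserve(1 << 22); oa.reserve(1 << 22);

  std::vector<int> bi; std::vector<double> bd, bl;
  for (int j = 0; j < nspot; ++j) {
    int l = slayer[j];
    const double *dc = &dose_curves(0, l);
    const double *lc = &let_curves(0, l);
    const double *sc = &sigma_curves(0, l);
    double sup = support[l];
    double sig_max = interp_col(sc, nd, dstep, sup);
    double cut = cut_sigma * sig_max;
    double cut2 = cut * cut;
    bi.clear(); bd.clear(); bl.clear();
    double colmax = 0.0;
    for (size_t i = 0; i < nvox; ++i) {
      double dv = vlat[i] - sv[j];
      if (dv > cut || dv < -cut) continue;
      double dz = zlat[i] - sz[j];
      if (dz > cut || dz < -cut) continue;
      double r2 = dv * dv + dz * dz;
      if (r2 > cut2) continue;
      double w = wed[i];
      if (w < 0 || w > sup) continue;
      double d0 = interp_col(dc, nd, dstep, w);
      if (d0 <= 0) continue;
      double sg = interp_col(sc, nd, dstep, w);
      double g = std::exp(-r2 / (2.0 * sg * sg)) / (2.0 * M_PI * sg * sg);
      double dd = d0 * g;
      if (dd <= 0) continue;
      if (dd > colmax) colmax = dd;
      bi.push_back((int)i);
      bd.push_back(dd);
      bl.push_back(interp_col(lc, nd, dstep, w));
    }
    double thr = rel_cutoff * colmax;
    for (size_t m = 0; m < bi.size(); ++m) {
      if (bd[m] < thr) continue;
      oi.push_back(bi[m]);
      oj.push_back(j);
      od.push_back(bd[m]);
      ol.push_back(bd[m] * bl[m]);
      oa.push_back(bd[m] * (1.0 + lambda * bl[m] / abx[bi[m]]));
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["d"] = wrap(od), _["l"] = wrap(ol),
                      _["a"] = wrap(oa));
}
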