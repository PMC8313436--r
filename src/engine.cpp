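#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact voxel-traversal (Amanatides-Woo) line integral of relative stopping
// power from the grid boundary to each query point, along direction -dir
// (dir is the beam travel direction, so integration marches toward the source).
// Grid: column-major (nx, ny, nz); voxel (i,j,k) center at origin + idx*spacing,
// half-open extents [center - spacing/2, center + spacing/2).
// Returns WEPL in cm (densities are relative to water, lengths in mm).

static double trace_one(const double* dens, const int* dim,
                        const double* sp, const double* org,
                        double px, double py, double pz,
                        double wx, double wy, double wz) {
  const double eps = 1e-12;
  double lo[3], hi[3], p[3] = {px, py, pz}, w[3] = {wx, wy, wz};
  for (int a = 0; a < 3; ++a) {
    lo[a] = org[a] - 0.5 * sp[a];
    hi[a] = org[a] + (dim[a] - 0.5) * sp[a];
  }
  // clip [0, tmax] of p + t*w against the box
  double t0 = 0.0, t1 = R_PosInf;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(w[a]) < eps) {
      if (p[a] < lo[a] || p[a] > hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p[a]) / w[a];
      double tb = (hi[a] - p[a]) / w[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return 0.0;

  int idx[3], step[3];
  double tMax[3], tDelta[3];
  double start[3];
  for (int a = 0; a < 3; ++a) {
    start[a] = p[a] + (t0 + eps) * w[a];
    int i = (int)std::floor((start[a] - lo[a]) / sp[a]);
    if (i < 0) i = 0;
    if (i >= dim[a]) i = dim[a] - 1;
    idx[a] = i;
    if (w[a] > eps) {
      step[a] = 1;
      tMax[a] = (lo[a] + (i + 1) * sp[a] - p[a]) / w[a];
      tDelta[a] = sp[a] / w[a];
    } else if (w[a] < -eps) {
      step[a] = -1;
      tMax[a] = (lo[a] + i * sp[a] - p[a]) / w[a];
      tDelta[a] = -sp[a] / w[a];
    } else {
      step[a] = 0;
      tMax[a] = R_PosInf;
      tDelta[a] = R_PosInf;
    }
  }

  double acc = 0.0, t = t0;
  const int nx = dim[0], ny = dim[1];
  while (t < t1) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tn = tMax[a] < t1 ? tMax[a] : t1;
    double seg = tn - t;
    if (seg > 0) {
      double d = dens[idx[0] + nx * (idx[1] + (long)ny * idx[2])];
      acc += d * seg;
    }
    t = tn;
    if (tMax[a] >= t1) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= dim[a]) break;
    tMax[a] += tDelta[a];
  }
  return acc / 10.0;  // mm -> cm of water
}

// [[Rcpp::export]]
NumericVector cpp_wepl(NumericVector density, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericMatrix pts, NumericVector dir) {
  int n = pts.nrow();
  NumericVector out(n);
  // march from the point toward the source: opposite of the travel direction
  double wx = -dir[0], wy = -dir[1], wz = -dir[2];
  double nrm = std::sqrt(wx * wx + wy * wy + wz * wz);
  wx /= nrm; wy /= nrm; wz /= nrm;
  const double* dens = REAL(density);
  for (int i = 0; i < n; ++i) {
    out[i] = trace_one(dens, INTEGER(dim), REAL(spacing), REAL(origin),
                       pts(i, 0), pts(i, 1), pts(i, 2), wx, wy, wz);
  }
  return out;
}

// Per-spot dose/LET deposition onto scoring voxels given their beam's-eye-view
// coordinates (u, v, mm) and WEPL (cm) for the spot's gantry angle.
// Depth curves are shared lookup tables on a uniform z grid (cm).
// Entries below cutoff * column max are dropped (the column max is kept).

// [[Rcpp::export]]
List cpp_spot_influence(NumericVector u, NumericVector v, NumericVector w,
                        NumericVector spotU, NumericVector spotV,
                        IntegerVector spotCurve,
                        NumericVector zgrid, NumericMatrix ddd,
                        NumericMatrix letd,
                        double sigma0, double sigmaGrowth, double cutoff,
                        int colOffset) {
  int nvox = u.size(), nspot = spotU.size();
  int nz = zgrid.size();
  double z0 = zgrid[0], dz = zgrid[1] - zgrid[0];
  std::vector<int> ri, rj;
  std::vector<double> rd, rl;
  std::vector<int> tmpI(nvox);
  std::vector<double> tmpD(nvox), tmpL(nvox);

  for (int s = 0; s < nspot; ++s) {
    int cu = spotCurve[s];
    double su = spotU[s], sv = spotV[s];
    int cnt = 0;
    double cmax = 0.0;
    for (int i = 0; i < nvox; ++i) {
      double wi = w[i];
      double f = (wi - z0) / dz;
      int k = (int)std::floor(f);
      if (k < 0 || k >= nz - 1) continue;
      double fr = f - k;
      double dk = ddd(k, cu) * (1 - fr) + ddd(k + 1, cu) * fr;
      if (dk <= 0) continue;
      double depth_mm = wi * 10.0;
      double sg = sigmaGrowth * depth_mm;
      double s2 = sigma0 * sigma0 + sg * sg;
      double du = u[i] - su, dv = v[i] - sv;
      double r2 = du * du + dv * dv;
      if (r2 > 20.25 * s2) continue;  // 4.5 sigma window
      double dose = dk * std::exp(-r2 / (2.0 * s2));
      double lk = letd(k, cu) * (1 - fr) + letd(k + 1, cu) * fr;
      tmpI[cnt] = i;
      tmpD[cnt] = dose;
      tmpL[cnt] = lk;
      if (dose > cmax) cmax = dose;
      ++cnt;
    }
    double thr = cutoff * cmax;
    for (int q = 0; q < cnt; ++q) {
      if (tmpD[q] >= thr && tmpD[q] > 0) {
        ri.push_back(tmpI[q] + 1);
        rj.push_back(s + colOffset + 1);
        rd.push_back(tmpD[q]);
        rl.push_back(tmpL[q]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(rj),
                      _["d"] = wrap(rd), _["l"] = wrap(rl));
}
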