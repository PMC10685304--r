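// Compiled kernels for the exhaustive comparison searches: global gamma,
// distance to agreement, and the bounded shift correction. The gamma and
// DTA searches walk displacement offsets on the fine interpolation lattice
// in order of increasing radius, which permits exact early termination
// (for gamma, once the distance term alone exceeds the current best; for
// DTA, at the first dose match).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Offset {
  int di, dj;
  double r2;  // squared physical displacement (mm^2)
};

std::vector<Offset> build_offsets(double step, double radius) {
  std::vector<Offset> offs;
  int n = (int)std::floor(radius / step + 1e-9);
  double r2max = radius * radius + 1e-12;
  for (int di = -n; di <= n; ++di) {
    for (int dj = -n; dj <= n; ++dj) {
      double r2 = (double(di) * di + double(dj) * dj) * step * step;
      if (r2 <= r2max) offs.push_back({di, dj, r2});
    }
  }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.r2 < b.r2; });
  return offs;
}

}  // namespace

// Global gamma map. ref: reference doses on the coarse grid; fine: the
// evaluated distribution interpolated on a lattice of pitch `step` whose
// point (k*(i-1)+1, k*(j-1)+1) coincides with reference voxel (i, j).
// dose_tol is absolute (already multiplied by the normalization dose).
// [[Rcpp::export]]
NumericMatrix cpp_gamma_map(NumericMatrix ref, NumericMatrix fine, int k,
                            double step, double dist_tol, double dose_tol,
                            double search_radius) {
  int nr = ref.nrow(), nc = ref.ncol();
  int fr = fine.nrow(), fc = fine.ncol();
  std::vector<Offset> offs = build_offsets(step, search_radius);
  double dt2 = dist_tol * dist_tol;
  double dd2 = dose_tol * dose_tol;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double rv = ref(i, j);
      if (ISNAN(rv)) {
        out(i, j) = NA_REAL;
        continue;
      }
      double best = R_PosInf;
      int I0 = i * k, J0 = j * k;
      for (size_t m = 0; m < offs.size(); ++m) {
        double dterm = offs[m].r2 / dt2;
        if (dterm >= best) break;  // offsets sorted by radius
        int I = I0 + offs[m].di, J = J0 + offs[m].dj;
        if (I < 0 || I >= fr || J < 0 || J >= fc) continue;
        double ev = fine(I, J);
        if (ISNAN(ev)) continue;
        double dd = ev - rv;
        double val = dterm + dd * dd / dd2;
        if (val < best) best = val;
      }
      out(i, j) = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
    }
  }
  return out;
}

// Distance-to-agreement map: smallest displacement |s| <= search_radius at
// which the evaluated dose matches the reference voxel dose within
// local_tol * |ref|. Saturated voxels carry the cap value and are flagged.
// [[Rcpp::export]]
List cpp_dta_map(NumericMatrix ref, NumericMatrix fine, int k, double step,
                 double local_tol, double search_radius) {
  int nr = ref.nrow(), nc = ref.ncol();
  int fr = fine.nrow(), fc = fine.ncol();
  std::vector<Offset> offs = build_offsets(step, search_radius);
  NumericMatrix dta(nr, nc);
  LogicalMatrix sat(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double rv = ref(i, j);
      if (ISNAN(rv)) {
        dta(i, j) = NA_REAL;
        sat(i, j) = NA_LOGICAL;
        continue;
      }
      double tol = local_tol * std::fabs(rv);
      double found = -1.0;
      bool any_valid = false;
      for (size_t m = 0; m < offs.size(); ++m) {
        int I = i * k + offs[m].di, J = j * k + offs[m].dj;
        if (I < 0 || I >= fr || J < 0 || J >= fc) continue;
        double ev = fine(I, J);
        if (ISNAN(ev)) continue;
        any_valid = true;
        if (std::fabs(ev - rv) <= tol) {
          found = std::sqrt(offs[m].r2);
          break;  // sorted by radius: first hit is the minimum
        }
      }
      if (!any_valid) {
        dta(i, j) = NA_REAL;
        sat(i, j) = NA_LOGICAL;
      } else if (found >= 0.0) {
        dta(i, j) = found;
        sat(i, j) = false;
      } else {
        dta(i, j) = search_radius;
        sat(i, j) = true;
      }
    }
  }
  return List::create(_["dta"] = dta, _["saturated"] = sat);
}

namespace {

// bilinear sample in index space (0-based); NaN outside or on NaN corners
inline double bilin_idx(const NumericMatrix& m, double gi, double gj) {
  int nr = m.nrow(), nc = m.ncol();
  const double eps = 1e-7;
  if (gi < -eps || gi > nr - 1 + eps || gj < -eps || gj > nc - 1 + eps)
    return NA_REAL;
  if (gi < 0) gi = 0;
  if (gj < 0) gj = 0;
  if (gi > nr - 1) gi = nr - 1;
  if (gj > nc - 1) gj = nc - 1;
  int fi = (int)std::floor(gi);
  int fj = (int)std::floor(gj);
  if (fi > nr - 2) fi = nr - 2 < 0 ? 0 : nr - 2;
  if (fj > nc - 2) fj = nc - 2 < 0 ? 0 : nc - 2;
  double wi = gi - fi, wj = gj - fj;
  int i2 = fi + 1 < nr ? fi + 1 : fi;
  int j2 = fj + 1 < nc ? fj + 1 : fj;
  double v11 = m(fi, fj), v21 = m(i2, fj), v12 = m(fi, j2), v22 = m(i2, j2);
  return (1 - wi) * (1 - wj) * v11 + wi * (1 - wj) * v21 +
         (1 - wi) * wj * v12 + wi * wj * v22;
}

}  // namespace

// Bounded shift search: candidate shifts s on a (step, max_shift) grid,
// ordered by |s| (ties broken toward the smaller shift); objective is the
// mean squared difference between the shifted measured plane, sampled as
// meas(r - s), and the calculated plane over the mask voxels. Returns the
// argmin shift, its objective and the number of voxels used.
// [[Rcpp::export]]
List cpp_shift_search(NumericMatrix meas, NumericMatrix calc,
                      LogicalMatrix mask, double sp1, double sp2,
                      double step, double max_shift) {
  int nr = calc.nrow(), nc = calc.ncol();
  int n = (int)std::round(max_shift / step);
  struct Cand {
    double s1, s2, r2;
  };
  std::vector<Cand> cands;
  for (int a = -n; a <= n; ++a) {
    for (int b = -n; b <= n; ++b) {
      double s1 = a * step, s2 = b * step;
      cands.push_back({s1, s2, s1 * s1 + s2 * s2});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
    if (x.r2 != y.r2) return x.r2 < y.r2;
    if (x.s1 != y.s1) return x.s1 < y.s1;
    return x.s2 < y.s2;
  });
  double best = R_PosInf, bs1 = 0, bs2 = 0;
  int bcount = 0;
  for (size_t m = 0; m < cands.size(); ++m) {
    double di = cands[m].s1 / sp1, dj = cands[m].s2 / sp2;
    double acc = 0.0;
    int count = 0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (mask(i, j) != TRUE) continue;
        double cv = calc(i, j);
        if (ISNAN(cv)) continue;
        double mv = bilin_idx(meas, i - di, j - dj);
        if (ISNAN(mv)) continue;
        double d = mv - cv;
        acc += d * d;
        ++count;
      }
    }
    if (count == 0) continue;
    double obj = acc / count;
    if (obj < best) {
      best = obj;
      bs1 = cands[m].s1;
      bs2 = cands[m].s2;
      bcount = count;
    }
  }
  if (!R_FINITE(best))
    stop("empty overlap between planes over the whole shift range");
  return List::create(_["shift"] = NumericVector::create(bs1, bs2),
                      _["objective"] = best, _["n_voxels"] = bcount);
}
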