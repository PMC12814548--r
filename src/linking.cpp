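#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete Gauss linking number of two closed polylines via the signed
// solid-angle (quadrilateral) formulation: each segment pair contributes the
// signed area of the spherical quadrilateral spanned by the four connecting
// directions, and the double sum over all pairs divided by 4*pi is the
// integer linking number for disjoint closed curves.

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline bool unit3(double* v) {
  double n = std::sqrt(dot3(v, v));
  if (n < 1e-14) return false;
  v[0] /= n; v[1] /= n; v[2] /= n;
  return true;
}

static inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// contribution of one segment pair (p1->p2 on curve A, q1->q2 on curve B)
static double segPairOmega(const double* p1, const double* p2,
                           const double* q1, const double* q2) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int k = 0; k < 3; ++k) {
    r12[k] = p2[k] - p1[k];
    r34[k] = q2[k] - q1[k];
    r13[k] = q1[k] - p1[k];
    r14[k] = q2[k] - p1[k];
    r23[k] = q1[k] - p2[k];
    r24[k] = q2[k] - p2[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  // degenerate (near-coplanar/zero-length) configurations contribute ~0
  if (!unit3(n1) || !unit3(n2) || !unit3(n3) || !unit3(n4)) return 0.0;
  double omega = std::asin(clamp1(dot3(n1, n2))) + std::asin(clamp1(dot3(n2, n3))) +
                 std::asin(clamp1(dot3(n3, n4))) + std::asin(clamp1(dot3(n4, n1)));
  double cr[3];
  cross3(r34, r12, cr);
  double s = dot3(cr, r13);
  double sign = (s > 0) - (s < 0);
  return omega * sign;
}

static double gaussSum(const double* a, int na, const double* b, int nb) {
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    const double* p1 = a + 3 * i;
    const double* p2 = a + 3 * ((i + 1) % na);
    for (int j = 0; j < nb; ++j) {
      const double* q1 = b + 3 * j;
      const double* q2 = b + 3 * ((j + 1) % nb);
      total += segPairOmega(p1, p2, q1, q2);
    }
  }
  return total / (4.0 * M_PI);
}

// curves as n x 3 matrices of vertices (closed implicitly: last connects to first)
// [[Rcpp::export]]
double gaussLinkingCpp(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  std::vector<double> av(3 * na), bv(3 * nb);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) av[3 * i + k] = a(i, k);
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < 3; ++k) bv[3 * j + k] = b(j, k);
  return gaussSum(av.data(), na, bv.data(), nb);
}

// Monte Carlo for two rigid perpendicular linked circles of radius R:
// ring A is a regular nSeg-gon inscribed in the circle of radius R in the
// xy-plane centered at the origin; ring B is the same polygon in a vertical
// plane (normal azimuth uniform), center uniform in [-boxHalf, boxHalf]^3.
// A candidate is accepted iff the discrete Gauss linking number is +/-1.
// Fast exact routes short-circuit the double sum where the answer is forced:
//  - |c| > 2R: convex hulls disjoint -> Lk = 0;
//  - both crossings of polygon B through z=0 lie outside the circumradius or
//    inside the inradius of polygon A -> crossing count through A's spanning
//    surface is 0 or 2 with opposite signs -> Lk = 0 / impossible +/-1 rule
//    decided by the crossing parity (homologically identical to Gauss).
// Ambiguous annulus cases fall back to the full Gauss sum.
// [[Rcpp::export]]
List mcLinkedCpp(double R, int nAccept, int nSeg, double boxHalf,
                 long maxTrials) {
  RNGScope scope;
  std::vector<double> ringA(3 * nSeg), ringB(3 * nSeg);
  std::vector<double> cs(nSeg), sn(nSeg);
  for (int i = 0; i < nSeg; ++i) {
    double t = 2.0 * M_PI * i / nSeg;
    cs[i] = std::cos(t);
    sn[i] = std::sin(t);
    ringA[3 * i + 0] = R * cs[i];
    ringA[3 * i + 1] = R * sn[i];
    ringA[3 * i + 2] = 0.0;
  }
  double inr2 = R * std::cos(M_PI / nSeg);  // inradius of the polygon
  inr2 *= inr2;
  double cir2 = R * R;                      // circumradius^2

  NumericVector dist(nAccept);
  NumericMatrix params(nAccept, 4);  // phi, cx, cy, cz
  long trials = 0;
  int acc = 0;
  while (acc < nAccept && trials < maxTrials) {
    ++trials;
    double cx = R::runif(-boxHalf, boxHalf);
    double cy = R::runif(-boxHalf, boxHalf);
    double cz = R::runif(-boxHalf, boxHalf);
    double phi = R::runif(0.0, 2.0 * M_PI);
    double d2 = cx * cx + cy * cy + cz * cz;
    if (d2 > 4.0 * R * R) continue;  // disjoint convex hulls: Lk = 0
    // plane basis of ring B: e1 = (-sin phi, cos phi, 0), e2 = (0,0,1)
    double e1x = -std::sin(phi), e1y = std::cos(phi);
    // crossings of polygon B with the z=0 plane: vertices z = cz + R*sn
    int decided = 0;    // 1 if fast path decided
    int linked = 0;
    if (std::fabs(cz) > R) {
      decided = 1;  // polygon B entirely above/below A's plane
    } else {
      int nin = 0, nout = 0, ncross = 0;
      bool ambiguous = false;
      for (int i = 0; i < nSeg && !ambiguous; ++i) {
        int j = (i + 1) % nSeg;
        double zi = cz + R * sn[i];
        double zj = cz + R * sn[j];
        if (zi == 0.0) { ambiguous = true; break; }  // vertex on plane
        if ((zi > 0) != (zj > 0)) {
          ++ncross;
          double t = zi / (zi - zj);
          double u = cs[i] + t * (cs[j] - cs[i]);  // in-plane coefficient
          double px = cx + R * u * e1x;
          double py = cy + R * u * e1y;
          double rho2 = px * px + py * py;
          if (rho2 < inr2) ++nin;
          else if (rho2 > cir2) ++nout;
          else ambiguous = true;  // inside annulus: defer to Gauss sum
        }
      }
      if (!ambiguous && nin + nout == ncross) {
        decided = 1;
        linked = (nin % 2 == 1);  // odd signed-crossing count <=> |Lk| = 1
      }
    }
    if (!decided) {
      for (int i = 0; i < nSeg; ++i) {
        ringB[3 * i + 0] = cx + R * cs[i] * e1x;
        ringB[3 * i + 1] = cy + R * cs[i] * e1y;
        ringB[3 * i + 2] = cz + R * sn[i];
      }
      double lk = gaussSum(ringA.data(), nSeg, ringB.data(), nSeg);
      double lkr = std::round(lk);
      if (std::fabs(lk - lkr) > 0.1) continue;  // degenerate: re-sample
      linked = (std::fabs(lkr) == 1.0);
    }
    if (linked) {
      dist[acc] = std::sqrt(d2);
      params(acc, 0) = phi;
      params(acc, 1) = cx;
      params(acc, 2) = cy;
      params(acc, 3) = cz;
      ++acc;
    }
  }
  return List::create(_["dist"] = dist, _["params"] = params,
                      _["n_accepted"] = acc, _["n_trials"] = (double)trials);
}

static inline double mimg1(double d, double box, double inv) {
  return d - box * std::nearbyint(d * inv);
}

struct Flat {
  std::vector<double> x, y, z;
  explicit Flat(const NumericMatrix& m) {
    int n = m.nrow();
    x.resize(n); y.resize(n); z.resize(n);
    for (int i = 0; i < n; ++i) { x[i] = m(i, 0); y[i] = m(i, 1); z[i] = m(i, 2); }
  }
};

// histogram counts of minimum-image pair distances between rows of a and b
// over bins defined by 'edges' (ascending); box of length 3 (or 0s for no pbc)
// [[Rcpp::export]]
IntegerVector binPairsCpp(NumericMatrix a, NumericMatrix b,
                          NumericVector box, NumericVector edges) {
  Flat A(a), B(b);
  int na = a.nrow(), nb = b.nrow(), ne = edges.size();
  IntegerVector counts(ne - 1);
  double lo = edges[0], hi = edges[ne - 1];
  double bw = edges[1] - edges[0];
  bool uniform = true;
  for (int k = 1; k < ne - 1; ++k)
    if (std::fabs((edges[k + 1] - edges[k]) - bw) > 1e-12 * bw) { uniform = false; break; }
  bool pbc = box[0] > 0 || box[1] > 0 || box[2] > 0;
  double bx = box[0], by = box[1], bz = box[2];
  double ix = pbc && bx > 0 ? 1.0 / bx : 0.0;
  double iy = pbc && by > 0 ? 1.0 / by : 0.0;
  double iz = pbc && bz > 0 ? 1.0 / bz : 0.0;
  double hi2 = hi * hi;
  for (int i = 0; i < na; ++i) {
    double ax = A.x[i], ay = A.y[i], az = A.z[i];
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B.x[j], dy = ay - B.y[j], dz = az - B.z[j];
      if (pbc) {
        if (bx > 0) dx = mimg1(dx, bx, ix);
        if (by > 0) dy = mimg1(dy, by, iy);
        if (bz > 0) dz = mimg1(dz, bz, iz);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= hi2) continue;
      double r = std::sqrt(r2);
      if (r < lo) continue;
      int k;
      if (uniform) {
        k = (int)((r - lo) / bw);
        if (k >= ne - 1) k = ne - 2;
      } else {
        k = (int)(std::upper_bound(edges.begin(), edges.end(), r) - edges.begin()) - 1;
      }
      counts[k] += 1;
    }
  }
  return counts;
}

// per-row (of a) minimum distance to any row of b, minimum-image if box > 0
// [[Rcpp::export]]
NumericVector rowMinDistCpp(NumericMatrix a, NumericMatrix b, NumericVector box) {
  Flat A(a), B(b);
  int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  bool pbc = box[0] > 0 || box[1] > 0 || box[2] > 0;
  double bx = box[0], by = box[1], bz = box[2];
  double ix = pbc && bx > 0 ? 1.0 / bx : 0.0;
  double iy = pbc && by > 0 ? 1.0 / by : 0.0;
  double iz = pbc && bz > 0 ? 1.0 / bz : 0.0;
  for (int i = 0; i < na; ++i) {
    double ax = A.x[i], ay = A.y[i], az = A.z[i];
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B.x[j], dy = ay - B.y[j], dz = az - B.z[j];
      if (pbc) {
        if (bx > 0) dx = mimg1(dx, bx, ix);
        if (by > 0) dy = mimg1(dy, by, iy);
        if (bz > 0) dz = mimg1(dz, bz, iz);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// index pairs (1-based rows of a, b) with minimum-image distance <= cutoff
// [[Rcpp::export]]
IntegerMatrix contactPairsCpp(NumericMatrix a, NumericMatrix b,
                              NumericVector box, double cutoff) {
  Flat A(a), B(b);
  int na = a.nrow(), nb = b.nrow();
  double c2 = cutoff * cutoff;
  bool pbc = box[0] > 0 || box[1] > 0 || box[2] > 0;
  double bx = box[0], by = box[1], bz = box[2];
  double ix = pbc && bx > 0 ? 1.0 / bx : 0.0;
  double iy = pbc && by > 0 ? 1.0 / by : 0.0;
  double iz = pbc && bz > 0 ? 1.0 / bz : 0.0;
  std::vector<int> ii, jj;
  for (int i = 0; i < na; ++i) {
    double ax = A.x[i], ay = A.y[i], az = A.z[i];
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B.x[j], dy = ay - B.y[j], dz = az - B.z[j];
      if (pbc) {
        if (bx > 0) dx = mimg1(dx, bx, ix);
        if (by > 0) dy = mimg1(dy, by, iy);
        if (bz > 0) dz = mimg1(dz, bz, iz);
      }
      if (dx * dx + dy * dy + dz * dz <= c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
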