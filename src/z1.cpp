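// Pairwise entanglement counting by primitive-path shrinking: termini stay
// pinned, each chain's contour is shortened by vertex removal and
// vertex-straightening moves whose swept triangles must not cross any other
// chain; surviving blocked kinks identify entangled pairs.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 sub(const V3& a, const V3& b) { return { a.x-b.x, a.y-b.y, a.z-b.z }; }
static inline V3 crs(const V3& a, const V3& b) {
  return { a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x };
}
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double nrm(const V3& a) { return std::sqrt(dot(a, a)); }

// segment (p,q) vs triangle (a,b,c); a small eps treats grazing contact as
// a hit (conservative: a blocked move stays blocked)
static bool seg_tri(const V3& p, const V3& q, const V3& a, const V3& b,
                    const V3& c, double eps) {
  V3 ab = sub(b, a), ac = sub(c, a), d = sub(q, p);
  V3 n = crs(ab, ac);
  double area2 = nrm(n);
  if (area2 < 1e-12) return false; // degenerate triangle sweeps nothing
  double denom = dot(n, d);
  double dn = dot(n, sub(a, p));
  if (std::fabs(denom) < 1e-14) {
    // segment parallel to triangle plane: treat near-coplanar overlap as hit
    if (std::fabs(dn) > eps * area2) return false;
    // coarse test: either endpoint projects inside -> hit
    denom = 1e-14;
  }
  double t = dn / denom;
  if (t < -eps || t > 1.0 + eps) return false;
  V3 pt = { p.x + t * d.x, p.y + t * d.y, p.z + t * d.z };
  // barycentric
  V3 ap = sub(pt, a);
  double d00 = dot(ab, ab), d01 = dot(ab, ac), d11 = dot(ac, ac);
  double d20 = dot(ap, ab), d21 = dot(ap, ac);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < 1e-14) return false;
  double vv = (d11 * d20 - d01 * d21) / den;
  double ww = (d00 * d21 - d01 * d20) / den;
  return vv >= -eps && ww >= -eps && vv + ww <= 1.0 + eps;
}

struct PP { std::vector<V3> pts; };

// check the triangle (a,b,c) against every segment of every other chain,
// including X/Y periodic images when periodic
static int blocking_chain(const std::vector<PP>& paths, int self,
                          const V3& a, const V3& b, const V3& c,
                          double Lx, double Ly, bool periodic, double eps,
                          double* best_d2) {
  V3 cen = { (a.x + b.x + c.x) / 3.0, (a.y + b.y + c.y) / 3.0,
             (a.z + b.z + c.z) / 3.0 };
  double rad = std::max({ nrm(sub(a, cen)), nrm(sub(b, cen)),
                          nrm(sub(c, cen)) });
  int blocker = -1;
  double bd2 = 1e300;
  int n1 = periodic ? 1 : 0;
  for (int ch = 0; ch < (int)paths.size(); ++ch) {
    if (ch == self) continue;
    const std::vector<V3>& P = paths[ch].pts;
    for (size_t s = 0; s + 1 < P.size(); ++s) {
      for (int ix = -n1; ix <= n1; ++ix)
        for (int iy = -n1; iy <= n1; ++iy) {
          V3 p = { P[s].x + ix * Lx, P[s].y + iy * Ly, P[s].z };
          V3 q = { P[s+1].x + ix * Lx, P[s+1].y + iy * Ly, P[s+1].z };
          // prune
          V3 m = { 0.5 * (p.x + q.x), 0.5 * (p.y + q.y), 0.5 * (p.z + q.z) };
          double half = 0.5 * nrm(sub(q, p));
          double dc = nrm(sub(m, cen));
          if (dc > rad + half + 1e-9) continue;
          if (seg_tri(p, q, a, b, c, eps)) {
            // tie-break on closest approach to the triangle apex b
            double d2 = std::min(dot(sub(p, b), sub(p, b)),
                                 dot(sub(q, b), sub(q, b)));
            if (d2 < bd2) { bd2 = d2; blocker = ch; }
          }
        }
    }
  }
  if (best_d2) *best_d2 = bd2;
  return blocker;
}

static double path_len(const PP& p) {
  double L = 0;
  for (size_t s = 0; s + 1 < p.pts.size(); ++s)
    L += nrm(sub(p.pts[s + 1], p.pts[s]));
  return L;
}

// [[Rcpp::export]]
List cpp_z1(NumericMatrix x, IntegerVector chain_id, double Lx, double Ly,
            bool periodic, double tol, int max_sweeps) {
  int n = x.nrow();
  int nch = 0;
  for (int i = 0; i < n; ++i) nch = std::max(nch, chain_id[i]);
  std::vector<PP> paths(nch);
  for (int i = 0; i < n; ++i)
    paths[chain_id[i] - 1].pts.push_back({ x(i, 0), x(i, 1), x(i, 2) });
  for (int c = 0; c < nch; ++c)
    if (paths[c].pts.size() < 2) stop("each chain needs at least 2 beads");

  double eps = 1e-9;
  double total0 = 0;
  for (int c = 0; c < nch; ++c) total0 += path_len(paths[c]);
  std::vector<double> sweep_lengths;
  bool converged = false;
  double prev = total0;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int c = 0; c < nch; ++c) {
      std::vector<V3>& P = paths[c].pts;
      // removal moves
      size_t v = 1;
      while (v + 1 <= P.size() - 2 + 1 && P.size() > 2) {
        if (v >= P.size() - 1) break;
        if (blocking_chain(paths, c, P[v - 1], P[v], P[v + 1], Lx, Ly,
                           periodic, eps, nullptr) < 0) {
          P.erase(P.begin() + v);
          if (v > 1) --v; // re-check the previous vertex
        } else {
          ++v;
        }
      }
      // straightening moves: pull blocked vertices toward the chord
      for (size_t w = 1; w + 1 < P.size(); ++w) {
        V3 m = { 0.5 * (P[w - 1].x + P[w + 1].x),
                 0.5 * (P[w - 1].y + P[w + 1].y),
                 0.5 * (P[w - 1].z + P[w + 1].z) };
        for (double alpha : { 0.5, 0.2, 0.05 }) {
          V3 tgt = { P[w].x + alpha * (m.x - P[w].x),
                     P[w].y + alpha * (m.y - P[w].y),
                     P[w].z + alpha * (m.z - P[w].z) };
          bool hit =
            blocking_chain(paths, c, P[w - 1], P[w], tgt, Lx, Ly, periodic,
                           eps, nullptr) >= 0 ||
            blocking_chain(paths, c, P[w + 1], P[w], tgt, Lx, Ly, periodic,
                           eps, nullptr) >= 0;
          if (!hit) { P[w] = tgt; break; }
        }
      }
    }
    double tot = 0;
    for (int c = 0; c < nch; ++c) tot += path_len(paths[c]);
    sweep_lengths.push_back(tot);
    if (prev - tot < tol * std::max(tot, 1e-12)) { converged = true; break; }
    prev = tot;
  }

  // final cleanup: remove every unblocked vertex, then attribute kinks
  for (int c = 0; c < nch; ++c) {
    std::vector<V3>& P = paths[c].pts;
    bool changed = true;
    while (changed && P.size() > 2) {
      changed = false;
      for (size_t v = 1; v + 1 < P.size(); ++v)
        if (blocking_chain(paths, c, P[v - 1], P[v], P[v + 1], Lx, Ly,
                           periodic, eps, nullptr) < 0) {
          P.erase(P.begin() + v);
          changed = true;
          break;
        }
    }
  }

  std::vector<int> ka, kb;
  std::vector<double> kx, ky, kz;
  std::vector<uint64_t> pairset;
  for (int c = 0; c < nch; ++c) {
    std::vector<V3>& P = paths[c].pts;
    for (size_t v = 1; v + 1 < P.size(); ++v) {
      double d2;
      int bl = blocking_chain(paths, c, P[v - 1], P[v], P[v + 1], Lx, Ly,
                              periodic, eps, &d2);
      if (bl >= 0) {
        ka.push_back(c + 1); kb.push_back(bl + 1);
        kx.push_back(P[v].x); ky.push_back(P[v].y); kz.push_back(P[v].z);
        int lo = std::min(c, bl), hi = std::max(c, bl);
        pairset.push_back(((uint64_t)lo << 32) | (uint64_t)hi);
      }
    }
  }
  std::sort(pairset.begin(), pairset.end());
  pairset.erase(std::unique(pairset.begin(), pairset.end()), pairset.end());

  List pl(nch);
  for (int c = 0; c < nch; ++c) {
    NumericMatrix m(paths[c].pts.size(), 3);
    for (size_t s = 0; s < paths[c].pts.size(); ++s) {
      m(s, 0) = paths[c].pts[s].x;
      m(s, 1) = paths[c].pts[s].y;
      m(s, 2) = paths[c].pts[s].z;
    }
    pl[c] = m;
  }
  int nk = (int)ka.size();
  IntegerVector A(nk), Bv(nk);
  NumericVector X(nk), Y(nk), Z(nk);
  for (int q = 0; q < nk; ++q) {
    A[q] = ka[q]; Bv[q] = kb[q];
    X[q] = kx[q]; Y[q] = ky[q]; Z[q] = kz[q];
  }
  IntegerVector pa(pairset.size()), pb(pairset.size());
  for (size_t q = 0; q < pairset.size(); ++q) {
    pa[q] = (int)(pairset[q] >> 32) + 1;
    pb[q] = (int)(pairset[q] & 0xFFFFFFFFULL) + 1;
  }
  return List::create(
      _["paths"] = pl,
      _["kinks"] = DataFrame::create(_["chain_a"] = A, _["chain_b"] = Bv,
                                     _["x"] = X, _["y"] = Y, _["z"] = Z),
      _["entangled_pairs"] = DataFrame::create(_["chain_a"] = pa,
                                               _["chain_b"] = pb),
      _["n_entanglements"] = (int)pairset.size(),
      _["sweep_lengths"] = wrap(sweep_lengths),
      _["converged"] = converged);
}
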