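// Grid-of-balls cavity detection: probe balls on a cubic grid, occupied
// where they overlap a residue, flood fill from the exterior through the
// X/Y periodic images and the open Z faces; remaining empty balls form
// cavities.  Optional grid rotations (about Z, interior sets intersected).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
#include <algorithm>
using namespace Rcpp;

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;  // spacings
  double z0;          // z of first layer
  inline int id(int i, int j, int k) const { return (k * ny + j) * nx + i; }
};

// classify: 0 occupied, 1 outside, 2 interior empty
static void classify(const std::vector<double>& px,
                     const std::vector<double>& py,
                     const std::vector<double>& pz,
                     double Lx, double Ly, const Grid& G, double rcap,
                     bool conn26, std::vector<uint8_t>& lab) {
  int ncell = G.nx * G.ny * G.nz;
  lab.assign(ncell, 2);
  // mark occupied
  double rc2 = rcap * rcap;
  int mx = (int)std::ceil(rcap / G.sx), my = (int)std::ceil(rcap / G.sy),
      mz = (int)std::ceil(rcap / G.sz);
  int n = (int)px.size();
  for (int a = 0; a < n; ++a) {
    double x = px[a] - std::floor(px[a] / Lx) * Lx;
    double y = py[a] - std::floor(py[a] / Ly) * Ly;
    int ci = (int)std::floor(x / G.sx);
    int cj = (int)std::floor(y / G.sy);
    int ck = (int)std::floor((pz[a] - G.z0) / G.sz);
    for (int dk = -mz; dk <= mz + 1; ++dk) {
      int k = ck + dk;
      if (k < 0 || k >= G.nz) continue;
      double gz = G.z0 + k * G.sz;
      for (int dj = -my; dj <= my + 1; ++dj) {
        int j = ((cj + dj) % G.ny + G.ny) % G.ny;
        double gy = (cj + dj) * G.sy;
        for (int di = -mx; di <= mx + 1; ++di) {
          int i = ((ci + di) % G.nx + G.nx) % G.nx;
          double gx = (ci + di) * G.sx;
          double dx = gx - x, dy = gy - y, dz = gz - pz[a];
          if (dx * dx + dy * dy + dz * dz < rc2)
            lab[G.id(i, j, k)] = 0;
        }
      }
    }
  }
  // flood fill exterior from top and bottom z layers
  std::queue<int> q;
  for (int j = 0; j < G.ny; ++j)
    for (int i = 0; i < G.nx; ++i) {
      int a = G.id(i, j, 0), b = G.id(i, j, G.nz - 1);
      if (lab[a] == 2) { lab[a] = 1; q.push(a); }
      if (lab[b] == 2) { lab[b] = 1; q.push(b); }
    }
  std::vector<int> d6i = { 1, -1, 0, 0, 0, 0 };
  std::vector<int> d6j = { 0, 0, 1, -1, 0, 0 };
  std::vector<int> d6k = { 0, 0, 0, 0, 1, -1 };
  std::vector<int> dii, djj, dkk;
  if (conn26) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dii.push_back(a); djj.push_back(b); dkk.push_back(c);
        }
  } else { dii = d6i; djj = d6j; dkk = d6k; }
  int nng = (int)dii.size();
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int k = cur / (G.nx * G.ny), rem = cur % (G.nx * G.ny);
    int j = rem / G.nx, i = rem % G.nx;
    for (int u = 0; u < nng; ++u) {
      int ii = ((i + dii[u]) % G.nx + G.nx) % G.nx;
      int jj = ((j + djj[u]) % G.ny + G.ny) % G.ny;
      int kk = k + dkk[u];
      if (kk < 0 || kk >= G.nz) continue;
      int b = G.id(ii, jj, kk);
      if (lab[b] == 2) { lab[b] = 1; q.push(b); }
    }
  }
}

// [[Rcpp::export]]
List cpp_spaceball(NumericMatrix x, double Lx, double Ly, double zlo,
                   double zhi, double ball_radius, double residue_radius,
                   double spacing, int rotations, bool conn26,
                   bool return_balls) {
  if (Lx <= 0 || Ly <= 0 || zhi <= zlo) stop("degenerate box");
  if (spacing > 2.0 * ball_radius)
    stop("grid spacing must not exceed the ball diameter");
  int n = x.nrow();
  std::vector<double> px(n), py(n), pz(n);
  double zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < n; ++i) {
    px[i] = x(i, 0); py[i] = x(i, 1); pz[i] = x(i, 2);
    zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
  }
  if (n == 0) { zmin = zlo; zmax = zhi; }
  double rcap = ball_radius + residue_radius;
  Grid G;
  G.nx = std::max(2, (int)std::round(Lx / spacing));
  G.ny = std::max(2, (int)std::round(Ly / spacing));
  G.sx = Lx / G.nx; G.sy = Ly / G.ny; G.sz = spacing;
  // z range: pad beyond the outermost residues so the extreme layers are
  // guaranteed exterior seeds; layers stay anchored to the lower wall so
  // reports are comparable across probe/residue radii
  double pad = rcap + 2.0 * spacing;
  G.z0 = zlo - std::ceil((zlo - (zmin - pad)) / spacing) * spacing;
  G.nz = std::max(3, (int)std::ceil((zmax + pad - G.z0) / spacing) + 1);

  std::vector<uint8_t> lab;
  classify(px, py, pz, Lx, Ly, G, rcap, conn26, lab);

  if (rotations > 1) {
    double cx = Lx / 2.0, cy = Ly / 2.0;
    for (int rnum = 1; rnum < rotations; ++rnum) {
      double th = (M_PI / 2.0) * rnum / rotations;
      double ct = std::cos(th), st = std::sin(th);
      std::vector<double> qx(n), qy(n);
      for (int i = 0; i < n; ++i) { // rotate points by -theta about centre
        double dx = px[i] - cx, dy = py[i] - cy;
        qx[i] = cx + ct * dx + st * dy;
        qy[i] = cy - st * dx + ct * dy;
      }
      std::vector<uint8_t> lab2;
      classify(qx, qy, pz, Lx, Ly, G, rcap, conn26, lab2);
      // a ball stays interior only if its rotated image is interior too
      for (int k = 0; k < G.nz; ++k)
        for (int j = 0; j < G.ny; ++j)
          for (int i = 0; i < G.nx; ++i) {
            int a = G.id(i, j, k);
            if (lab[a] != 2) continue;
            double gx = i * G.sx - cx, gy = j * G.sy - cy;
            double rx = cx + ct * gx + st * gy, ry = cy - st * gx + ct * gy;
            int ii = (int)std::floor(rx / G.sx + 0.5);
            int jj = (int)std::floor(ry / G.sy + 0.5);
            ii = (ii % G.nx + G.nx) % G.nx;
            jj = (jj % G.ny + G.ny) % G.ny;
            if (lab2[G.id(ii, jj, k)] != 2) lab[a] = 1;
          }
    }
  }

  // connected components of interior empties
  std::vector<int> comp(lab.size(), -1);
  std::vector<double> vols;
  std::vector<int> d6i = { 1, -1, 0, 0, 0, 0 };
  std::vector<int> d6j = { 0, 0, 1, -1, 0, 0 };
  std::vector<int> d6k = { 0, 0, 0, 0, 1, -1 };
  double vball = G.sx * G.sy * G.sz;
  int ncomp = 0;
  for (size_t s = 0; s < lab.size(); ++s) {
    if (lab[s] != 2 || comp[s] >= 0) continue;
    int cnt = 0;
    std::queue<int> q;
    comp[s] = ncomp; q.push((int)s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      ++cnt;
      int k = cur / (G.nx * G.ny), rem = cur % (G.nx * G.ny);
      int j = rem / G.nx, i = rem % G.nx;
      for (int u = 0; u < 6; ++u) {
        int ii = ((i + d6i[u]) % G.nx + G.nx) % G.nx;
        int jj = ((j + d6j[u]) % G.ny + G.ny) % G.ny;
        int kk = k + d6k[u];
        if (kk < 0 || kk >= G.nz) continue;
        int b = G.id(ii, jj, kk);
        if (lab[b] == 2 && comp[b] < 0) { comp[b] = ncomp; q.push(b); }
      }
    }
    vols.push_back(cnt * vball);
    ++ncomp;
  }
  // sort volumes descending, keep component relabelling consistent
  std::vector<int> ord(ncomp);
  for (int i = 0; i < ncomp; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return vols[a] > vols[b]; });
  std::vector<int> rank(ncomp);
  for (int i = 0; i < ncomp; ++i) rank[ord[i]] = i;
  NumericVector volume(ncomp);
  for (int i = 0; i < ncomp; ++i) volume[i] = vols[ord[i]];

  List out;
  out["n_cavities"] = ncomp;
  out["volumes"] = volume;
  {
    // ball tallies restricted to layers inside the walls (the grid is
    // anchored to zlo, so these are comparable across radii)
    long nocc = 0, nout = 0, ncav = 0;
    for (int k = 0; k < G.nz; ++k) {
      double gz = G.z0 + k * G.sz;
      if (gz < zlo - 1e-9 || gz > zhi + 1e-9) continue;
      for (int j = 0; j < G.ny; ++j)
        for (int i = 0; i < G.nx; ++i) {
          uint8_t l = lab[G.id(i, j, k)];
          if (l == 0) ++nocc; else if (l == 1) ++nout; else ++ncav;
        }
    }
    out["n_occupied"] = (double)nocc;
    out["n_outside"] = (double)nout;
    out["n_cavity_balls"] = (double)ncav;
  }
  if (return_balls) {
    int nb = 0;
    for (size_t s = 0; s < lab.size(); ++s) if (lab[s] == 2) ++nb;
    NumericMatrix balls(nb, 4);
    int r = 0;
    for (size_t s = 0; s < lab.size(); ++s) {
      if (lab[s] != 2) continue;
      int k = (int)s / (G.nx * G.ny), rem = (int)s % (G.nx * G.ny);
      int j = rem / G.nx, i = rem % G.nx;
      balls(r, 0) = i * G.sx;
      balls(r, 1) = j * G.sy;
      balls(r, 2) = G.z0 + k * G.sz;
      balls(r, 3) = rank[comp[s]] + 1;
      ++r;
    }
    out["balls"] = balls;
  }
  out["ball_volume"] = vball;
  return out;
}
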