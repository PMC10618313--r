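// Core engine: DSB force field, dynamic contact registry and Langevin
// integrator.  Internal units: length in Angstrom, energy in epsilon,
// time in tau, mass in average-residue-mass units.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

static const double TWO16 = 1.1224620483093730; // 2^(1/6)

// ---------------------------------------------------------------- box ----
struct BoxG {
  double Lx, Ly, tilt, zlo, zhi;
  int adhesion;
};

static BoxG box_from_list(const List& b) {
  BoxG B;
  B.Lx = as<double>(b["Lx"]);
  B.Ly = as<double>(b["Ly"]);
  B.tilt = as<double>(b["tilt"]);
  B.zlo = as<double>(b["zlo"]);
  B.zhi = as<double>(b["zhi"]);
  B.adhesion = as<bool>(b["adhesion"]) ? 1 : 0;
  if (B.Lx <= 0 || B.Ly <= 0 || B.zhi <= B.zlo)
    stop("degenerate box");
  return B;
}

static List box_to_list(const BoxG& B) {
  return List::create(_["Lx"] = B.Lx, _["Ly"] = B.Ly, _["tilt"] = B.tilt,
                      _["zlo"] = B.zlo, _["zhi"] = B.zhi,
                      _["adhesion"] = (bool)B.adhesion);
}

// Minimum-image displacement under X/Y periodicity of a possibly sheared
// cell; Z is never wrapped.  Cell vectors a = (Lx,0,0), b = (tilt,Ly,0).
static inline void mi_disp(const BoxG& B, double dx, double dy, double dz,
                           double out[3]) {
  double s2 = dy / B.Ly;
  double s1 = (dx - s2 * B.tilt) / B.Lx;
  s1 -= std::nearbyint(s1);
  s2 -= std::nearbyint(s2);
  double bx = s1 * B.Lx + s2 * B.tilt, by = s2 * B.Ly;
  if (B.tilt != 0.0) {
    double best = bx * bx + by * by, bbx = bx, bby = by;
    for (int n1 = -1; n1 <= 1; ++n1)
      for (int n2 = -1; n2 <= 1; ++n2) {
        double cx = bx + n1 * B.Lx + n2 * B.tilt;
        double cy = by + n2 * B.Ly;
        double q = cx * cx + cy * cy;
        if (q < best - 1e-12) { best = q; bbx = cx; bby = cy; }
      }
    bx = bbx; by = bby;
  }
  out[0] = bx; out[1] = by; out[2] = dz;
}

// [[Rcpp::export]]
NumericVector cpp_min_image(NumericVector ri, NumericVector rj, List boxL) {
  BoxG B = box_from_list(boxL);
  double d[3];
  mi_disp(B, rj[0] - ri[0], rj[1] - ri[1], rj[2] - ri[2], d);
  return NumericVector::create(d[0], d[1], d[2]);
}

// ---------------------------------------------------------------- rng ----
struct RNG {
  uint64_t s;
  inline uint64_t nx() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  inline double unif() { return (nx() >> 11) * (1.0 / 9007199254740992.0); }
  inline double gauss() {
    double u = unif();
    while (u <= 0.0) u = unif();
    double v = unif();
    return std::sqrt(-2.0 * std::log(u)) * std::cos(6.283185307179586 * v);
  }
};

static RNG rng_from(const NumericVector& st) {
  RNG r;
  uint64_t hi = (uint64_t)(uint32_t)st[0], lo = (uint64_t)(uint32_t)st[1];
  r.s = (hi << 32) | lo;
  if (r.s == 0) r.s = 0x9E3779B97F4A7C15ULL;
  return r;
}

static NumericVector rng_to(const RNG& r) {
  return NumericVector::create((double)(uint32_t)(r.s >> 32),
                               (double)(uint32_t)(r.s & 0xFFFFFFFFULL));
}

// [[Rcpp::export]]
NumericVector cpp_rng_init(int seed) {
  RNG r;
  r.s = (uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 0x2545F4914F6CDD1DULL;
  if (r.s == 0) r.s = 1;
  for (int k = 0; k < 8; ++k) r.nx();
  return rng_to(r);
}

// [[Rcpp::export]]
NumericVector cpp_rng_gauss(NumericVector state, int n) {
  RNG r = rng_from(state);
  NumericVector out(n + 2);
  for (int k = 0; k < n; ++k) out[k] = r.gauss();
  NumericVector st = rng_to(r);
  out[n] = st[0]; out[n + 1] = st[1];
  return out;
}

// ------------------------------------------------------------- spline ----
// Cubic spline through (X, Y); natural ends or periodic.  Dense solve is
// fine at the table sizes used (<= a few hundred nodes).
struct Spline {
  std::vector<double> X, Y, M;
  bool per = false;
  double period = 0.0;
  bool ok = false;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             bool periodic, double prd) {
    int n = (int)x.size();
    if (n < 4) stop("potential table needs at least 4 grid points");
    for (int i = 1; i < n; ++i)
      if (x[i] <= x[i - 1]) stop("potential table grid must be increasing");
    per = periodic; period = prd;
    if (per) {
      if (x[n - 1] - x[0] >= prd - 1e-9)
        stop("periodic table grid must span less than one period");
      X.assign(x.begin(), x.end());
      X.push_back(x[0] + prd);
      Y.assign(y.begin(), y.end());
      Y.push_back(y[0]);
      int m = n; // unknown second derivatives M_0..M_{m-1}, cyclic
      std::vector<double> A(m * m, 0.0), b(m, 0.0);
      for (int i = 0; i < m; ++i) {
        int im = (i - 1 + m) % m, ip = (i + 1) % m;
        double h0 = X[i] - X[(i - 1 + m) % m + ((i == 0) ? 0 : 0)];
        // interval lengths with wrap
        double hm = (i == 0) ? (X[m] - X[m - 1]) : (X[i] - X[i - 1]);
        double hp = X[i + 1] - X[i];
        (void)h0;
        double ym = (i == 0) ? Y[m - 1] : Y[i - 1];
        A[i * m + im] += hm / 6.0;
        A[i * m + i]  += (hm + hp) / 3.0;
        A[i * m + ip] += hp / 6.0;
        b[i] = (Y[i + 1] - Y[i]) / hp - (Y[i] - ym) / hm;
      }
      M = solve_dense(A, b, m);
    } else {
      X = x; Y = y;
      int m = n;
      std::vector<double> A(m * m, 0.0), b(m, 0.0);
      A[0] = 1.0; b[0] = 0.0;                    // natural ends
      A[(m - 1) * m + (m - 1)] = 1.0; b[m - 1] = 0.0;
      for (int i = 1; i < m - 1; ++i) {
        double hm = X[i] - X[i - 1], hp = X[i + 1] - X[i];
        A[i * m + i - 1] = hm / 6.0;
        A[i * m + i] = (hm + hp) / 3.0;
        A[i * m + i + 1] = hp / 6.0;
        b[i] = (Y[i + 1] - Y[i]) / hp - (Y[i] - Y[i - 1]) / hm;
      }
      M = solve_dense(A, b, m);
    }
    ok = true;
  }

  static std::vector<double> solve_dense(std::vector<double>& A,
                                         std::vector<double>& b, int n) {
    for (int c = 0; c < n; ++c) {
      int p = c;
      for (int r = c + 1; r < n; ++r)
        if (std::fabs(A[r * n + c]) > std::fabs(A[p * n + c])) p = r;
      if (std::fabs(A[p * n + c]) < 1e-14) stop("singular table system");
      if (p != c) {
        for (int k = 0; k < n; ++k) std::swap(A[p * n + k], A[c * n + k]);
        std::swap(b[p], b[c]);
      }
      for (int r = c + 1; r < n; ++r) {
        double f = A[r * n + c] / A[c * n + c];
        if (f == 0.0) continue;
        for (int k = c; k < n; ++k) A[r * n + k] -= f * A[c * n + k];
        b[r] -= f * b[c];
      }
    }
    std::vector<double> x(n);
    for (int r = n - 1; r >= 0; --r) {
      double s = b[r];
      for (int k = r + 1; k < n; ++k) s -= A[r * n + k] * x[k];
      x[r] = s / A[r * n + r];
    }
    return x;
  }

  inline void eval(double q, double& V, double& dV) const {
    int nn = (int)X.size();
    if (per) {
      q = q - std::floor((q - X[0]) / period) * period;
    } else {
      if (q < X[0]) q = X[0];
      if (q > X[nn - 1]) q = X[nn - 1];
    }
    int i = (int)(std::upper_bound(X.begin(), X.end(), q) - X.begin()) - 1;
    if (i < 0) i = 0;
    if (i >= nn - 1) i = nn - 2;
    double h = X[i + 1] - X[i], t = (q - X[i]) / h;
    double Mi = M[i];
    double Mj = per ? M[(i + 1) % (int)M.size()] : M[i + 1];
    double omt = 1.0 - t;
    V = Y[i] * omt + Y[i + 1] * t +
        (h * h / 6.0) * ((omt * omt * omt - omt) * Mi + (t * t * t - t) * Mj);
    dV = (Y[i + 1] - Y[i]) / h +
         (h / 6.0) * ((-3.0 * omt * omt + 1.0) * Mi + (3.0 * t * t - 1.0) * Mj);
  }
};

// ------------------------------------------------------------- params ----
struct Pars {
  double eps, dt, mass, gamma, kBT;
  double k_bond, r_bond, r_excl, r_bb, r_bs;
  std::vector<double> r_ss;        // 20x20 row-major
  std::vector<int> nc_bb, nc_ss;   // per residue type
  std::vector<double> charge;      // per residue type, in e
  double depth_contact, depth_dis;
  double kappa_perm, debye_len, ke;
  double switch_time, breakage, capture;
  double cos_bb, cos_bs, cos_ss;
  double wall_sigma, wall_depth, wall_r0;
  int wall_printed_sign, walls_on;
  int n_t; double solv_r; int solv_delta;
  int stride;
  double skin;
  int use_angles;
  Spline sang, sdih;
  double es_cut;
  double rlist() const {
    double rmax = std::max(r_bs, r_bb);
    for (double v : r_ss) rmax = std::max(rmax, v);
    return std::max(r_excl, capture * rmax) + skin;
  }
};

static Pars pars_from_list(const List& p) {
  Pars P;
  P.eps = as<double>(p["epsilon"]);
  P.dt = as<double>(p["dt"]);
  P.mass = as<double>(p["mass"]);
  P.gamma = as<double>(p["gamma"]);
  P.kBT = as<double>(p["kBT"]);
  P.k_bond = as<double>(p["k_bond"]);
  P.r_bond = as<double>(p["r_bond"]);
  P.r_excl = as<double>(p["r_excl"]);
  P.r_bb = as<double>(p["r_bb"]);
  P.r_bs = as<double>(p["r_bs"]);
  NumericMatrix rss = p["r_ss"];
  P.r_ss.assign(400, 0.0);
  for (int a = 0; a < 20; ++a)
    for (int b = 0; b < 20; ++b) P.r_ss[a * 20 + b] = rss(a, b);
  IntegerVector ncb = p["nc_bb"], ncs = p["nc_ss"];
  P.nc_bb.assign(ncb.begin(), ncb.end());
  P.nc_ss.assign(ncs.begin(), ncs.end());
  NumericVector ch = p["charge"];
  P.charge.assign(ch.begin(), ch.end());
  P.depth_contact = as<double>(p["depth_contact"]);
  P.depth_dis = as<double>(p["depth_disulfide"]);
  P.kappa_perm = as<double>(p["kappa_perm"]);
  P.debye_len = as<double>(p["debye_length"]);
  P.ke = as<double>(p["coulomb_k"]);
  P.switch_time = as<double>(p["switch_time"]);
  P.breakage = as<double>(p["breakage_factor"]);
  P.capture = as<double>(p["capture_factor"]);
  P.cos_bb = as<double>(p["cos_bb"]);
  P.cos_bs = as<double>(p["cos_bs"]);
  P.cos_ss = as<double>(p["cos_ss"]);
  P.wall_sigma = as<double>(p["wall_sigma"]);
  P.wall_depth = as<double>(p["wall_adhesion_depth"]);
  P.wall_r0 = as<double>(p["wall_adhesion_r0"]);
  P.wall_printed_sign = as<bool>(p["wall_printed_sign"]) ? 1 : 0;
  P.walls_on = as<bool>(p["walls_enabled"]) ? 1 : 0;
  P.n_t = as<int>(p["solvation_n_t"]);
  P.solv_r = as<double>(p["solvation_radius"]);
  P.solv_delta = as<int>(p["solvation_delta"]);
  P.stride = as<int>(p["contact_stride"]);
  P.skin = as<double>(p["verlet_skin"]);
  P.use_angles = as<bool>(p["use_angle_potentials"]) ? 1 : 0;
  P.es_cut = 4.0 * P.debye_len;
  if (P.use_angles) {
    List ta = p["angle_table"], td = p["dihedral_table"];
    NumericVector ax = ta["x"], ay = ta["y"], dx = td["x"], dy = td["y"];
    if (ax[0] > 1e-9 || ax[ax.size() - 1] < M_PI - 1e-9)
      stop("angle table must cover [0, pi]");
    P.sang.build(std::vector<double>(ax.begin(), ax.end()),
                 std::vector<double>(ay.begin(), ay.end()), false, 0.0);
    P.sdih.build(std::vector<double>(dx.begin(), dx.end()),
                 std::vector<double>(dy.begin(), dy.end()), true, 2.0 * M_PI);
  }
  return P;
}

// ----------------------------------------------------------- topology ----
struct Topo {
  int N = 0;
  std::vector<int> type;   // 0..19
  std::vector<int> chain;  // 0-based chain id
  std::vector<int> cys;
  std::vector<int> go_i, go_j;
  std::vector<double> go_r0;
  std::vector<int> cstart, cend; // inclusive residue ranges per chain
};

static Topo topo_from_list(const List& t) {
  Topo T;
  IntegerVector ty = t["type_code"], ch = t["chain_id"];
  LogicalVector cy = t["is_cysteine"];
  T.N = ty.size();
  T.type.resize(T.N); T.chain.resize(T.N); T.cys.resize(T.N);
  for (int i = 0; i < T.N; ++i) {
    T.type[i] = ty[i] - 1;
    T.chain[i] = ch[i] - 1;
    T.cys[i] = cy[i] ? 1 : 0;
  }
  int nc = 0;
  for (int i = 0; i < T.N; ++i) nc = std::max(nc, T.chain[i] + 1);
  T.cstart.assign(nc, -1); T.cend.assign(nc, -1);
  for (int i = 0; i < T.N; ++i) {
    int c = T.chain[i];
    if (T.cstart[c] < 0) T.cstart[c] = i;
    T.cend[c] = i;
  }
  if (t.containsElementNamed("go_contacts")) {
    DataFrame g(t["go_contacts"]);
    if (g.nrows() > 0) {
      IntegerVector gi = g["i"], gj = g["j"];
      NumericVector gr = g["r0"];
      for (int k = 0; k < gi.size(); ++k) {
        T.go_i.push_back(gi[k] - 1);
        T.go_j.push_back(gj[k] - 1);
        T.go_r0.push_back(gr[k]);
      }
    }
  }
  return T;
}

// ----------------------------------------------------------- registry ----
// kind codes: 1 bb, 2 bs (i backbone, j side), 3 sb, 4 ss, 5 disulfide,
// 6 go, 7 wall (j = -1 lower wall, -2 upper wall).
struct Rec {
  int i, j, kind;
  double r0, depth, lambda;
  int dir; // +1 switching on, 0 steady, -1 switching off
};

static std::vector<Rec> regs_from_df(const DataFrame& d) {
  std::vector<Rec> R;
  if (d.nrows() == 0) return R;
  IntegerVector i = d["i"], j = d["j"], k = d["kind"], dir = d["dir"];
  NumericVector r0 = d["r0"], dp = d["depth"], lm = d["lambda"];
  for (int q = 0; q < d.nrows(); ++q) {
    Rec r;
    r.i = i[q] - 1;
    r.j = (j[q] > 0) ? j[q] - 1 : j[q]; // walls stay -1/-2
    r.kind = k[q]; r.r0 = r0[q]; r.depth = dp[q];
    r.lambda = lm[q]; r.dir = dir[q];
    R.push_back(r);
  }
  return R;
}

static DataFrame regs_to_df(const std::vector<Rec>& R) {
  int n = (int)R.size();
  IntegerVector i(n), j(n), k(n), dir(n);
  NumericVector r0(n), dp(n), lm(n);
  for (int q = 0; q < n; ++q) {
    i[q] = R[q].i + 1;
    j[q] = (R[q].j >= 0) ? R[q].j + 1 : R[q].j;
    k[q] = R[q].kind; dir[q] = R[q].dir;
    r0[q] = R[q].r0; dp[q] = R[q].depth; lm[q] = R[q].lambda;
  }
  return DataFrame::create(_["i"] = i, _["j"] = j, _["kind"] = k,
                           _["r0"] = r0, _["depth"] = dp,
                           _["lambda"] = lm, _["dir"] = dir);
}

static inline uint64_t pkey(int i, int j) {
  if (i > j) std::swap(i, j);
  return ((uint64_t)i << 32) | (uint64_t)j;
}

// ------------------------------------------------------------- frames ----
struct Frames {
  std::vector<double> n, b; // 3N each
  std::vector<int> ok;
};

static void comp_frames(const std::vector<double>& X, const BoxG& B,
                        const Topo& T, Frames& fr) {
  fr.n.assign(3 * T.N, 0.0);
  fr.b.assign(3 * T.N, 0.0);
  fr.ok.assign(T.N, 0);
  for (int i = 0; i < T.N; ++i) {
    int c = T.chain[i];
    if (i == T.cstart[c] || i == T.cend[c]) continue;
    double u1[3], u2[3];
    mi_disp(B, X[3 * i] - X[3 * (i - 1)], X[3 * i + 1] - X[3 * (i - 1) + 1],
            X[3 * i + 2] - X[3 * (i - 1) + 2], u1);
    mi_disp(B, X[3 * (i + 1)] - X[3 * i], X[3 * (i + 1) + 1] - X[3 * i + 1],
            X[3 * (i + 1) + 2] - X[3 * i + 2], u2);
    double bx = u1[1] * u2[2] - u1[2] * u2[1];
    double by = u1[2] * u2[0] - u1[0] * u2[2];
    double bz = u1[0] * u2[1] - u1[1] * u2[0];
    double nb = std::sqrt(bx * bx + by * by + bz * bz);
    double l1 = std::sqrt(u1[0]*u1[0] + u1[1]*u1[1] + u1[2]*u1[2]);
    double l2 = std::sqrt(u2[0]*u2[0] + u2[1]*u2[1] + u2[2]*u2[2]);
    if (nb < 1e-6 * l1 * l2 || l1 < 1e-9 || l2 < 1e-9) continue; // collinear
    // bisector of the bend: hat(-u1) + hat(u2) points "inside" the turn;
    // the side chain sits opposite (-n).
    double wx = -u1[0] / l1 + u2[0] / l2;
    double wy = -u1[1] / l1 + u2[1] / l2;
    double wz = -u1[2] / l1 + u2[2] / l2;
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nw < 1e-9) continue;
    fr.b[3 * i] = bx / nb; fr.b[3 * i + 1] = by / nb; fr.b[3 * i + 2] = bz / nb;
    fr.n[3 * i] = wx / nw; fr.n[3 * i + 1] = wy / nw; fr.n[3 * i + 2] = wz / nw;
    fr.ok[i] = 1;
  }
}

// --------------------------------------------------------- pair lists ----
static void build_plist(const std::vector<double>& X, const BoxG& B,
                        const Topo& T, double rl,
                        std::vector<std::pair<int, int>>& plist) {
  plist.clear();
  double rl2 = rl * rl;
  double d[3];
  for (int i = 0; i < T.N; ++i)
    for (int j = i + 1; j < T.N; ++j) {
      if (T.chain[i] == T.chain[j] && j - i == 1) continue; // bonded
      mi_disp(B, X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
              X[3 * j + 2] - X[3 * i + 2], d);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rl2)
        plist.push_back(std::make_pair(i, j));
    }
}

// ----------------------------------------------------------- energies ----
// Full 6-12 well, minimum -depth at r = r0.
static inline void lj_full(double r, double r0, double depth,
                           double& V, double& dVdr) {
  double s = r0 / r, s3 = s * s * s, s6 = s3 * s3, s12 = s6 * s6;
  V = depth * (s12 - 2.0 * s6);
  dVdr = (12.0 * depth / r) * (s6 - s12);
}

// Excluded volume: shifted LJ, zero at and beyond r0 (Eq. 2 style).
static inline void lj_excl(double r, double r0, double eps,
                           double& V, double& dVdr) {
  if (r >= r0) { V = 0.0; dVdr = 0.0; return; }
  double s = r0 / r, s3 = s * s * s, s6 = s3 * s3, s12 = s6 * s6;
  V = eps * (s12 - 2.0 * s6 + 1.0);
  dVdr = (12.0 * eps / r) * (s6 - s12);
}

// Energy breakdown slots.
enum { E_BOND = 0, E_ANGLE, E_DIH, E_EXCL, E_BB, E_BS, E_SS, E_GO, E_DIS,
       E_ELEC, E_WALL, E_TOT, E_NSLOT };

static void add_pair_force(std::vector<double>& F, int i, int j,
                           const double d[3], double r, double dVdr) {
  // d = r_j - r_i (minimum image); force on j is -dVdr * dhat
  double f = -dVdr / r;
  F[3 * j] += f * d[0];     F[3 * j + 1] += f * d[1];  F[3 * j + 2] += f * d[2];
  F[3 * i] -= f * d[0];     F[3 * i + 1] -= f * d[1];  F[3 * i + 2] -= f * d[2];
}

static void forces_all(const std::vector<double>& X, const BoxG& B,
                       const Topo& T, const Pars& P,
                       const std::vector<Rec>& regs,
                       const std::vector<std::pair<int, int>>& plist,
                       const std::unordered_set<uint64_t>& active,
                       std::vector<double>& F, double EB[E_NSLOT]) {
  const int N = T.N;
  F.assign(3 * N, 0.0);
  for (int k = 0; k < E_NSLOT; ++k) EB[k] = 0.0;
  double d[3];

  // bonds
  for (int i = 0; i + 1 < N; ++i) {
    if (T.chain[i] != T.chain[i + 1]) continue;
    mi_disp(B, X[3 * (i + 1)] - X[3 * i], X[3 * (i + 1) + 1] - X[3 * i + 1],
            X[3 * (i + 1) + 2] - X[3 * i + 2], d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r < 1e-9) stop("overlapping bonded residues");
    double dr = r - P.r_bond;
    EB[E_BOND] += P.k_bond * dr * dr;
    add_pair_force(F, i, i + 1, d, r, 2.0 * P.k_bond * dr);
  }

  // angles and dihedrals from tabulated potentials
  if (P.use_angles) {
    for (int c = 0; c < (int)T.cstart.size(); ++c) {
      for (int j = T.cstart[c] + 1; j <= T.cend[c] - 1; ++j) {
        int i = j - 1, k = j + 1;
        double u[3], w[3];
        mi_disp(B, X[3*i]-X[3*j], X[3*i+1]-X[3*j+1], X[3*i+2]-X[3*j+2], u);
        mi_disp(B, X[3*k]-X[3*j], X[3*k+1]-X[3*j+1], X[3*k+2]-X[3*j+2], w);
        double lu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
        double lw = std::sqrt(w[0]*w[0]+w[1]*w[1]+w[2]*w[2]);
        if (lu < 1e-9 || lw < 1e-9) continue;
        double ct = (u[0]*w[0]+u[1]*w[1]+u[2]*w[2]) / (lu * lw);
        ct = std::max(-1.0, std::min(1.0, ct));
        double st = std::sqrt(std::max(1e-16, 1.0 - ct * ct));
        double th = std::acos(ct);
        double V, dV;
        P.sang.eval(th, V, dV);
        EB[E_ANGLE] += V;
        // dtheta/dri etc.
        double gi[3], gk[3];
        for (int q = 0; q < 3; ++q) {
          gi[q] = (ct * u[q] / lu - w[q] / lw) / (lu * st);
          gk[q] = (ct * w[q] / lw - u[q] / lu) / (lw * st);
        }
        for (int q = 0; q < 3; ++q) {
          F[3*i+q] -= dV * gi[q];
          F[3*k+q] -= dV * gk[q];
          F[3*j+q] += dV * (gi[q] + gk[q]);
        }
      }
      for (int a = T.cstart[c]; a + 3 <= T.cend[c]; ++a) {
        int i = a, j = a + 1, k = a + 2, l = a + 3;
        double b1[3], b2[3], b3[3];
        mi_disp(B, X[3*j]-X[3*i], X[3*j+1]-X[3*i+1], X[3*j+2]-X[3*i+2], b1);
        mi_disp(B, X[3*k]-X[3*j], X[3*k+1]-X[3*j+1], X[3*k+2]-X[3*j+2], b2);
        mi_disp(B, X[3*l]-X[3*k], X[3*l+1]-X[3*k+1], X[3*l+2]-X[3*k+2], b3);
        double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                         b1[0]*b2[1]-b1[1]*b2[0] };
        double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                         b2[0]*b3[1]-b2[1]*b3[0] };
        double ln1 = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
        double ln2 = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
        double lb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
        if (ln1 < 1e-12 || ln2 < 1e-12 || lb2 < 1e-9) continue;
        double m1[3] = { n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                         n1[0]*n2[1]-n1[1]*n2[0] };
        double y = (m1[0]*b2[0]+m1[1]*b2[1]+m1[2]*b2[2]) / lb2;
        double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
        double phi = std::atan2(y, x);
        double V, dV;
        P.sdih.eval(phi, V, dV);
        EB[E_DIH] += V;
        double gi[3], gl[3], gj[3], gk2[3];
        double c12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (lb2 * lb2);
        double c32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (lb2 * lb2);
        for (int q = 0; q < 3; ++q) {
          gi[q] = -(lb2 / ln1) * n1[q];
          gl[q] = (lb2 / ln2) * n2[q];
        }
        for (int q = 0; q < 3; ++q) {
          gj[q] = -(1.0 + c12) * gi[q] + c32 * gl[q];
          gk2[q] = c12 * gi[q] - (1.0 + c32) * gl[q];
        }
        for (int q = 0; q < 3; ++q) {
          F[3*i+q] -= dV * gi[q];
          F[3*j+q] -= dV * gj[q];
          F[3*k+q] -= dV * gk2[q];
          F[3*l+q] -= dV * gl[q];
        }
      }
    }
  }

  // non-bonded excluded volume (pairs not covered by an active contact)
  for (size_t q = 0; q < plist.size(); ++q) {
    int i = plist[q].first, j = plist[q].second;
    if (active.count(pkey(i, j))) continue;
    mi_disp(B, X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
            X[3 * j + 2] - X[3 * i + 2], d);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= P.r_excl * P.r_excl) continue;
    double r = std::sqrt(r2);
    if (r < 1e-9) stop("overlapping residues");
    double V, dVdr;
    lj_excl(r, P.r_excl, P.eps, V, dVdr);
    EB[E_EXCL] += V;
    add_pair_force(F, i, j, d, r, dVdr);
  }

  // registry (contacts, go, disulfides, adhesive walls)
  for (size_t q = 0; q < regs.size(); ++q) {
    const Rec& rc = regs[q];
    if (rc.kind == 7) {
      double z = X[3 * rc.i + 2];
      double dist = (rc.j == -1) ? (z - B.zlo) : (B.zhi - z);
      double sgn = (rc.j == -1) ? 1.0 : -1.0;
      if (dist < 0.05) dist = 0.05;
      double V, dVdr;
      lj_full(dist, rc.r0, rc.depth, V, dVdr);
      EB[E_WALL] += rc.lambda * V;
      F[3 * rc.i + 2] += -rc.lambda * dVdr * sgn;
      continue;
    }
    mi_disp(B, X[3 * rc.j] - X[3 * rc.i], X[3 * rc.j + 1] - X[3 * rc.i + 1],
            X[3 * rc.j + 2] - X[3 * rc.i + 2], d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r < 1e-9) stop("overlapping residues in contact");
    double V, dVdr;
    lj_full(r, rc.r0, rc.depth, V, dVdr);
    int slot = (rc.kind == 1) ? E_BB
             : (rc.kind == 2 || rc.kind == 3) ? E_BS
             : (rc.kind == 4) ? E_SS
             : (rc.kind == 5) ? E_DIS : E_GO;
    EB[slot] += rc.lambda * V;
    double dtot = rc.lambda * dVdr;
    if (rc.lambda < 1.0 && rc.kind != 6) {
      double Ve, dVe;
      lj_excl(r, P.r_excl, P.eps, Ve, dVe);
      EB[E_EXCL] += (1.0 - rc.lambda) * Ve;
      dtot += (1.0 - rc.lambda) * dVe;
    }
    add_pair_force(F, rc.i, rc.j, d, r, dtot);
  }

  // screened electrostatics with distance-dependent permittivity
  bool any_q = false;
  for (int i = 0; i < N; ++i)
    if (P.charge[T.type[i]] != 0.0) { any_q = true; break; }
  if (any_q) {
    std::vector<int> qi;
    for (int i = 0; i < N; ++i)
      if (P.charge[T.type[i]] != 0.0) qi.push_back(i);
    for (size_t a = 0; a < qi.size(); ++a)
      for (size_t b = a + 1; b < qi.size(); ++b) {
        int i = qi[a], j = qi[b];
        if (T.chain[i] == T.chain[j] && std::abs(i - j) <= 2) continue;
        mi_disp(B, X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                X[3 * j + 2] - X[3 * i + 2], d);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 > P.es_cut * P.es_cut) continue;
        double r = std::sqrt(r2);
        double qq = P.charge[T.type[i]] * P.charge[T.type[j]];
        double pref = P.ke * qq / P.kappa_perm;
        double ex = std::exp(-r / P.debye_len);
        double V = pref * ex / r2;
        double dVdr = pref * ex * (-2.0 / (r2 * r) - 1.0 / (P.debye_len * r2));
        EB[E_ELEC] += V;
        add_pair_force(F, i, j, d, r, dVdr);
      }
  }

  // wall repulsion
  if (P.walls_on) {
    double sgnV = P.wall_printed_sign ? -1.0 : 1.0;
    for (int i = 0; i < N; ++i) {
      double z = X[3 * i + 2];
      double dd[2] = { z - B.zlo, B.zhi - z };
      double sg[2] = { 1.0, -1.0 };
      for (int w = 0; w < 2; ++w) {
        double dist = dd[w];
        if (dist < 0.05) dist = 0.05;
        double s = P.wall_sigma / dist;
        double s9 = std::pow(s, 9.0);
        EB[E_WALL] += sgnV * (P.eps / 9.0) * s9;
        double dVdd = sgnV * (-P.eps) * s9 / dist;
        F[3 * i + 2] += -dVdd * sg[w];
      }
    }
  }

  EB[E_TOT] = 0.0;
  for (int k = 0; k < E_TOT; ++k) EB[E_TOT] += EB[k];
}

// ------------------------------------------------- contact eligibility ----
struct SlotCount {
  std::vector<int> bb, ss, dis;
};

static void count_slots(const std::vector<Rec>& regs, int N, SlotCount& S) {
  S.bb.assign(N, 0); S.ss.assign(N, 0); S.dis.assign(N, 0);
  for (size_t q = 0; q < regs.size(); ++q) {
    const Rec& r = regs[q];
    switch (r.kind) {
    case 1: S.bb[r.i]++; S.bb[r.j]++; break;
    case 2: S.bb[r.i]++; S.ss[r.j]++; break;
    case 3: S.ss[r.i]++; S.bb[r.j]++; break;
    case 4: S.ss[r.i]++; S.ss[r.j]++; break;
    case 5: S.ss[r.i]++; S.ss[r.j]++; S.dis[r.i]++; S.dis[r.j]++; break;
    default: break; // go and wall records do not hold slots
    }
  }
}

struct Cand { int i, j, kind; double r, r0, depth; };

// Effective side-chain coordination limits, optionally adjusted by the
// solvation rule (neighbour count within solv_r).
static void eff_nc_ss(const std::vector<double>& X, const BoxG& B,
                      const Topo& T, const Pars& P,
                      const std::vector<std::pair<int, int>>& plist,
                      std::vector<int>& nc) {
  nc.resize(T.N);
  for (int i = 0; i < T.N; ++i) nc[i] = P.nc_ss[T.type[i]];
  if (P.n_t <= 0) return;
  std::vector<int> nn(T.N, 0);
  double d[3], r2c = P.solv_r * P.solv_r;
  for (size_t q = 0; q < plist.size(); ++q) {
    int i = plist[q].first, j = plist[q].second;
    mi_disp(B, X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
            X[3 * j + 2] - X[3 * i + 2], d);
    if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < r2c) { nn[i]++; nn[j]++; }
  }
  // bonded neighbours are within 0.75 nm too
  for (int i = 0; i + 1 < T.N; ++i)
    if (T.chain[i] == T.chain[i + 1]) { nn[i]++; nn[i + 1]++; }
  for (int i = 0; i < T.N; ++i)
    if (nn[i] > P.n_t) nc[i] = std::max(0, nc[i] + P.solv_delta);
}

static void find_candidates(const std::vector<double>& X, const BoxG& B,
                            const Topo& T, const Pars& P, const Frames& fr,
                            const std::vector<Rec>& regs,
                            const std::vector<std::pair<int, int>>& plist,
                            std::vector<Cand>& cands) {
  cands.clear();
  std::unordered_set<uint64_t> act;
  std::vector<int> cys_busy(T.N, 0);
  for (size_t q = 0; q < regs.size(); ++q) {
    if (regs[q].kind == 7) continue;
    act.insert(pkey(regs[q].i, regs[q].j));
    if (regs[q].kind == 5) { cys_busy[regs[q].i] = 1; cys_busy[regs[q].j] = 1; }
  }
  SlotCount S;
  count_slots(regs, T.N, S);
  std::vector<int> ncss;
  eff_nc_ss(X, B, T, P, plist, ncss);
  auto bb_free = [&](int a) { return S.bb[a] < P.nc_bb[T.type[a]]; };
  auto ss_free = [&](int a) { return S.ss[a] < ncss[a]; };
  double d[3];
  int tC = 1; // index of 'C' in "ACDEFGHIKLMNPQRSTVWY"
  double r0cc = P.r_ss[tC * 20 + tC];
  for (size_t q = 0; q < plist.size(); ++q) {
    int i = plist[q].first, j = plist[q].second;
    if (T.chain[i] == T.chain[j] && j - i <= 2) continue;
    if (act.count(pkey(i, j))) continue;
    mi_disp(B, X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
            X[3 * j + 2] - X[3 * i + 2], d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r < 1e-9) continue;
    double rh[3] = { d[0] / r, d[1] / r, d[2] / r };
    bool fi = fr.ok[i], fj = fr.ok[j];
    double bi = 0, bj = 0, ni = 0, nj = 0;
    if (fi) {
      bi = fr.b[3*i]*rh[0] + fr.b[3*i+1]*rh[1] + fr.b[3*i+2]*rh[2];
      ni = fr.n[3*i]*rh[0] + fr.n[3*i+1]*rh[1] + fr.n[3*i+2]*rh[2];
    }
    if (fj) {
      bj = fr.b[3*j]*rh[0] + fr.b[3*j+1]*rh[1] + fr.b[3*j+2]*rh[2];
      nj = fr.n[3*j]*rh[0] + fr.n[3*j+1]*rh[1] + fr.n[3*j+2]*rh[2];
    }
    // side chain of i points along -n_i, toward j when (-n_i).rhat > cos
    bool side_i = fi && (-ni >= P.cos_ss);
    bool side_j = fj && (nj >= P.cos_ss); // toward i: (-n_j).(-rhat)
    bool back_i = fi && (std::fabs(bi) >= P.cos_bb);
    bool back_j = fj && (std::fabs(bj) >= P.cos_bb);
    bool side_i_bs = fi && (-ni >= P.cos_bs);
    bool side_j_bs = fj && (nj >= P.cos_bs);
    Cand c; c.i = i; c.j = j; c.r = r;
    if (T.cys[i] && T.cys[j] && !cys_busy[i] && !cys_busy[j] &&
        r < P.capture * r0cc && side_i && side_j &&
        ss_free(i) && ss_free(j)) {
      c.kind = 5; c.r0 = r0cc; c.depth = P.depth_dis;
      cands.push_back(c);
      continue;
    }
    if (back_i && back_j && r < P.capture * P.r_bb &&
        bb_free(i) && bb_free(j)) {
      c.kind = 1; c.r0 = P.r_bb; c.depth = P.depth_contact;
      cands.push_back(c);
      continue;
    }
    if (back_i && side_j_bs && r < P.capture * P.r_bs &&
        bb_free(i) && ss_free(j)) {
      c.kind = 2; c.r0 = P.r_bs; c.depth = P.depth_contact;
      cands.push_back(c);
      continue;
    }
    if (side_i_bs && back_j && r < P.capture * P.r_bs &&
        ss_free(i) && bb_free(j)) {
      c.kind = 3; c.r0 = P.r_bs; c.depth = P.depth_contact;
      cands.push_back(c);
      continue;
    }
    double r0ss = P.r_ss[T.type[i] * 20 + T.type[j]];
    if (side_i && side_j && r < P.capture * r0ss &&
        ss_free(i) && ss_free(j)) {
      c.kind = 4; c.r0 = r0ss; c.depth = P.depth_contact;
      cands.push_back(c);
    }
  }
}

// One registry maintenance pass: rupture check, candidate admission
// (greedy by distance, then lexicographic), wall candidates; then a
// lambda advance by dtau.
static void registry_step(const std::vector<double>& X, const BoxG& B,
                          const Topo& T, const Pars& P, const Frames& fr,
                          std::vector<Rec>& regs,
                          const std::vector<std::pair<int, int>>& plist,
                          double dtau, int* cys_violation) {
  double d[3];
  // rupture
  for (size_t q = 0; q < regs.size(); ++q) {
    Rec& rc = regs[q];
    if (rc.kind == 6 || rc.dir == -1) continue;
    double r;
    if (rc.kind == 7) {
      double z = X[3 * rc.i + 2];
      r = (rc.j == -1) ? (z - B.zlo) : (B.zhi - z);
    } else {
      mi_disp(B, X[3 * rc.j] - X[3 * rc.i], X[3 * rc.j + 1] - X[3 * rc.i + 1],
              X[3 * rc.j + 2] - X[3 * rc.i + 2], d);
      r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    }
    if (r > P.breakage * rc.r0 / TWO16) rc.dir = -1;
  }

  // admission
  std::vector<Cand> cands;
  find_candidates(X, B, T, P, fr, regs, plist, cands);
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.r != b.r) return a.r < b.r;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  SlotCount S;
  count_slots(regs, T.N, S);
  std::vector<int> ncss;
  eff_nc_ss(X, B, T, P, plist, ncss);
  for (size_t q = 0; q < cands.size(); ++q) {
    const Cand& c = cands[q];
    bool okslot = true;
    switch (c.kind) {
    case 1:
      okslot = S.bb[c.i] < P.nc_bb[T.type[c.i]] &&
               S.bb[c.j] < P.nc_bb[T.type[c.j]];
      break;
    case 2:
      okslot = S.bb[c.i] < P.nc_bb[T.type[c.i]] && S.ss[c.j] < ncss[c.j];
      break;
    case 3:
      okslot = S.ss[c.i] < ncss[c.i] && S.bb[c.j] < P.nc_bb[T.type[c.j]];
      break;
    case 4:
      okslot = S.ss[c.i] < ncss[c.i] && S.ss[c.j] < ncss[c.j];
      break;
    case 5:
      okslot = S.ss[c.i] < ncss[c.i] && S.ss[c.j] < ncss[c.j] &&
               S.dis[c.i] == 0 && S.dis[c.j] == 0;
      break;
    }
    if (!okslot) continue;
    Rec nr;
    nr.i = c.i; nr.j = c.j; nr.kind = c.kind;
    nr.r0 = c.r0; nr.depth = c.depth; nr.lambda = 0.0; nr.dir = 1;
    regs.push_back(nr);
    switch (c.kind) {
    case 1: S.bb[c.i]++; S.bb[c.j]++; break;
    case 2: S.bb[c.i]++; S.ss[c.j]++; break;
    case 3: S.ss[c.i]++; S.bb[c.j]++; break;
    case 4: S.ss[c.i]++; S.ss[c.j]++; break;
    case 5: S.ss[c.i]++; S.ss[c.j]++; S.dis[c.i]++; S.dis[c.j]++; break;
    }
  }

  // adhesive wall candidates
  if (B.adhesion) {
    std::vector<char> haveW(2 * T.N, 0);
    for (size_t q = 0; q < regs.size(); ++q)
      if (regs[q].kind == 7)
        haveW[2 * regs[q].i + ((regs[q].j == -1) ? 0 : 1)] = 1;
    for (int i = 0; i < T.N; ++i) {
      double z = X[3 * i + 2];
      double dd[2] = { z - B.zlo, B.zhi - z };
      for (int w = 0; w < 2; ++w) {
        if (haveW[2 * i + w]) continue;
        if (dd[w] < P.capture * P.wall_r0) {
          Rec nr;
          nr.i = i; nr.j = (w == 0) ? -1 : -2; nr.kind = 7;
          nr.r0 = P.wall_r0; nr.depth = P.wall_depth;
          nr.lambda = 0.0; nr.dir = 1;
          regs.push_back(nr);
        }
      }
    }
  }

  // lambda advance and removal
  double dl = dtau / P.switch_time;
  std::vector<Rec> keep;
  keep.reserve(regs.size());
  for (size_t q = 0; q < regs.size(); ++q) {
    Rec rc = regs[q];
    if (rc.dir == 1) {
      rc.lambda += dl;
      if (rc.lambda >= 1.0) { rc.lambda = 1.0; rc.dir = 0; }
    } else if (rc.dir == -1) {
      rc.lambda -= dl;
      if (rc.lambda <= 0.0) continue; // removed
    }
    keep.push_back(rc);
  }
  regs.swap(keep);

  if (cys_violation) {
    std::vector<int> nd(T.N, 0);
    for (size_t q = 0; q < regs.size(); ++q)
      if (regs[q].kind == 5) { nd[regs[q].i]++; nd[regs[q].j]++; }
    for (int i = 0; i < T.N; ++i)
      if (nd[i] > *cys_violation) *cys_violation = nd[i];
  }
}

// --------------------------------------------------------- exported ------

static std::vector<double> xvec_from(const NumericMatrix& x) {
  std::vector<double> X(3 * x.nrow());
  for (int i = 0; i < x.nrow(); ++i)
    for (int q = 0; q < 3; ++q) X[3 * i + q] = x(i, q);
  return X;
}

static NumericMatrix xmat_to(const std::vector<double>& X) {
  int n = (int)X.size() / 3;
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < 3; ++q) m(i, q) = X[3 * i + q];
  return m;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix x, List boxL, List topoL, List parsL,
                       DataFrame regdf) {
  BoxG B = box_from_list(boxL);
  Topo T = topo_from_list(topoL);
  Pars P = pars_from_list(parsL);
  std::vector<double> X = xvec_from(x);
  for (double v : X) if (!std::isfinite(v)) stop("non-finite position");
  std::vector<Rec> regs = regs_from_df(regdf);
  std::vector<std::pair<int, int>> plist;
  build_plist(X, B, T, P.rlist(), plist);
  std::unordered_set<uint64_t> active;
  for (size_t q = 0; q < regs.size(); ++q)
    if (regs[q].kind != 7) active.insert(pkey(regs[q].i, regs[q].j));
  std::vector<double> F;
  double EB[E_NSLOT];
  forces_all(X, B, T, P, regs, plist, active, F, EB);
  NumericVector eb = NumericVector::create(
      _["bond"] = EB[E_BOND], _["angle"] = EB[E_ANGLE],
      _["dihedral"] = EB[E_DIH], _["excluded"] = EB[E_EXCL],
      _["contact_bb"] = EB[E_BB], _["contact_bs"] = EB[E_BS],
      _["contact_ss"] = EB[E_SS], _["go"] = EB[E_GO],
      _["disulfide"] = EB[E_DIS], _["electrostatic"] = EB[E_ELEC],
      _["wall"] = EB[E_WALL], _["total"] = EB[E_TOT]);
  return List::create(_["breakdown"] = eb, _["forces"] = xmat_to(F));
}

// [[Rcpp::export]]
List cpp_local_frames(NumericMatrix x, List boxL, List topoL) {
  BoxG B = box_from_list(boxL);
  Topo T = topo_from_list(topoL);
  std::vector<double> X = xvec_from(x);
  Frames fr;
  comp_frames(X, B, T, fr);
  LogicalVector ok(T.N);
  for (int i = 0; i < T.N; ++i) ok[i] = fr.ok[i] == 1;
  return List::create(_["normal"] = xmat_to(fr.n),
                      _["binormal"] = xmat_to(fr.b), _["ok"] = ok);
}

// [[Rcpp::export]]
DataFrame cpp_candidates(NumericMatrix x, List boxL, List topoL, List parsL,
                         DataFrame regdf) {
  BoxG B = box_from_list(boxL);
  Topo T = topo_from_list(topoL);
  Pars P = pars_from_list(parsL);
  std::vector<double> X = xvec_from(x);
  std::vector<Rec> regs = regs_from_df(regdf);
  std::vector<std::pair<int, int>> plist;
  build_plist(X, B, T, P.rlist(), plist);
  Frames fr;
  comp_frames(X, B, T, fr);
  std::vector<Cand> cands;
  find_candidates(X, B, T, P, fr, regs, plist, cands);
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.r != b.r) return a.r < b.r;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  int n = (int)cands.size();
  IntegerVector ci(n), cj(n), ck(n);
  NumericVector cr(n), cr0(n);
  for (int q = 0; q < n; ++q) {
    ci[q] = cands[q].i + 1; cj[q] = cands[q].j + 1;
    ck[q] = cands[q].kind; cr[q] = cands[q].r; cr0[q] = cands[q].r0;
  }
  return DataFrame::create(_["i"] = ci, _["j"] = cj, _["kind"] = ck,
                           _["r"] = cr, _["r0"] = cr0);
}

// [[Rcpp::export]]
List cpp_registry_step(NumericMatrix x, List boxL, List topoL, List parsL,
                       DataFrame regdf, double dtau) {
  BoxG B = box_from_list(boxL);
  Topo T = topo_from_list(topoL);
  Pars P = pars_from_list(parsL);
  std::vector<double> X = xvec_from(x);
  std::vector<Rec> regs = regs_from_df(regdf);
  std::vector<std::pair<int, int>> plist;
  build_plist(X, B, T, P.rlist(), plist);
  Frames fr;
  comp_frames(X, B, T, fr);
  int viol = 0;
  registry_step(X, B, T, P, fr, regs, plist, dtau, &viol);
  return List::create(_["registry"] = regs_to_df(regs),
                      _["max_disulfides_per_cys"] = viol);
}

// [[Rcpp::export]]
IntegerVector cpp_effective_nc_ss(NumericMatrix x, List boxL, List topoL,
                                  List parsL) {
  BoxG B = box_from_list(boxL);
  Topo T = topo_from_list(topoL);
  Pars P = pars_from_list(parsL);
  std::vector<double> X = xvec_from(x);
  std::vector<std::pair<int, int>> plist;
  build_plist(X, B, T, std::max(P.rlist(), P.solv_r + 0.5), plist);
  std::vector<int> nc;
  eff_nc_ss(X, B, T, P, plist, nc);
  return IntegerVector(nc.begin(), nc.end());
}

// Motion: type 0 none, 1 squeeze {rate, target_Lx, target_Ly, target_gap},
// 2 oscillate {mode (1 shear, 2 normal), amp, period}.
// [[Rcpp::export]]
List cpp_run_segment(NumericMatrix x, NumericMatrix v, List boxL,
                     DataFrame regdf, List topoL, List parsL,
                     int n_steps, List motion, int frame_stride,
                     NumericVector rng_state, double t0,
                     bool collect_registry) {
  BoxG B = box_from_list(boxL);
  Topo T = topo_from_list(topoL);
  Pars P = pars_from_list(parsL);
  std::vector<double> X = xvec_from(x), Vv = xvec_from(v);
  std::vector<Rec> regs = regs_from_df(regdf);
  RNG rng = rng_from(rng_state);

  // permanent go-contact records are created R-side at state creation
  int mtype = as<int>(motion["type"]);
  double mrate = 0, tLx = 0, tLy = 0, tgap = 0, mamp = 0, mper = 0;
  int mmode = 1;
  if (mtype == 1) {
    mrate = as<double>(motion["rate"]);
    tLx = as<double>(motion["target_Lx"]);
    tLy = as<double>(motion["target_Ly"]);
    tgap = as<double>(motion["target_gap"]);
  } else if (mtype == 2) {
    mmode = as<int>(motion["mode"]);
    mamp = as<double>(motion["amp"]);
    mper = as<double>(motion["period"]);
  }
  double Lx0 = B.Lx, Ly0 = B.Ly, tilt0 = B.tilt;

  double rl = P.rlist();
  std::vector<std::pair<int, int>> plist;
  build_plist(X, B, T, rl, plist);
  std::unordered_set<uint64_t> active;
  auto rebuild_active = [&]() {
    active.clear();
    for (size_t q = 0; q < regs.size(); ++q)
      if (regs[q].kind != 7) active.insert(pkey(regs[q].i, regs[q].j));
  };
  rebuild_active();

  std::vector<double> F;
  double EB[E_NSLOT];
  forces_all(X, B, T, P, regs, plist, active, F, EB);

  double c1 = std::exp(-P.gamma * P.dt / P.mass);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) *
              std::sqrt(P.kBT / P.mass);
  double hdtm = 0.5 * P.dt / P.mass;

  List frames;
  std::vector<List> fvec;
  Frames fr;
  int viol = 0;
  int rebuild_every = 12;
  double t = t0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int k = 0; k < 3 * T.N; ++k) Vv[k] += hdtm * F[k];
    // A
    for (int k = 0; k < 3 * T.N; ++k) X[k] += 0.5 * P.dt * Vv[k];
    // O
    if (P.kBT > 0.0 || c1 != 1.0)
      for (int k = 0; k < 3 * T.N; ++k)
        Vv[k] = c1 * Vv[k] + c2 * rng.gauss();
    // A
    for (int k = 0; k < 3 * T.N; ++k) X[k] += 0.5 * P.dt * Vv[k];

    t = t0 + step * P.dt;

    // imposed box kinematics + wrap into the cell (X/Y only)
    BoxG Bn = B;
    if (mtype == 1) {
      Bn.Lx = std::max(tLx, B.Lx - mrate * P.dt);
      Bn.Ly = std::max(tLy, B.Ly - mrate * P.dt);
      double gap = B.zhi - B.zlo;
      double ng = std::max(tgap, gap - mrate * P.dt);
      double zc = 0.5 * (B.zlo + B.zhi);
      Bn.zlo = zc - 0.5 * ng; Bn.zhi = zc + 0.5 * ng;
    } else if (mtype == 2) {
      double ph = std::sin(2.0 * M_PI * (t - t0) / mper);
      if (mmode == 1) {
        Bn.tilt = tilt0 + mamp * Ly0 * ph;
      } else {
        double fac = 1.0 + mamp * ph;
        Bn.Lx = Lx0 * fac;
        Bn.Ly = Ly0 / fac;
      }
    }
    for (int i = 0; i < T.N; ++i) {
      double s2 = X[3 * i + 1] / B.Ly;
      double s1 = (X[3 * i] - s2 * B.tilt) / B.Lx;
      s1 -= std::floor(s1);
      s2 -= std::floor(s2);
      X[3 * i] = s1 * Bn.Lx + s2 * Bn.tilt;
      X[3 * i + 1] = s2 * Bn.Ly;
    }
    B = Bn;

    if (step % rebuild_every == 0) build_plist(X, B, T, rl, plist);

    if (step % P.stride == 0) {
      comp_frames(X, B, T, fr);
      size_t nreg = regs.size();
      registry_step(X, B, T, P, fr, regs, plist, P.dt * P.stride, &viol);
      (void)nreg;
      rebuild_active();
    }

    forces_all(X, B, T, P, regs, plist, active, F, EB);
    for (int k = 0; k < 3 * T.N; ++k) {
      if (!std::isfinite(F[k])) stop("non-finite force at t=%f", t);
      Vv[k] += hdtm * F[k];
    }

    if (frame_stride > 0 && step % frame_stride == 0) {
      List f = List::create(_["x"] = xmat_to(X), _["v"] = xmat_to(Vv),
                            _["box"] = box_to_list(B), _["time"] = t);
      if (collect_registry) f["registry"] = regs_to_df(regs);
      fvec.push_back(f);
    }
  }

  List out;
  out["x"] = xmat_to(X);
  out["v"] = xmat_to(Vv);
  out["box"] = box_to_list(B);
  out["registry"] = regs_to_df(regs);
  out["rng"] = rng_to(rng);
  out["time"] = t;
  out["frames"] = wrap(fvec);
  out["max_disulfides_per_cys"] = viol;
  return out;
}
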