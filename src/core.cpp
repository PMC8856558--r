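// Mechanics core for lumensim.
//
// Internal unit system (set up by the R layer): length um, time s,
// force nN. All out-of-plane (slab-depth) factors are folded into the
// per-element coefficients before they reach this file.
//
// Deformable cells are closed CCW node rings; element i joins node i to
// the next node of the same ring. Center-based (CBM) cells are discs.
// The stepper is explicit Euler on the overdamped force balance with
// per-node diagonal friction.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// fast 2-norm (no overflow guards needed at tissue scale)
static inline double lhyp(double x, double y) { return std::sqrt(x * x + y * y); }

// ----------------------------------------------------------------------
// RNG: splitmix64 streams keyed per cell / particle for reproducibility
// ----------------------------------------------------------------------
static inline uint64_t sm64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
struct Stream {
  uint64_t s;
  explicit Stream(uint64_t key) : s(key ^ 0xD1B54A32D192ED03ULL) {
    for (int i = 0; i < 3; ++i) sm64(s);  // decorrelate nearby keys
  }
  double unif() { return (sm64(s) >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};
static inline uint64_t key3(uint64_t seed, uint64_t counter, uint64_t id) {
  uint64_t k = seed;
  k ^= counter * 0xBF58476D1CE4E5B9ULL + 0x9E3779B97F4A7C15ULL;
  k ^= id * 0x94D049BB133111EBULL + 0x2545F4914F6CDD1DULL;
  return k;
}

// ----------------------------------------------------------------------
// Flattened simulation state
// ----------------------------------------------------------------------
struct Sim {
  int N = 0, C = 0, M = 0;
  // nodes
  std::vector<double> px, py;
  std::vector<int> off;      // C+1 ring offsets
  std::vector<int> cellof;   // node -> cell
  std::vector<int> nxt, prv; // ring-neighbour node indices
  // elements (indexed by start node)
  std::vector<double> rest, rest0, kel, welem, l0n, cfac;
  std::vector<int> region;   // 0 lateral, 1 apical, 2 basal, 3 TJ
  std::vector<int> marked;
  // cells
  std::vector<double> Aref, KV, kb, th0, Dmig, cfx, cfy;
  std::vector<int> cid, cfixed;
  // CBM
  std::vector<double> bx, by, brad, bE, bnu, bW, bD, bfex, bfey;
  std::vector<int> bid, bfix;
  // tracers
  std::vector<double> tx, ty;
  std::vector<int> towner, tpid;  // owner: -1 retired, 0 extracellular, >0 cell index+1
};

struct Pars {
  double dt, g_ext, g_free, g_int, g_cbm, h_int, k_rep, PL, Dtp, r_cap,
      skin, domR, maxdisp, cbm_tol, gap_open, gap_close, tau_ve, kcoef;
  int tp_every, cbm_iters;
  std::vector<double> jx, jy;  // JKR density-correction table over delta/R*
  uint64_t seed, counter;
};

static Pars read_pars(List p) {
  Pars q;
  q.dt = as<double>(p["dt"]);
  q.g_ext = as<double>(p["g_ext"]);
  q.g_free = as<double>(p["g_free"]);
  q.g_int = as<double>(p["g_int"]);
  q.g_cbm = as<double>(p["g_cbm"]);
  q.h_int = as<double>(p["h_int"]);
  q.k_rep = as<double>(p["k_rep"]);
  q.PL = as<double>(p["PL"]);
  q.Dtp = as<double>(p["Dtp"]);
  q.r_cap = as<double>(p["r_cap"]);
  q.skin = as<double>(p["skin"]);
  q.domR = as<double>(p["domR"]);
  q.maxdisp = as<double>(p["maxdisp"]);
  q.cbm_tol = as<double>(p["cbm_tol"]);
  q.gap_open = as<double>(p["gap_open"]);
  q.gap_close = as<double>(p["gap_close"]);
  q.tau_ve = as<double>(p["tau_ve"]);
  q.kcoef = as<double>(p["kcoef"]);
  q.tp_every = as<int>(p["tp_every"]);
  q.cbm_iters = as<int>(p["cbm_iters"]);
  q.jx = as<std::vector<double>>(p["jx"]);
  q.jy = as<std::vector<double>>(p["jy"]);
  q.seed = (uint64_t)as<double>(p["seed"]);
  q.counter = (uint64_t)as<double>(p["counter"]);
  return q;
}

static Sim read_sim(List s) {
  Sim z;
  NumericMatrix pos = s["pos"];
  z.N = pos.nrow();
  z.px.resize(z.N); z.py.resize(z.N);
  for (int i = 0; i < z.N; ++i) { z.px[i] = pos(i, 0); z.py[i] = pos(i, 1); }
  z.off = as<std::vector<int>>(s["off"]);
  z.C = (int)z.off.size() - 1;
  z.cellof.assign(z.N, 0);
  z.nxt.assign(z.N, 0); z.prv.assign(z.N, 0);
  for (int c = 0; c < z.C; ++c) {
    int a = z.off[c], b = z.off[c + 1];
    for (int i = a; i < b; ++i) {
      z.cellof[i] = c;
      z.nxt[i] = (i + 1 < b) ? i + 1 : a;
      z.prv[i] = (i - 1 >= a) ? i - 1 : b - 1;
    }
  }
  z.rest = as<std::vector<double>>(s["rest"]);
  z.rest0 = as<std::vector<double>>(s["rest0"]);
  z.kel = as<std::vector<double>>(s["kel"]);
  z.cfac = as<std::vector<double>>(s["cfac"]);
  z.welem = as<std::vector<double>>(s["welem"]);
  z.region = as<std::vector<int>>(s["region"]);
  z.marked = as<std::vector<int>>(s["marked"]);
  z.Aref = as<std::vector<double>>(s["Aref"]);
  z.KV = as<std::vector<double>>(s["KV"]);
  z.kb = as<std::vector<double>>(s["kb"]);
  z.th0 = as<std::vector<double>>(s["th0"]);
  z.Dmig = as<std::vector<double>>(s["Dmig"]);
  z.cfx = as<std::vector<double>>(s["cfx"]);
  z.cfy = as<std::vector<double>>(s["cfy"]);
  z.cid = as<std::vector<int>>(s["cid"]);
  z.cfixed = as<std::vector<int>>(s["cfixed"]);
  z.l0n.assign(z.N, 0.0);
  for (int i = 0; i < z.N; ++i) z.l0n[i] = 0.5 * (z.rest[i] + z.rest[z.prv[i]]);
  NumericMatrix cb = s["cbm"];
  z.M = cb.nrow();
  z.bx.resize(z.M); z.by.resize(z.M); z.brad.resize(z.M); z.bE.resize(z.M);
  z.bnu.resize(z.M); z.bW.resize(z.M); z.bD.resize(z.M);
  z.bfex.resize(z.M); z.bfey.resize(z.M);
  for (int j = 0; j < z.M; ++j) {
    z.bx[j] = cb(j, 0); z.by[j] = cb(j, 1); z.brad[j] = cb(j, 2);
    z.bE[j] = cb(j, 3); z.bnu[j] = cb(j, 4); z.bW[j] = cb(j, 5);
    z.bD[j] = cb(j, 6); z.bfex[j] = cb(j, 7); z.bfey[j] = cb(j, 8);
  }
  z.bfix = as<std::vector<int>>(s["cbm_fixed"]);
  z.bid = as<std::vector<int>>(s["cbm_id"]);
  NumericMatrix tp = s["tp"];
  int K = tp.nrow();
  z.tx.resize(K); z.ty.resize(K); z.towner.resize(K); z.tpid.resize(K);
  for (int k = 0; k < K; ++k) {
    z.tx[k] = tp(k, 0); z.ty[k] = tp(k, 1);
    z.towner[k] = (int)tp(k, 2); z.tpid[k] = (int)tp(k, 3);
  }
  return z;
}

// ----------------------------------------------------------------------
// Cohesive-zone traction law (per side; both surfaces carry half the
// work of separation). E is the pair work-of-separation per unit
// contact length; positive tau = attraction.
// ----------------------------------------------------------------------
static inline double traction(double d, double E, double h, double krep) {
  double t0 = E / (1.5 * h);  // per-side Dugdale plateau, trapezoid integral
  double hc = 0.5 * h;
  if (d >= h) return 0.0;
  if (d >= hc) return t0 * (h - d) / (h - hc);
  if (d >= 0.0) return t0;
  return t0 + krep * d;  // linear repulsion below contact
}
// energy per unit node length: U(d) = -int_d^h tau(u) du
static inline double u_of_d(double d, double E, double h, double krep) {
  double t0 = E / (1.5 * h);
  double hc = 0.5 * h;
  if (d >= h) return 0.0;
  if (d >= hc) { double u = h - d; return -0.5 * t0 * u * u / (h - hc); }
  double Uhc = -0.5 * t0 * (h - hc);              // U at d = hc
  if (d >= 0.0) return Uhc - t0 * (hc - d);
  double U0 = Uhc - t0 * hc;                      // U at d = 0
  // int_d^0 (t0 + krep u) du = -t0 d - krep d^2/2
  return U0 - (-t0 * d - 0.5 * krep * d * d) * 1.0;
}

// ----------------------------------------------------------------------
// Spatial grid over element midpoints
// ----------------------------------------------------------------------
struct Grid {
  double x0, y0, cs;
  int nx, ny;
  std::vector<int> head, items;  // counting-sort layout, reused buffers
  void build(const Sim& z, double cellsize) {
    cs = cellsize;
    double xmin = 1e300, ymin = 1e300, xmax = -1e300, ymax = -1e300;
    for (int i = 0; i < z.N; ++i) {
      xmin = std::min(xmin, z.px[i]); xmax = std::max(xmax, z.px[i]);
      ymin = std::min(ymin, z.py[i]); ymax = std::max(ymax, z.py[i]);
    }
    if (z.N == 0) { xmin = ymin = 0; xmax = ymax = 1; }
    x0 = xmin - cs; y0 = ymin - cs;
    nx = std::max(1, (int)((xmax - x0) / cs) + 2);
    ny = std::max(1, (int)((ymax - y0) / cs) + 2);
    size_t nb = (size_t)nx * ny;
    head.assign(nb + 1, 0);
    items.resize(z.N);
    std::vector<int> binof(z.N);
    for (int e = 0; e < z.N; ++e) {
      double mx = 0.5 * (z.px[e] + z.px[z.nxt[e]]);
      double my = 0.5 * (z.py[e] + z.py[z.nxt[e]]);
      int ix = std::min(nx - 1, std::max(0, (int)((mx - x0) / cs)));
      int iy = std::min(ny - 1, std::max(0, (int)((my - y0) / cs)));
      binof[e] = iy * nx + ix;
      ++head[binof[e] + 1];
    }
    for (size_t b = 0; b < nb; ++b) head[b + 1] += head[b];
    std::vector<int> cur(head.begin(), head.end() - 1);
    for (int e = 0; e < z.N; ++e) items[cur[binof[e]]++] = e;
  }
  template <class F>
  void near(double x, double y, double r, F f) const {
    int ix0 = std::max(0, (int)((x - r - x0) / cs));
    int ix1 = std::min(nx - 1, (int)((x + r - x0) / cs));
    int iy0 = std::max(0, (int)((y - r - y0) / cs));
    int iy1 = std::min(ny - 1, (int)((y + r - y0) / cs));
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix) {
        int b = iy * nx + ix;
        for (int k = head[b]; k < head[b + 1]; ++k) f(items[k]);
      }
  }
};

static inline double seg_dist(double x, double y, double ax, double ay,
                              double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = L2 > 0 ? ((x - ax) * dx + (y - ay) * dy) / L2 : 0.0;
  t = std::min(1.0, std::max(0.0, t));
  double cx = ax + t * dx, cy = ay + t * dy;
  return lhyp(x - cx, y - cy);
}

// ----------------------------------------------------------------------
// Neighbour lists
// ----------------------------------------------------------------------
struct Neigh {
  std::vector<int> estart, elist;      // node -> candidate foreign elements
  std::vector<int> bstart, blist;      // node -> candidate CBM cells
  std::vector<std::pair<int,int>> bb;  // CBM-CBM pairs
  std::vector<double> rbx, rby, rbbx, rbby;  // positions at rebuild
  double maxelen = 1.0;
  Grid grid;
  void build(const Sim& z, const Pars& p) {
    maxelen = 0.5;
    for (int e = 0; e < z.N; ++e) {
      double L = lhyp(z.px[z.nxt[e]] - z.px[e], z.py[z.nxt[e]] - z.py[e]);
      maxelen = std::max(maxelen, L);
    }
    double cutoff = p.h_int + p.skin;
    grid.build(z, cutoff + maxelen);
    estart.assign(z.N + 1, 0);
    elist.clear();
    std::vector<int> tmp;
    for (int i = 0; i < z.N; ++i) {
      tmp.clear();
      int ci = z.cellof[i];
      grid.near(z.px[i], z.py[i], cutoff + 0.5 * maxelen, [&](int e) {
        if (z.cellof[e] == ci) return;
        double d = seg_dist(z.px[i], z.py[i], z.px[e], z.py[e],
                            z.px[z.nxt[e]], z.py[z.nxt[e]]);
        if (d <= cutoff) tmp.push_back(e);
      });
      estart[i + 1] = estart[i] + (int)tmp.size();
      for (int e : tmp) elist.push_back(e);
    }
    bstart.assign(z.N + 1, 0);
    blist.clear();
    for (int i = 0; i < z.N; ++i) {
      int n0 = (int)blist.size();
      for (int j = 0; j < z.M; ++j) {
        double d = lhyp(z.px[i] - z.bx[j], z.py[i] - z.by[j]) - z.brad[j];
        if (d <= cutoff) blist.push_back(j);
      }
      bstart[i + 1] = n0 + ((int)blist.size() - n0);
    }
    for (int i = 1; i <= z.N; ++i) bstart[i] = std::max(bstart[i], bstart[i - 1]);
    bb.clear();
    for (int i = 0; i < z.M; ++i)
      for (int j = i + 1; j < z.M; ++j) {
        double gap = lhyp(z.bx[i] - z.bx[j], z.by[i] - z.by[j]) -
                     z.brad[i] - z.brad[j];
        // JKR adhesion of soft cells acts over ~um-scale negative overlap
        if (gap <= p.skin + 4.0) bb.emplace_back(i, j);
      }
    rbx = z.px; rby = z.py; rbbx = z.bx; rbby = z.by;
  }
  double drift(const Sim& z) const {
    double m = 0.0;
    for (int i = 0; i < z.N; ++i)
      m = std::max(m, lhyp(z.px[i] - rbx[i], z.py[i] - rby[i]));
    for (int j = 0; j < z.M; ++j)
      m = std::max(m, lhyp(z.bx[j] - rbbx[j], z.by[j] - rbby[j]));
    return m;
  }
};

// ----------------------------------------------------------------------
// JKR sphere-sphere contact (with density-correction multiplier)
// ----------------------------------------------------------------------
static double jkr_delta_of_a(double a, double Rs, double Es, double w) {
  return a * a / Rs - std::sqrt(2.0 * M_PI * w * a / Es);
}
// solves the JKR overlap-contact-radius relation; returns a (or -1 if
// separated beyond the fixed-grips detachment point)
static double jkr_a_of_delta(double delta, double Rs, double Es, double w) {
  double admin = std::pow(0.25 * Rs * std::sqrt(2.0 * M_PI * w / Es), 2.0 / 3.0);
  double dmin = jkr_delta_of_a(admin, Rs, Es, w);
  if (delta < dmin) return -1.0;
  double lo = admin, hi = std::max(2.0 * admin, std::sqrt(std::max(delta, 0.0) * Rs) + admin);
  while (jkr_delta_of_a(hi, Rs, Es, w) < delta) hi *= 2.0;
  // coarse bisection bracket, then Newton polish
  for (int it = 0; it < 20; ++it) {
    double mid = 0.5 * (lo + hi);
    if (jkr_delta_of_a(mid, Rs, Es, w) < delta) lo = mid; else hi = mid;
  }
  double a = 0.5 * (lo + hi);
  double c = std::sqrt(2.0 * M_PI * w / Es);
  for (int it = 0; it < 6; ++it) {
    double f = a * a / Rs - c * std::sqrt(a) - delta;
    double fp = 2.0 * a / Rs - 0.5 * c / std::sqrt(a);
    if (fp <= 0.0) break;
    double an = a - f / fp;
    if (an < lo || an > hi) break;
    if (std::fabs(an - a) < 1e-14 * a) { a = an; break; }
    a = an;
  }
  return a;
}
static double jkr_mult(double rel, const std::vector<double>& jx,
                       const std::vector<double>& jy) {
  if (jx.empty() || rel <= jx.front()) return 1.0;
  if (rel >= jx.back()) return jy.back();
  for (size_t k = 1; k < jx.size(); ++k)
    if (rel <= jx[k]) {
      double t = (rel - jx[k - 1]) / (jx[k] - jx[k - 1]);
      return jy[k - 1] + t * (jy[k] - jy[k - 1]);
    }
  return jy.back();
}
// Modified JKR: the density-correction multiplier (calibrated against a
// DCM cell pair) stiffens the elastic (Hertz) part of the force at
// relative overlaps above 5%; the adhesive term is untouched, so the
// pull-off force stays the classical (3/2) pi w R*.
static double jkr_pair(double delta, double Ri, double Rj, double Ei, double Ej,
                       double nui, double nuj, double w,
                       const std::vector<double>& jx, const std::vector<double>& jy) {
  double Rs = 1.0 / (1.0 / Ri + 1.0 / Rj);
  double Es = 1.0 / ((1.0 - nui * nui) / Ei + (1.0 - nuj * nuj) / Ej);
  if (w <= 0.0) {
    if (delta <= 0.0) return 0.0;
    double F = (4.0 / 3.0) * Es * std::sqrt(Rs) * std::pow(delta, 1.5);
    if (delta > 0.05 * Rs) F *= jkr_mult(delta / Rs, jx, jy);
    return F;
  }
  double a = jkr_a_of_delta(delta, Rs, Es, w);
  if (a < 0.0) return 0.0;
  double m = (delta > 0.05 * Rs) ? jkr_mult(delta / Rs, jx, jy) : 1.0;
  return m * (4.0 / 3.0) * Es * a * a * a / Rs -
         std::sqrt(8.0 * M_PI * w * Es * a * a * a);
}

// [[Rcpp::export]]
NumericVector cpp_jkr_force(NumericVector delta, double Ri, double Rj,
                            double Ei, double Ej, double nui, double nuj,
                            double w, NumericVector jx, NumericVector jy) {
  std::vector<double> vx = as<std::vector<double>>(jx);
  std::vector<double> vy = as<std::vector<double>>(jy);
  NumericVector out(delta.size());
  for (int i = 0; i < delta.size(); ++i)
    out[i] = jkr_pair(delta[i], Ri, Rj, Ei, Ej, nui, nuj, w, vx, vy);
  return out;
}

static bool point_in_ring(const Sim& z, int c, double x, double y);

// ----------------------------------------------------------------------
// Force evaluation. Term masks:
//   1 in-plane, 2 bending, 4 volume, 8 contact, 16 osmotic
// ----------------------------------------------------------------------
static void eval_forces(const Sim& z, const Pars& p, const Neigh& nb, int mask,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& bFx, std::vector<double>& bFy,
                        std::vector<int>& ncontact, std::vector<double>& ngap,
                        bool cbm_pairs = true) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(bFx.begin(), bFx.end(), 0.0);
  std::fill(bFy.begin(), bFy.end(), 0.0);
  std::fill(ncontact.begin(), ncontact.end(), 0);
  std::fill(ngap.begin(), ngap.end(), 1e9);

  // --- per-cell ring terms
  for (int c = 0; c < z.C; ++c) {
    int a = z.off[c], b = z.off[c + 1];
    if (mask & 1) {  // in-plane springs
      for (int i = a; i < b; ++i) {
        int j = z.nxt[i];
        double ex = z.px[j] - z.px[i], ey = z.py[j] - z.py[i];
        double L = lhyp(ex, ey);
        if (L < 1e-12) continue;
        double f = z.kel[i] * (L - z.rest[i]) / L;
        fx[i] += f * ex; fy[i] += f * ey;
        fx[j] -= f * ex; fy[j] -= f * ey;
      }
    }
    if ((mask & 2) && z.kb[c] > 0.0) {  // bending (turning-angle penalty)
      for (int i = a; i < b; ++i) {
        int ip = z.prv[i], in = z.nxt[i];
        double e1x = z.px[i] - z.px[ip], e1y = z.py[i] - z.py[ip];
        double e2x = z.px[in] - z.px[i], e2y = z.py[in] - z.py[i];
        double L1 = e1x * e1x + e1y * e1y, L2 = e2x * e2x + e2y * e2y;
        if (L1 < 1e-18 || L2 < 1e-18) continue;
        double th = std::atan2(e1x * e2y - e1y * e2x, e1x * e2x + e1y * e2y);
        double m = z.kb[c] * (th - z.th0[c]);
        // grad theta: d/dx_prv = perp(e1)/L1, d/dx_nxt = perp(e2)/L2
        double g1x = -e1y / L1, g1y = e1x / L1;
        double g2x = -e2y / L2, g2y = e2x / L2;
        fx[ip] -= m * g1x;          fy[ip] -= m * g1y;
        fx[i]  -= m * (-g1x - g2x); fy[i]  -= m * (-g1y - g2y);
        fx[in] -= m * g2x;          fy[in] -= m * g2y;
      }
    }
    if ((mask & 4) && z.KV[c] > 0.0) {  // volume (area) control
      double A = 0.0;
      for (int i = a; i < b; ++i) {
        int j = z.nxt[i];
        A += z.px[i] * z.py[j] - z.px[j] * z.py[i];
      }
      A *= 0.5;
      double pr = z.KV[c] * (1.0 - A / z.Aref[c]);
      for (int i = a; i < b; ++i) {
        int ip = z.prv[i], in = z.nxt[i];
        fx[i] += pr * 0.5 * (z.py[in] - z.py[ip]);
        fy[i] += pr * 0.5 * (z.px[ip] - z.px[in]);
      }
    }
  }

  // --- contact: node vs nearest point on each foreign cell's boundary
  //     (interior projection or clamped endpoint; the combined distance
  //     field is continuous, so the cohesive energy is too), and node vs
  //     CBM discs
  if (mask & 8) {
    const int MAXC = 16;
    int bcell[MAXC], belem[MAXC], bkind[MAXC];
    double bd[MAXC], bs[MAXC], bnx[MAXC], bny[MAXC];
    for (int i = 0; i < z.N; ++i) {
      int nc = 0;
      for (int k = nb.estart[i]; k < nb.estart[i + 1]; ++k) {
        int e = nb.elist[k];
        int j = z.nxt[e];
        double ax = z.px[e], ay = z.py[e], bx2 = z.px[j], by2 = z.py[j];
        double dx = bx2 - ax, dy = by2 - ay;
        double L2 = dx * dx + dy * dy;
        if (L2 < 1e-18) continue;
        double t = ((z.px[i] - ax) * dx + (z.py[i] - ay) * dy) / L2;
        double d, nx, ny;
        int kind;
        if (t > 0.0 && t < 1.0) {
          double L = std::sqrt(L2);
          nx = dy / L; ny = -dx / L;  // outward normal of CCW ring
          d = (z.px[i] - (ax + t * dx)) * nx + (z.py[i] - (ay + t * dy)) * ny;
          kind = 0;
        } else {
          double qx = (t <= 0.0) ? ax : bx2, qy = (t <= 0.0) ? ay : by2;
          double rx = z.px[i] - qx, ry = z.py[i] - qy;
          double r = lhyp(rx, ry);
          if (r < 1e-12) continue;
          nx = rx / r; ny = ry / r;  // sign resolved for the winner only
          d = r;
          t = (t <= 0.0) ? 0.0 : 1.0;
          kind = 1;
        }
        int oc = z.cellof[e];
        int slot = -1;
        for (int q = 0; q < nc; ++q) if (bcell[q] == oc) { slot = q; break; }
        if (slot < 0) {
          if (nc >= MAXC) continue;
          slot = nc++; bcell[slot] = oc; bd[slot] = 1e300;
        }
        if (std::fabs(d) < std::fabs(bd[slot])) {
          bd[slot] = d; belem[slot] = e; bs[slot] = t;
          bnx[slot] = nx; bny[slot] = ny; bkind[slot] = kind;
        }
      }
      for (int q = 0; q < nc; ++q) {
        double d = bd[q];
        int e = belem[q], j = z.nxt[e];
        double nx = bnx[q], ny = bny[q], t = bs[q];
        if (bkind[q] == 1) {
          // clamped endpoint: sign from containment in the foreign ring
          if (point_in_ring(z, z.cellof[e], z.px[i], z.py[i])) {
            d = -d; nx = -nx; ny = -ny;
          }
        }
        if (d >= p.h_int) continue;
        if (std::fabs(d) < std::fabs(ngap[i])) ngap[i] = d;
        if (std::fabs(d) < std::fabs(ngap[e])) ngap[e] = d;
        if (std::fabs(d) < std::fabs(ngap[j])) ngap[j] = d;
        double Epair = std::min(z.welem[i], z.welem[e]);
        double tau = traction(d, Epair, p.h_int, p.k_rep) * z.l0n[i];
        fx[i] -= tau * nx; fy[i] -= tau * ny;
        fx[e] += tau * nx * (1.0 - t); fy[e] += tau * ny * (1.0 - t);
        fx[j] += tau * nx * t;         fy[j] += tau * ny * t;
        // both surfaces are within interaction range: cell-cell friction
        ncontact[i] = 1; ncontact[e] = 1; ncontact[j] = 1;
      }
      // CBM discs as rigid circular boundaries (cohesive-zone law)
      for (int k = nb.bstart[i]; k < nb.bstart[i + 1]; ++k) {
        int j = nb.blist[k];
        double rx = z.px[i] - z.bx[j], ry = z.py[i] - z.by[j];
        double r = lhyp(rx, ry);
        if (r < 1e-12) continue;
        double d = r - z.brad[j];
        if (d >= p.h_int) continue;
        if (std::fabs(d) < std::fabs(ngap[i])) ngap[i] = d;
        double Epair = std::min(z.welem[i], z.bW[j]);
        double tau = traction(d, Epair, p.h_int, p.k_rep) * z.l0n[i];
        double nx = rx / r, ny = ry / r;
        fx[i] -= tau * nx; fy[i] -= tau * ny;
        bFx[j] += tau * nx; bFy[j] += tau * ny;
        ncontact[i] = 1;
      }
    }
    // CBM-CBM JKR (consumed by the strided CBM update only)
    if (cbm_pairs)
    for (auto& pr : nb.bb) {
      int i = pr.first, j = pr.second;
      double rx = z.bx[i] - z.bx[j], ry = z.by[i] - z.by[j];
      double r = lhyp(rx, ry);
      if (r < 1e-9) continue;
      double delta = z.brad[i] + z.brad[j] - r;
      double w = std::min(z.bW[i], z.bW[j]) / 10.0;  // line energy (W*hz) -> area energy (W), hz = 10
      double F = jkr_pair(delta, z.brad[i], z.brad[j], z.bE[i], z.bE[j],
                          z.bnu[i], z.bnu[j], w, p.jx, p.jy);
      if (F != 0.0) {
        double nx = rx / r, ny = ry / r;
        bFx[i] += F * nx; bFy[i] += F * ny;
        bFx[j] -= F * nx; bFy[j] -= F * ny;
      }
    }
  }

  // --- osmotic loading on marked (free, lumen-facing) elements
  if ((mask & 16) && p.PL > 0.0) {
    for (int e = 0; e < z.N; ++e) {
      if (!z.marked[e]) continue;
      int j = z.nxt[e];
      double ex = z.px[j] - z.px[e], ey = z.py[j] - z.py[e];
      // pressure from the cavity side pushes the wall opposite to the
      // outward normal; current-length lumping, half to each node
      double fxr = -p.PL * ey * 0.5, fyr = p.PL * ex * 0.5;
      fx[e] += fxr; fy[e] += fyr;
      fx[j] += fxr; fy[j] += fyr;
    }
  }
}

static List sim_to_list(const Sim& z) {
  NumericMatrix pos(z.N, 2);
  for (int i = 0; i < z.N; ++i) { pos(i, 0) = z.px[i]; pos(i, 1) = z.py[i]; }
  NumericMatrix cb(z.M, 2);
  for (int j = 0; j < z.M; ++j) { cb(j, 0) = z.bx[j]; cb(j, 1) = z.by[j]; }
  int K = (int)z.tx.size();
  NumericMatrix tp(K, 4);
  for (int k = 0; k < K; ++k) {
    tp(k, 0) = z.tx[k]; tp(k, 1) = z.ty[k];
    tp(k, 2) = z.towner[k]; tp(k, 3) = z.tpid[k];
  }
  return List::create(_["pos"] = pos, _["cbm_pos"] = cb, _["tp"] = tp,
                      _["marked"] = wrap(z.marked), _["rest"] = wrap(z.rest));
}

// Exported: term-wise forces (for the R-level force API and gradient tests)
// [[Rcpp::export]]
List cpp_forces(List state, List params, int mask) {
  Sim z = read_sim(state);
  Pars p = read_pars(params);
  Neigh nb;
  nb.build(z, p);
  std::vector<double> fx(z.N), fy(z.N), bFx(z.M), bFy(z.M);
  std::vector<int> nc(z.N);
  std::vector<double> ng(z.N);
  eval_forces(z, p, nb, mask, fx, fy, bFx, bFy, nc, ng);
  NumericMatrix F(z.N, 2), BF(z.M, 2);
  for (int i = 0; i < z.N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; }
  for (int j = 0; j < z.M; ++j) { BF(j, 0) = bFx[j]; BF(j, 1) = bFy[j]; }
  return List::create(_["F"] = F, _["Fcbm"] = BF, _["node_contact"] = wrap(nc));
}

// ----------------------------------------------------------------------
// Element-level contact classification (standalone; used for regions,
// marking, polarity, differentiation and lumen tracing)
// ----------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_classify_contacts(List state, List params) {
  Sim z = read_sim(state);
  Pars p = read_pars(params);
  Neigh nb;
  nb.build(z, p);
  std::vector<int> ncon(z.N, 0), npart(z.N, -1);
  std::vector<double> ngap(z.N, 1e300);
  const int MAXC = 16;
  for (int i = 0; i < z.N; ++i) {
    int bcell[MAXC]; double bd[MAXC]; int belem[MAXC]; int bkind[MAXC];
    int nc = 0;
    for (int k = nb.estart[i]; k < nb.estart[i + 1]; ++k) {
      int e = nb.elist[k];
      int j = z.nxt[e];
      double ax = z.px[e], ay = z.py[e], bx2 = z.px[j], by2 = z.py[j];
      double dx = bx2 - ax, dy = by2 - ay;
      double L2 = dx * dx + dy * dy;
      if (L2 < 1e-18) continue;
      double t = ((z.px[i] - ax) * dx + (z.py[i] - ay) * dy) / L2;
      double d;
      int kind;
      if (t > 0.0 && t < 1.0) {
        double L = std::sqrt(L2);
        double nx = dy / L, ny = -dx / L;
        d = (z.px[i] - (ax + t * dx)) * nx + (z.py[i] - (ay + t * dy)) * ny;
        kind = 0;
      } else {
        double qx = (t <= 0.0) ? ax : bx2, qy = (t <= 0.0) ? ay : by2;
        d = lhyp(z.px[i] - qx, z.py[i] - qy);
        kind = 1;
      }
      int oc = z.cellof[e];
      int slot = -1;
      for (int q = 0; q < nc; ++q) if (bcell[q] == oc) { slot = q; break; }
      if (slot < 0) { if (nc >= MAXC) continue; slot = nc++; bcell[slot] = oc; bd[slot] = 1e300; }
      if (std::fabs(d) < std::fabs(bd[slot])) {
        bd[slot] = d; belem[slot] = e; bkind[slot] = kind;
      }
    }
    for (int q = 0; q < nc; ++q) {
      double d = bd[q];
      if (bkind[q] == 1 &&
          point_in_ring(z, z.cellof[belem[q]], z.px[i], z.py[i]))
        d = -d;
      if (d <= p.h_int && std::fabs(d) < std::fabs(ngap[i])) {
        ngap[i] = d; npart[i] = belem[q]; ncon[i] = 1;
      }
    }
    for (int k = nb.bstart[i]; k < nb.bstart[i + 1]; ++k) {
      int j = nb.blist[k];
      double d = lhyp(z.px[i] - z.bx[j], z.py[i] - z.by[j]) - z.brad[j];
      if (d <= p.h_int && std::fabs(d) < std::fabs(ngap[i])) {
        ngap[i] = d; npart[i] = -(j + 2); ncon[i] = 1;
      }
    }
  }
  std::vector<int> econ(z.N, 0), epart(z.N, -1);
  for (int e = 0; e < z.N; ++e) {
    int j = z.nxt[e];
    if (ncon[e] || ncon[j]) {
      econ[e] = 1;
      if (ncon[e] && (!ncon[j] || std::fabs(ngap[e]) <= std::fabs(ngap[j])))
        epart[e] = npart[e];
      else
        epart[e] = npart[j];
    }
  }
  std::vector<double> egap(z.N);
  for (int e = 0; e < z.N; ++e)
    egap[e] = std::min(ngap[e], ngap[z.nxt[e]]);
  return List::create(_["node_contact"] = wrap(ncon),
                      _["node_partner"] = wrap(npart),
                      _["elem_contact"] = wrap(econ),
                      _["elem_partner"] = wrap(epart),
                      _["elem_gap"] = wrap(egap));
}

// ----------------------------------------------------------------------
// Tracer step helpers
// ----------------------------------------------------------------------
static inline bool seg_cross(double p0x, double p0y, double p1x, double p1y,
                             double ax, double ay, double bx, double by,
                             double& tout) {
  double rx = p1x - p0x, ry = p1y - p0y;
  double sx = bx - ax, sy = by - ay;
  double den = rx * sy - ry * sx;
  if (std::fabs(den) < 1e-300) return false;
  double qx = ax - p0x, qy = ay - p0y;
  double t = (qx * sy - qy * sx) / den;
  double u = (qx * ry - qy * rx) / den;
  if (t <= 0.0 || t >= 1.0 || u <= 0.0 || u >= 1.0) return false;
  tout = t;
  return true;
}
static bool point_in_ring(const Sim& z, int c, double x, double y) {
  int a = z.off[c], b = z.off[c + 1];
  bool in = false;
  for (int i = a; i < b; ++i) {
    int j = z.nxt[i];
    double xi = z.px[i], yi = z.py[i], xj = z.px[j], yj = z.py[j];
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      in = !in;
  }
  return in;
}
static double cell_cx(const Sim& z, int c, bool yaxis) {
  int a = z.off[c], b = z.off[c + 1];
  double s = 0.0;
  for (int i = a; i < b; ++i) s += yaxis ? z.py[i] : z.px[i];
  return s / (b - a);
}

static void tracer_step(Sim& z, const Pars& p, const Neigh& nb,
                        const std::vector<double>& egap, double dtp,
                        uint64_t counter) {
  int K = (int)z.tx.size();
  double sd = std::sqrt(2.0 * p.Dtp * dtp);
  for (int k = 0; k < K; ++k) {
    if (z.towner[k] < 0) continue;
    Stream rs(key3(p.seed, counter, 0x7F000000ULL + (uint64_t)z.tpid[k]));
    double p0x = z.tx[k], p0y = z.ty[k];
    double p1x = p0x + sd * rs.norm(), p1y = p0y + sd * rs.norm();
    if (z.towner[k] > 0) {
      int c = z.towner[k] - 1;
      int a = z.off[c], b = z.off[c + 1];
      double tbest = 2.0; int ebest = -1;
      for (int e = a; e < b; ++e) {
        double t;
        if (seg_cross(p0x, p0y, p1x, p1y, z.px[e], z.py[e],
                      z.px[z.nxt[e]], z.py[z.nxt[e]], t) && t < tbest) {
          tbest = t; ebest = e;
        }
      }
      if (ebest < 0) { z.tx[k] = p1x; z.ty[k] = p1y; }
      else {
        int j = z.nxt[ebest];
        double ex = z.px[j] - z.px[ebest], ey = z.py[j] - z.py[ebest];
        double L = lhyp(ex, ey);
        double nx = ey / L, ny = -ex / L;
        bool outward = ((p1x - p0x) * nx + (p1y - p0y) * ny) > 0.0;
        if (z.region[ebest] == 1 && egap[ebest] > p.gap_open && outward) {
          // excreted apically: deposited just outside the membrane, in
          // the extracellular cleft
          z.tx[k] = p0x + tbest * (p1x - p0x) + 0.1 * nx;
          z.ty[k] = p0y + tbest * (p1y - p0y) + 0.1 * ny;
          z.towner[k] = 0;
        }
        // else: rejected, stays in place (tight junctions / contacts block)
      }
      // containment safeguard against surfaces sweeping past particles
      if (z.towner[k] > 0 && !point_in_ring(z, c, z.tx[k], z.ty[k])) {
        z.tx[k] = cell_cx(z, c, false);
        z.ty[k] = cell_cx(z, c, true);
      }
    } else {
      // extracellular: reject any move that crosses a cell surface
      bool blocked = false;
      double lox = std::min(p0x, p1x), hix = std::max(p0x, p1x);
      double loy = std::min(p0y, p1y), hiy = std::max(p0y, p1y);
      double r = 0.5 * lhyp(hix - lox, hiy - loy) + nb.maxelen + p.skin;
      nb.grid.near(0.5 * (lox + hix), 0.5 * (loy + hiy), r, [&](int e) {
        if (blocked) return;
        double t;
        if (seg_cross(p0x, p0y, p1x, p1y, z.px[e], z.py[e],
                      z.px[z.nxt[e]], z.py[z.nxt[e]], t))
          blocked = true;
      });
      for (int j = 0; j < z.M && !blocked; ++j) {
        if (lhyp(p1x - z.bx[j], p1y - z.by[j]) < z.brad[j]) blocked = true;
      }
      if (!blocked) { z.tx[k] = p1x; z.ty[k] = p1y; }
      if (lhyp(z.tx[k], z.ty[k]) > p.domR) { z.towner[k] = -1; continue; }
      // a fluctuating surface that sweeps shallowly over an extracellular
      // particle pushes it back out; deep engulfment absorbs it (the ion
      // cloud is taken up by the cell)
      int inc = -1;
      nb.grid.near(z.tx[k], z.ty[k], nb.maxelen + 1.0, [&](int e) {
        int c = z.cellof[e];
        if (inc == c) return;
        if (inc < 0 && point_in_ring(z, c, z.tx[k], z.ty[k])) inc = c;
      });
      if (inc >= 0) {
        int a2 = z.off[inc], b2 = z.off[inc + 1];
        double bdist = 1e300, bcx = 0, bcy = 0;
        for (int e = a2; e < b2; ++e) {
          double dx = z.px[z.nxt[e]] - z.px[e], dy = z.py[z.nxt[e]] - z.py[e];
          double L2 = std::max(dx * dx + dy * dy, 1e-18);
          double t = ((z.tx[k] - z.px[e]) * dx + (z.ty[k] - z.py[e]) * dy) / L2;
          t = std::min(1.0, std::max(0.0, t));
          double cx2 = z.px[e] + t * dx, cy2 = z.py[e] + t * dy;
          double dd = lhyp(z.tx[k] - cx2, z.ty[k] - cy2);
          if (dd < bdist) { bdist = dd; bcx = cx2; bcy = cy2; }
        }
        if (bdist > 0.8) { z.towner[k] = -1; continue; }
        double ox = bcx - z.tx[k], oy = bcy - z.ty[k];
        double on = std::max(lhyp(ox, oy), 1e-12);
        z.tx[k] = bcx + 0.05 * ox / on;
        z.ty[k] = bcy + 0.05 * oy / on;
      }
      // mark nearby open (unsealed) surface elements
      nb.grid.near(z.tx[k], z.ty[k], p.r_cap + nb.maxelen, [&](int e) {
        if (egap[e] <= p.gap_close) return;
        double d = seg_dist(z.tx[k], z.ty[k], z.px[e], z.py[e],
                            z.px[z.nxt[e]], z.py[z.nxt[e]]);
        if (d <= p.r_cap) z.marked[e] = 1;
      });
    }
  }
}

// ----------------------------------------------------------------------
// Main integrator
// ----------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_advance(List state, List params, int nsub) {
  Sim z = read_sim(state);
  Pars p = read_pars(params);
  Neigh nb;
  nb.build(z, p);
  std::vector<double> fx(z.N), fy(z.N), bFx(z.M), bFy(z.M);
  std::vector<int> ncon(z.N), econ(z.N, 0);
  std::vector<double> vbx(z.M, 0.0), vby(z.M, 0.0);
  std::vector<double> gnode(z.N), ngap(z.N), egap(z.N);
  std::vector<int> close_ct(z.N, 0);  // consecutive substeps pressed shut
  bool ok = true;
  int rebuilds = 0;

  for (int step = 0; step < nsub; ++step) {
    if (step > 0 && nb.drift(z) > 0.5 * p.skin) { nb.build(z, p); ++rebuilds; }

    bool cbm_step_now = (z.M > 0) && ((step % 10) == 9);
    eval_forces(z, p, nb, 1 | 2 | 4 | 8 | 16, fx, fy, bFx, bFy, ncon, ngap,
                cbm_step_now);

    // cortical viscoelasticity: the element rest length remodels toward
    // the current length times the active-constriction factor, so elastic
    // tension relaxes on the cortical-turnover timescale while active
    // constriction maintains its strain offset
    if (p.tau_ve > 0.0) {
      double al = p.dt / p.tau_ve;
      for (int c2 = 0; c2 < z.C; ++c2) {
        if (z.cfixed[c2]) continue;
        int a2 = z.off[c2], b2 = z.off[c2 + 1];
        for (int e = a2; e < b2; ++e) {
          double L = lhyp(z.px[z.nxt[e]] - z.px[e], z.py[z.nxt[e]] - z.py[e]);
          double r = z.rest[e] + (L * z.cfac[e] - z.rest[e]) * al;
          // bounded plasticity: turnover cannot grow or shrink an element
          // beyond 40% of its creation length, so membranes keep a finite
          // perimeter and large deformations stay elastic
          r = std::min(std::max(r, 0.6 * z.rest0[e]), 1.4 * z.rest0[e]);
          z.rest[e] = r;
          z.kel[e] = p.kcoef / r;
        }
      }
    }

    // element flags and gaps; an element pressed back into sustained
    // adhesive contact loses its osmotic mark (momentary touches from
    // surface fluctuations do not erase it)
    for (int e = 0; e < z.N; ++e) {
      econ[e] = (ncon[e] || ncon[z.nxt[e]]) ? 1 : 0;
      egap[e] = std::min(ngap[e], ngap[z.nxt[e]]);
      if (egap[e] < p.gap_close) {
        if (++close_ct[e] > 100) z.marked[e] = 0;
      } else {
        close_ct[e] = 0;
      }
    }

    // friction per node
    for (int i = 0; i < z.N; ++i)
      gnode[i] = z.l0n[i] * ((ncon[i] ? p.g_ext : p.g_free) + p.g_int);

    // per-cell external force, distributed equally on all nodes
    for (int c = 0; c < z.C; ++c) {
      if (z.cfixed[c] || (z.cfx[c] == 0.0 && z.cfy[c] == 0.0)) continue;
      int a = z.off[c], b = z.off[c + 1];
      double n = (double)(b - a);
      for (int i = a; i < b; ++i) { fx[i] += z.cfx[c] / n; fy[i] += z.cfy[c] / n; }
    }

    // migration: one Brownian force per cell, equal on all nodes
    for (int c = 0; c < z.C; ++c) {
      if (z.cfixed[c] || z.Dmig[c] <= 0.0) continue;
      int a = z.off[c], b = z.off[c + 1];
      bool freeSurf = false;
      for (int i = a; i < b && !freeSurf; ++i) if (!ncon[i]) freeSurf = true;
      if (!freeSurf) continue;
      double G = 0.0;
      for (int i = a; i < b; ++i) G += gnode[i];
      Stream rs(key3(p.seed, p.counter * 100000ULL + (uint64_t)step, (uint64_t)z.cid[c]));
      double s = G * std::sqrt(2.0 * z.Dmig[c] / p.dt);
      double Fx = s * rs.norm() / (b - a), Fy = s * rs.norm() / (b - a);
      for (int i = a; i < b; ++i) { fx[i] += Fx; fy[i] += Fy; }
    }

    // node update (diagonal friction, explicit Euler)
    for (int c = 0; c < z.C; ++c) {
      if (z.cfixed[c]) continue;
      int a = z.off[c], b = z.off[c + 1];
      for (int i = a; i < b; ++i) {
        double ux = fx[i] / gnode[i] * p.dt, uy = fy[i] / gnode[i] * p.dt;
        if (!std::isfinite(ux) || !std::isfinite(uy)) { ok = false; break; }
        double m = lhyp(ux, uy);
        if (m > p.maxdisp) { ux *= p.maxdisp / m; uy *= p.maxdisp / m; }
        z.px[i] += ux; z.py[i] += uy;
      }
      if (!ok) break;
    }
    if (!ok) break;

    // CBM update: Gamma_ECM v_i + sum_j Gamma_cc (v_i - v_j) = F_i.
    // CBM dynamics are far from their stability limit, so the centers
    // advance every 10th substep with a correspondingly larger step.
    if (cbm_step_now) {
      const double dtc = 10.0 * p.dt;
      std::vector<double> Gd(z.M), mfx(z.M, 0.0), mfy(z.M, 0.0);
      for (int j = 0; j < z.M; ++j) {
        Gd[j] = p.g_cbm * 2.0 * M_PI * z.brad[j];  // slab depth folded into g_cbm
        if (z.bD[j] > 0.0 && !z.bfix[j]) {
          Stream rs(key3(p.seed, p.counter * 100000ULL + (uint64_t)step,
                         0x3F000000ULL + (uint64_t)z.bid[j]));
          double s = Gd[j] * std::sqrt(2.0 * z.bD[j] / dtc);
          mfx[j] = s * rs.norm(); mfy[j] = s * rs.norm();
        }
      }
      std::vector<double> gcc(nb.bb.size());
      for (size_t q = 0; q < nb.bb.size(); ++q) {
        int i = nb.bb[q].first, j = nb.bb[q].second;
        double delta = z.brad[i] + z.brad[j] -
                       lhyp(z.bx[i] - z.bx[j], z.by[i] - z.by[j]);
        if (delta > 0) {
          double Rs = 1.0 / (1.0 / z.brad[i] + 1.0 / z.brad[j]);
          gcc[q] = p.g_ext * 2.0 * std::sqrt(Rs * delta);  // chord length, slab in g_ext
        } else gcc[q] = 0.0;
      }
      std::vector<double> sx(z.M), sy(z.M), sg(z.M);
      double vscale = 1e-12;
      for (int it = 0; it < p.cbm_iters; ++it) {
        double dmax = 0.0;
        std::fill(sx.begin(), sx.end(), 0.0);
        std::fill(sy.begin(), sy.end(), 0.0);
        std::fill(sg.begin(), sg.end(), 0.0);
        for (size_t q = 0; q < nb.bb.size(); ++q) {
          if (gcc[q] <= 0) continue;
          int i = nb.bb[q].first, j = nb.bb[q].second;
          sx[i] += gcc[q] * vbx[j]; sy[i] += gcc[q] * vby[j]; sg[i] += gcc[q];
          sx[j] += gcc[q] * vbx[i]; sy[j] += gcc[q] * vby[i]; sg[j] += gcc[q];
        }
        for (int j = 0; j < z.M; ++j) {
          double nxv = 0.0, nyv = 0.0;
          if (!z.bfix[j]) {
            nxv = (bFx[j] + z.bfex[j] + mfx[j] + sx[j]) / (Gd[j] + sg[j]);
            nyv = (bFy[j] + z.bfey[j] + mfy[j] + sy[j]) / (Gd[j] + sg[j]);
          }
          dmax = std::max(dmax, std::fabs(nxv - vbx[j]) + std::fabs(nyv - vby[j]));
          vscale = std::max(vscale, std::fabs(nxv) + std::fabs(nyv));
          vbx[j] = nxv; vby[j] = nyv;
        }
        if (dmax < p.cbm_tol || dmax < 1e-4 * vscale) break;
      }
      for (int j = 0; j < z.M; ++j) {
        if (z.bfix[j]) continue;
        double ux = vbx[j] * dtc, uy = vby[j] * dtc;
        if (!std::isfinite(ux) || !std::isfinite(uy)) { ok = false; break; }
        double m = lhyp(ux, uy);
        if (m > p.maxdisp) { ux *= p.maxdisp / m; uy *= p.maxdisp / m; }
        z.bx[j] += ux; z.by[j] += uy;
      }
      if (!ok) break;
    }

    if (p.tp_every > 0 && !z.tx.empty() &&
        (step % p.tp_every) == p.tp_every - 1) {
      tracer_step(z, p, nb, egap, p.dt * p.tp_every,
                  p.counter * 100000ULL + (uint64_t)step);
    }
  }

  List out = sim_to_list(z);
  out["elem_contact"] = wrap(econ);
  out["node_contact"] = wrap(ncon);
  out["ok"] = ok;
  out["rebuilds"] = rebuilds;
  return out;
}

// ----------------------------------------------------------------------
// Contact energy mirror used by tests is in R; here we export the
// primitive traction/energy law so R can build the same pair energies.
// ----------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_traction(NumericVector d, double Epair, double h_int,
                           double k_rep) {
  NumericVector out(d.size());
  for (int i = 0; i < d.size(); ++i)
    out[i] = traction(d[i], Epair, h_int, k_rep);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_traction_energy(NumericVector d, double Epair, double h_int,
                                  double k_rep) {
  NumericVector out(d.size());
  for (int i = 0; i < d.size(); ++i)
    out[i] = u_of_d(d[i], Epair, h_int, k_rep);
  return out;
}

// Tracer diffusion/transfer with frozen mechanics (one tracer step of
// duration dtp per call iteration)
// [[Rcpp::export]]
List cpp_tracers_only(List state, List params, int nsteps, double dtp) {
  Sim z = read_sim(state);
  Pars p = read_pars(params);
  Neigh nb;
  nb.build(z, p);
  std::vector<double> fx(z.N), fy(z.N), bFx(z.M), bFy(z.M);
  std::vector<int> ncon(z.N);
  std::vector<double> ngap(z.N), egap(z.N, 1e9);
  if (z.N > 0) {
    eval_forces(z, p, nb, 8, fx, fy, bFx, bFy, ncon, ngap);
    for (int e = 0; e < z.N; ++e)
      egap[e] = std::min(ngap[e], ngap[z.nxt[e]]);
  }
  for (int s = 0; s < nsteps; ++s)
    tracer_step(z, p, nb, egap, dtp, p.counter * 100000ULL + (uint64_t)s);
  return sim_to_list(z);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  LogicalVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = pts(k, 0), y = pts(k, 1);
    bool in = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1);
      double xj = poly(j, 0), yj = poly(j, 1);
      if (((yi > y) != (yj > y)) && (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        in = !in;
    }
    out[k] = in;
  }
  return out;
}
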