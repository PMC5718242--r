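// Condensed-history Monte Carlo transport core.
//
// Geometry is a fixed parametric beamline (titanium exit window, PMMA
// collimator cylinders, water phantom box) plus an optional two-layer Al-Pb
// disc in arbitrary pose (depth, lateral shift, tilt about the z-diameter,
// 180-degree flip). All boundary distances are exact plane/cylinder
// intersections; extra fictitious boundaries (infinite extensions of the
// surfaces) only shorten steps and never let a step cross a material change.
//
// Units: lengths mm, energies MeV, stopping powers MeV/mm, attenuation 1/mm.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const int REG_OUTSIDE = -1;
static const int REG_AIR = 0, REG_TI = 1, REG_PMMA = 2, REG_WATER = 3,
                 REG_AL = 4, REG_PB = 5;

struct Mat {
  double rho, x0_mm, ecut, gcut, zeff, omega_coef, max_step_mm;
  double log_e0, dlog;
  std::vector<double> scol, srad, mu;
};

struct Cyl { double x0, x1, rin, rout; };

struct Geo {
  double win_x0, win_x1, win_r;
  std::vector<Cyl> cyls;
  double ph_depth, ph_half;
  double wx0, wx1, wy, wz;
  bool disc;
  double dc_cx, dc_cy;       // disc centre (x, y); z = 0
  double dc_h2, dc_first;    // half thickness, thickness of proximal layer
  int reg_first, reg_second; // REG_AL / REG_PB depending on flip
  double dc_r;
  double ct, st;             // cos/sin tilt
};

struct Settings {
  double frac_eloss, push, kcut_min;
  bool brems, straggle, scatter;
};

struct GridSpec {
  int nx, ny, nz;
  double vox, oy, oz; // origin offsets (x origin is 0)
};

static Mat parse_mat(const List& L) {
  Mat m;
  m.rho = as<double>(L["rho"]);
  m.x0_mm = as<double>(L["x0_mm"]);
  m.ecut = as<double>(L["ecut"]);
  m.gcut = as<double>(L["gcut"]);
  m.zeff = as<double>(L["zeff"]);
  m.omega_coef = as<double>(L["omega_coef"]);
  m.max_step_mm = as<double>(L["max_step_mm"]);
  m.log_e0 = as<double>(L["log_e0"]);
  m.dlog = as<double>(L["dlog"]);
  m.scol = as<std::vector<double> >(L["scol"]);
  m.srad = as<std::vector<double> >(L["srad"]);
  m.mu = as<std::vector<double> >(L["mu"]);
  return m;
}

static std::vector<Mat> parse_mats(const List& L) {
  std::vector<Mat> v;
  for (int i = 0; i < L.size(); ++i) v.push_back(parse_mat(L[i]));
  return v;
}

static Geo parse_geo(const List& L) {
  Geo g;
  g.win_x0 = as<double>(L["win_x0"]);
  g.win_x1 = as<double>(L["win_x1"]);
  g.win_r = as<double>(L["win_r"]);
  NumericMatrix cy = L["cylinders"];
  for (int i = 0; i < cy.nrow(); ++i) {
    Cyl c = {cy(i, 0), cy(i, 1), cy(i, 2), cy(i, 3)};
    g.cyls.push_back(c);
  }
  g.ph_depth = as<double>(L["phantom_depth"]);
  g.ph_half = as<double>(L["phantom_half"]);
  g.wx0 = as<double>(L["world_x0"]);
  g.wx1 = as<double>(L["world_x1"]);
  g.wy = as<double>(L["world_half_y"]);
  g.wz = as<double>(L["world_half_z"]);
  g.disc = as<bool>(L["disc_enabled"]);
  if (g.disc) {
    double depth = as<double>(L["disc_depth"]);
    double al = as<double>(L["disc_al"]), pb = as<double>(L["disc_pb"]);
    bool flipped = as<bool>(L["disc_flipped"]);
    double h = al + pb;
    g.dc_h2 = h / 2.0;
    g.dc_cx = depth + h / 2.0;
    g.dc_cy = as<double>(L["disc_shift"]);
    g.dc_first = flipped ? pb : al;
    g.reg_first = flipped ? REG_PB : REG_AL;
    g.reg_second = flipped ? REG_AL : REG_PB;
    g.dc_r = as<double>(L["disc_radius"]);
    double t = as<double>(L["disc_tilt_rad"]);
    g.ct = std::cos(t); g.st = std::sin(t);
  }
  return g;
}

static Settings parse_settings(const List& L) {
  Settings s;
  s.frac_eloss = as<double>(L["max_fractional_eloss"]);
  s.push = as<double>(L["push"]);
  s.kcut_min = as<double>(L["brems_kcut"]);
  s.brems = as<bool>(L["brems"]);
  s.straggle = as<bool>(L["straggling"]);
  s.scatter = as<bool>(L["scatter"]);
  return s;
}

static GridSpec parse_grid(const List& L) {
  GridSpec gr;
  gr.nx = as<int>(L["nx"]); gr.ny = as<int>(L["ny"]); gr.nz = as<int>(L["nz"]);
  gr.vox = as<double>(L["voxel"]);
  gr.oy = -0.5 * gr.ny * gr.vox;
  gr.oz = -0.5 * gr.nz * gr.vox;
  return gr;
}

static inline double lut(const std::vector<double>& v, const Mat& m, double E) {
  double x = (std::log(E) - m.log_e0) / m.dlog;
  int n = (int)v.size();
  if (x <= 0) return v.front();
  if (x >= n - 1) return v.back();
  int i = (int)x;
  double f = x - i;
  return v[i] * (1 - f) + v[i + 1] * f;
}

// ---------------------------------------------------------------- geometry

static int locate_pt(const Geo& g, double x, double y, double z) {
  if (x < g.wx0 || x > g.wx1 || std::fabs(y) > g.wy || std::fabs(z) > g.wz)
    return REG_OUTSIDE;
  if (x >= 0.0) {
    if (x <= g.ph_depth && std::fabs(y) <= g.ph_half && std::fabs(z) <= g.ph_half) {
      if (g.disc) {
        double px = x - g.dc_cx, py = y - g.dc_cy;
        double qx = g.ct * px + g.st * py;
        double qy = -g.st * px + g.ct * py;
        if (qx >= -g.dc_h2 && qx < g.dc_h2 && qy * qy + z * z <= g.dc_r * g.dc_r)
          return (qx < -g.dc_h2 + g.dc_first) ? g.reg_first : g.reg_second;
      }
      return REG_WATER;
    }
    return REG_AIR;
  }
  double r2 = y * y + z * z;
  if (x >= g.win_x0 && x < g.win_x1 && r2 <= g.win_r * g.win_r) return REG_TI;
  for (size_t i = 0; i < g.cyls.size(); ++i) {
    const Cyl& c = g.cyls[i];
    if (x >= c.x0 && x < c.x1 && r2 >= c.rin * c.rin && r2 < c.rout * c.rout)
      return REG_PMMA;
  }
  return REG_AIR;
}

static inline void plane_hit(double px, double dx, double X, double& best) {
  if (std::fabs(dx) > 1e-13) {
    double t = (X - px) / dx;
    if (t > 1e-9 && t < best) best = t;
  }
}

// cylinder about the (local) x-axis with radius R, bounded to the axial
// interval [x0, x1]; (y,z) are the transverse components, (ax, adx) the
// axial position/direction
static inline void cyl_hit(double y, double z, double dy, double dz, double R,
                           double ax, double adx, double x0, double x1,
                           double& best) {
  double a = dy * dy + dz * dz;
  if (a < 1e-16) return;
  double b = y * dy + z * dz;
  double c = y * y + z * z - R * R;
  double disc = b * b - a * c;
  if (disc < 0) return;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
  if (t1 > 1e-9 && t1 < best) {
    double xh = ax + adx * t1;
    if (xh >= x0 - 1e-9 && xh <= x1 + 1e-9) best = t1;
  }
  if (t2 > 1e-9 && t2 < best) {
    double xh = ax + adx * t2;
    if (xh >= x0 - 1e-9 && xh <= x1 + 1e-9) best = t2;
  }
}

// plane at axial coordinate X, bounded to transverse radius <= R
static inline void disk_plane_hit(double px, double dx, double X, double qy,
                                  double qz, double ey, double ez, double R,
                                  double& best) {
  if (std::fabs(dx) <= 1e-13) return;
  double t = (X - px) / dx;
  if (t <= 1e-9 || t >= best) return;
  double y = qy + ey * t, z = qz + ez * t;
  if (y * y + z * z <= R * R + 1e-9) best = t;
}

static double dist_to_boundary(const Geo& g, const double p[3], const double d[3]) {
  double best = 1e12;
  plane_hit(p[0], d[0], g.wx0, best);
  plane_hit(p[0], d[0], g.wx1, best);
  plane_hit(p[0], d[0], 0.0, best);
  plane_hit(p[0], d[0], g.win_x0, best);
  plane_hit(p[0], d[0], g.win_x1, best);
  plane_hit(p[1], d[1], g.wy, best);  plane_hit(p[1], d[1], -g.wy, best);
  plane_hit(p[2], d[2], g.wz, best);  plane_hit(p[2], d[2], -g.wz, best);
  plane_hit(p[1], d[1], g.ph_half, best); plane_hit(p[1], d[1], -g.ph_half, best);
  plane_hit(p[2], d[2], g.ph_half, best); plane_hit(p[2], d[2], -g.ph_half, best);
  cyl_hit(p[1], p[2], d[1], d[2], g.win_r, p[0], d[0], g.win_x0, g.win_x1, best);
  for (size_t i = 0; i < g.cyls.size(); ++i) {
    const Cyl& c = g.cyls[i];
    plane_hit(p[0], d[0], c.x0, best);
    plane_hit(p[0], d[0], c.x1, best);
    if (c.rin > 0)
      cyl_hit(p[1], p[2], d[1], d[2], c.rin, p[0], d[0], c.x0, c.x1, best);
    cyl_hit(p[1], p[2], d[1], d[2], c.rout, p[0], d[0], c.x0, c.x1, best);
  }
  if (g.disc) {
    // transform to disc-local frame (rotation about z through disc centre)
    double px = p[0] - g.dc_cx, py = p[1] - g.dc_cy, pz = p[2];
    double qx = g.ct * px + g.st * py, qy = -g.st * px + g.ct * py;
    double ex = g.ct * d[0] + g.st * d[1], ey = -g.st * d[0] + g.ct * d[1];
    disk_plane_hit(qx, ex, -g.dc_h2, qy, pz, ey, d[2], g.dc_r, best);
    disk_plane_hit(qx, ex, -g.dc_h2 + g.dc_first, qy, pz, ey, d[2], g.dc_r, best);
    disk_plane_hit(qx, ex, g.dc_h2, qy, pz, ey, d[2], g.dc_r, best);
    cyl_hit(qy, pz, ey, d[2], g.dc_r, qx, ex, -g.dc_h2, g.dc_h2, best);
  }
  return best;
}

// [[Rcpp::export]]
int cpp_locate(List geo, NumericVector point) {
  Geo g = parse_geo(geo);
  return locate_pt(g, point[0], point[1], point[2]);
}

// [[Rcpp::export]]
double cpp_distance_to_boundary(List geo, NumericVector point, NumericVector dir) {
  Geo g = parse_geo(geo);
  double p[3] = {point[0], point[1], point[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  if (locate_pt(g, p[0], p[1], p[2]) == REG_OUTSIDE)
    stop("point outside the world volume");
  return dist_to_boundary(g, p, d);
}

// ------------------------------------------------------------- transport

struct Pstate {
  double p[3], d[3], e;
};

struct Tally {
  std::vector<double>* cur;
  double outside, escaped, injected;
  double path_primary;
  const GridSpec* gr;
};

static inline void deposit(Tally& t, double x, double y, double z, double e) {
  const GridSpec& g = *t.gr;
  int ix = (int)std::floor(x / g.vox);
  int iy = (int)std::floor((y - g.oy) / g.vox);
  int iz = (int)std::floor((z - g.oz) / g.vox);
  if (ix >= 0 && ix < g.nx && iy >= 0 && iy < g.ny && iz >= 0 && iz < g.nz) {
    (*t.cur)[(size_t)ix + (size_t)g.nx * ((size_t)iy + (size_t)g.ny * iz)] += e;
  } else {
    t.outside += e;
  }
}

static inline void rotate_dir(double d[3], double theta, double phi) {
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  // orthonormal basis perpendicular to u
  double vx, vy, vz;
  if (std::fabs(uz) < 0.99) { vx = -uy; vy = ux; vz = 0.0; }
  else { vx = 0.0; vy = -uz; vz = uy; }
  double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
  vx /= nv; vy /= nv; vz /= nv;
  double wx = uy * vz - uz * vy, wy = uz * vx - ux * vz, wz = ux * vy - uy * vx;
  d[0] = ux * ct + st * (cp * vx + sp * wx);
  d[1] = uy * ct + st * (cp * vy + sp * wy);
  d[2] = uz * ct + st * (cp * vz + sp * wz);
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

// photon: single exponential flight with kerma-style local deposit
static void transport_photon(Pstate ph, const Geo& g, const std::vector<Mat>& M,
                             const Settings& S, Tally& T, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double tau = -std::log(std::max(U(rng), 1e-300));
  for (int guard = 0; guard < 100000; ++guard) {
    int reg = locate_pt(g, ph.p[0], ph.p[1], ph.p[2]);
    if (reg == REG_OUTSIDE) { T.escaped += ph.e; return; }
    const Mat& m = M[reg];
    if (ph.e <= m.gcut) {
      deposit(T, ph.p[0], ph.p[1], ph.p[2], ph.e);
      return;
    }
    double mu = lut(m.mu, m, ph.e);
    double db = dist_to_boundary(g, ph.p, ph.d);
    double need = (mu > 1e-14) ? tau / mu : 1e12;
    if (need <= db) {
      for (int k = 0; k < 3; ++k) ph.p[k] += ph.d[k] * need;
      deposit(T, ph.p[0], ph.p[1], ph.p[2], ph.e);
      return;
    }
    tau -= mu * db;
    for (int k = 0; k < 3; ++k) ph.p[k] += ph.d[k] * (db + S.push);
  }
  T.escaped += ph.e; // pathological guard; energy stays accounted
}

// One condensed-history electron step. Returns true while alive.
// Any emitted bremsstrahlung photon is appended to `photons`.
static bool electron_step(Pstate& st, const Geo& g, const std::vector<Mat>& M,
                          const Settings& S, Tally& T, std::mt19937_64& rng,
                          std::vector<Pstate>& photons, bool is_primary) {
  int reg = locate_pt(g, st.p[0], st.p[1], st.p[2]);
  if (reg == REG_OUTSIDE) { T.escaped += st.e; return false; }
  const Mat& m = M[reg];
  if (st.e <= m.ecut) {
    deposit(T, st.p[0], st.p[1], st.p[2], st.e);
    return false;
  }
  double scol = lut(m.scol, m, st.e);
  double srad = lut(m.srad, m, st.e);
  double stot = scol + srad;
  double s_el = S.frac_eloss * st.e / stot;
  double db = dist_to_boundary(g, st.p, st.d);
  double s = std::min(std::min(m.max_step_mm, s_el), db);
  if (is_primary) T.path_primary += s;

  double kcut = std::max(m.gcut, S.kcut_min);
  double de = scol * s;
  double de_r = srad * s;
  double k_emit = 0.0;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  if (S.brems && st.e > kcut * 1.0000001) {
    de += de_r * (kcut / st.e); // sub-cutoff radiative loss, local
    double lam = (srad / st.e) * std::log(st.e / kcut);
    if (U(rng) < lam * s) {
      double k = kcut * std::pow(st.e / kcut, U(rng)); // 1/k spectrum
      if (k < st.e - m.ecut) k_emit = k;
    }
  } else {
    de += de_r;
  }
  if (S.straggle && de > 0) {
    double omega = m.omega_coef * std::sqrt(s / 10.0); // s in cm for Bohr
    double shape = (de / omega) * (de / omega);
    std::gamma_distribution<double> G(shape, omega * omega / de);
    de = G(rng);
  }

  double mid[3];
  for (int k = 0; k < 3; ++k) mid[k] = st.p[k] + st.d[k] * (s * 0.5);
  if (de + k_emit >= st.e - m.ecut) {
    // range out within the step: everything (minus any photon) deposits here
    deposit(T, mid[0], mid[1], mid[2], st.e - k_emit);
  } else {
    deposit(T, mid[0], mid[1], mid[2], de);
  }
  double e_after = st.e - de - k_emit;

  for (int k = 0; k < 3; ++k) st.p[k] += st.d[k] * (s + S.push);
  if (k_emit > 0) {
    Pstate ph;
    for (int k = 0; k < 3; ++k) { ph.p[k] = st.p[k]; ph.d[k] = st.d[k]; }
    ph.e = k_emit;
    photons.push_back(ph);
  }
  if (de + k_emit >= st.e - m.ecut) return false;
  st.e = e_after;

  if (S.scatter) {
    double theta0 = 0.0;
    double tx0 = s / m.x0_mm;
    if (tx0 > 0) {
      double mc2 = 0.51099895;
      double pc = std::sqrt(st.e * (st.e + 2 * mc2));
      double beta = pc / (st.e + mc2);
      theta0 = 13.6 / (beta * pc) * std::sqrt(tx0) * (1 + 0.038 * std::log(tx0));
      if (theta0 < 0) theta0 = 0;
      if (theta0 > 1.4) theta0 = 1.4;
    }
    if (theta0 > 0) {
      std::normal_distribution<double> N(0.0, theta0);
      rotate_dir(st.d, N(rng), 2.0 * M_PI * U(rng));
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_run_engine(NumericMatrix primaries, IntegerVector batch, List geo,
                    List mats, List settings, List grid, double seed) {
  Geo g = parse_geo(geo);
  std::vector<Mat> M = parse_mats(mats);
  Settings S = parse_settings(settings);
  GridSpec GR = parse_grid(grid);
  size_t nvox = (size_t)GR.nx * GR.ny * GR.nz;
  std::vector<double> total(nvox, 0.0), cur(nvox, 0.0), sumsq(nvox, 0.0);

  Tally T;
  T.cur = &cur; T.outside = 0; T.escaped = 0; T.injected = 0;
  T.path_primary = 0; T.gr = &GR;

  int n = primaries.nrow();
  int nbatch = 0;
  int cur_batch = n > 0 ? batch[0] : 0;
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + (uint64_t)cur_batch);

  std::vector<Pstate> photons;
  for (int i = 0; i < n; ++i) {
    if (batch[i] != cur_batch) {
      for (size_t v = 0; v < nvox; ++v) {
        total[v] += cur[v];
        sumsq[v] += cur[v] * cur[v];
        cur[v] = 0.0;
      }
      ++nbatch;
      cur_batch = batch[i];
      rng.seed((uint64_t)seed * 2654435761u + (uint64_t)cur_batch);
    }
    Pstate st;
    st.e = primaries(i, 0);
    for (int k = 0; k < 3; ++k) {
      st.p[k] = primaries(i, 1 + k);
      st.d[k] = primaries(i, 4 + k);
    }
    if (!R_finite(st.e) || st.e < 0) stop("invalid primary energy at history %d", i + 1);
    T.injected += st.e;
    photons.clear();
    int guard = 0;
    while (electron_step(st, g, M, S, T, rng, photons, true)) {
      if (++guard > 2000000) stop("electron step guard tripped at history %d", i + 1);
    }
    for (size_t q = 0; q < photons.size(); ++q)
      transport_photon(photons[q], g, M, S, T, rng);
    if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  for (size_t v = 0; v < nvox; ++v) {
    total[v] += cur[v];
    sumsq[v] += cur[v] * cur[v];
  }
  ++nbatch;

  double dep = T.outside;
  for (size_t v = 0; v < nvox; ++v) dep += total[v];

  NumericVector energy(total.begin(), total.end());
  NumericVector ssq(sumsq.begin(), sumsq.end());
  return List::create(
      _["energy"] = energy, _["batch_sumsq"] = ssq, _["n_batches"] = nbatch,
      _["outside"] = T.outside, _["escaped"] = T.escaped,
      _["injected"] = T.injected, _["deposited"] = dep,
      _["primary_path_mm"] = T.path_primary, _["n_histories"] = n);
}

// Single-step / single-flight wrappers (used by the R-level step API).

// [[Rcpp::export]]
List cpp_step_electron(NumericVector state, List geo, List mats, List settings,
                       List grid, double seed) {
  Geo g = parse_geo(geo);
  std::vector<Mat> M = parse_mats(mats);
  Settings S = parse_settings(settings);
  GridSpec GR = parse_grid(grid);
  std::vector<double> cur((size_t)GR.nx * GR.ny * GR.nz, 0.0);
  Tally T; T.cur = &cur; T.outside = 0; T.escaped = 0; T.injected = 0;
  T.path_primary = 0; T.gr = &GR;
  std::mt19937_64 rng((uint64_t)seed);
  Pstate st;
  st.e = state[0];
  for (int k = 0; k < 3; ++k) { st.p[k] = state[1 + k]; st.d[k] = state[4 + k]; }
  std::vector<Pstate> photons;
  bool alive = electron_step(st, g, M, S, T, rng, photons, true);
  double dep = T.outside;
  for (size_t v = 0; v < cur.size(); ++v) dep += cur[v];
  List ph = R_NilValue;
  if (!photons.empty()) {
    ph = List::create(
        _["energy"] = photons[0].e,
        _["position"] = NumericVector::create(photons[0].p[0], photons[0].p[1], photons[0].p[2]),
        _["direction"] = NumericVector::create(photons[0].d[0], photons[0].d[1], photons[0].d[2]));
  }
  return List::create(
      _["alive"] = alive,
      _["energy"] = st.e,
      _["position"] = NumericVector::create(st.p[0], st.p[1], st.p[2]),
      _["direction"] = NumericVector::create(st.d[0], st.d[1], st.d[2]),
      _["deposited"] = dep, _["escaped"] = T.escaped,
      _["step_mm"] = T.path_primary, _["photon"] = ph);
}

// [[Rcpp::export]]
List cpp_step_photon(NumericVector state, List geo, List mats, List settings,
                     List grid, double seed) {
  Geo g = parse_geo(geo);
  std::vector<Mat> M = parse_mats(mats);
  Settings S = parse_settings(settings);
  GridSpec GR = parse_grid(grid);
  std::vector<double> cur((size_t)GR.nx * GR.ny * GR.nz, 0.0);
  Tally T; T.cur = &cur; T.outside = 0; T.escaped = 0; T.injected = 0;
  T.path_primary = 0; T.gr = &GR;
  std::mt19937_64 rng((uint64_t)seed);
  Pstate ph;
  ph.e = state[0];
  for (int k = 0; k < 3; ++k) { ph.p[k] = state[1 + k]; ph.d[k] = state[4 + k]; }
  transport_photon(ph, g, M, S, T, rng);
  size_t imax = 0; double vmax = -1.0; double dep_grid = 0.0;
  for (size_t v = 0; v < cur.size(); ++v) {
    dep_grid += cur[v];
    if (cur[v] > vmax) { vmax = cur[v]; imax = v; }
  }
  int ix = (int)(imax % GR.nx);
  int iy = (int)((imax / GR.nx) % GR.ny);
  int iz = (int)(imax / ((size_t)GR.nx * GR.ny));
  NumericVector at = NumericVector::create(
      (ix + 0.5) * GR.vox, GR.oy + (iy + 0.5) * GR.vox, GR.oz + (iz + 0.5) * GR.vox);
  return List::create(
      _["deposited_grid"] = dep_grid, _["deposited_outside"] = T.outside,
      _["escaped"] = T.escaped, _["deposit_voxel_center"] = at);
}

// Density at each voxel centre (for dose conversion), from the geometry.
// [[Rcpp::export]]
NumericVector cpp_density_map(List geo, List grid, NumericVector rho_by_region) {
  Geo g = parse_geo(geo);
  GridSpec GR = parse_grid(grid);
  size_t nvox = (size_t)GR.nx * GR.ny * GR.nz;
  NumericVector out(nvox);
  size_t idx = 0;
  for (int iz = 0; iz < GR.nz; ++iz) {
    double z = GR.oz + (iz + 0.5) * GR.vox;
    for (int iy = 0; iy < GR.ny; ++iy) {
      double y = GR.oy + (iy + 0.5) * GR.vox;
      for (int ix = 0; ix < GR.nx; ++ix) {
        double x = (ix + 0.5) * GR.vox;
        int reg = locate_pt(g, x, y, z);
        out[idx++] = (reg >= 0) ? rho_by_region[reg] : NA_REAL;
      }
    }
  }
  return out;
}
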