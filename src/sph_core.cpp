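// Compiled core: kernel, neighbor search, WCSPH density/forces, mass-spring
// and hinge forces, no-penetration repulsion, time integrator with solid
// sub-stepping, bond fragmentation, and grid field reconstruction.
//
// Conventions: 2D, x optionally periodic (minimum image), y bounded.
// Particle kinds: 0 = FLUID, 1 = WALL, 2 = MEMBRANE, 3 = AGGREGATE.
// All indices crossing the R boundary are 1-based; internal indices 0-based.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <cstdint>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace Rcpp;

// Subnormal velocities/forces arise from round-off-scale residuals in
// near-equilibrium states and cost 50-100x in microcoded arithmetic while
// carrying no physics; flush them to zero inside the solver.
static inline void flush_denormals() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

static const double SIG2D = 10.0 / (7.0 * M_PI); // 2D cubic-spline norm / h^2

// Cubic spline, support radius 2h.
static inline double w_cubic(double r, double h) {
  double q = r / h;
  if (q >= 2.0) return 0.0;
  double s = SIG2D / (h * h);
  if (q < 1.0) return s * (1.0 - 1.5 * q * q + 0.75 * q * q * q);
  double t = 2.0 - q;
  return s * 0.25 * t * t * t;
}

// dW/dr (radial derivative).
static inline double dw_cubic(double r, double h) {
  double q = r / h;
  if (q >= 2.0) return 0.0;
  double s = SIG2D / (h * h * h);
  if (q < 1.0) return s * (-3.0 * q + 2.25 * q * q);
  double t = 2.0 - q;
  return -s * 0.75 * t * t;
}

// [[Rcpp::export]]
List cpp_kernel(NumericVector r, double h) {
  int n = r.size();
  NumericVector W(n), dW(n);
  for (int i = 0; i < n; ++i) {
    W[i] = w_cubic(r[i], h);
    dW[i] = dw_cubic(r[i], h);
  }
  return List::create(_["W"] = W, _["dWdr"] = dW);
}

// ---------------------------------------------------------------------------
// Neighbor pairs (half list, i < j), periodic minimum image in x only.

struct Pairs {
  std::vector<int> i, j;
  std::vector<double> dx, dy, r;
  void push(int a, int b, double ddx, double ddy, double rr) {
    i.push_back(a); j.push_back(b); dx.push_back(ddx); dy.push_back(ddy); r.push_back(rr);
  }
};

static inline double min_image(double dx, double Lx, bool periodic) {
  if (periodic) dx -= Lx * std::nearbyint(dx / Lx);
  return dx;
}

static void build_pairs(const double* x, const double* y, int n, double support,
                        double xlo, double xhi, bool periodic, Pairs& out) {
  double Lx = xhi - xlo;
  double sup2 = support * support;
  // brute force for small systems or when cells would be too coarse
  int ncx = periodic ? (int)std::floor(Lx / support) : 1000000;
  if (n < 300 || (periodic && ncx < 3)) {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double ddx = min_image(x[a] - x[b], Lx, periodic);
        double ddy = y[a] - y[b];
        double r2 = ddx * ddx + ddy * ddy;
        if (r2 < sup2) out.push(a, b, ddx, ddy, std::sqrt(r2));
      }
    return;
  }
  // cell list
  double ylo = y[0], yhi = y[0];
  double pxlo = x[0], pxhi = x[0];
  for (int a = 1; a < n; ++a) {
    if (y[a] < ylo) ylo = y[a];
    if (y[a] > yhi) yhi = y[a];
    if (x[a] < pxlo) pxlo = x[a];
    if (x[a] > pxhi) pxhi = x[a];
  }
  double cx0 = periodic ? xlo : pxlo;
  double cLx = periodic ? Lx : (pxhi - pxlo + 1e-12);
  if (!periodic) ncx = std::max(1, (int)std::floor(cLx / support));
  double csx = cLx / ncx;
  int ncy = std::max(1, (int)std::floor((yhi - ylo + 1e-12) / support));
  double csy = (yhi - ylo + 1e-12) / ncy;
  std::vector<int> head(ncx * ncy, -1), nxt(n, -1), cellof(n);
  for (int a = 0; a < n; ++a) {
    int ix = (int)std::floor((x[a] - cx0) / csx);
    if (ix < 0) ix = 0; if (ix >= ncx) ix = ncx - 1;
    int iy = (int)std::floor((y[a] - ylo) / csy);
    if (iy < 0) iy = 0; if (iy >= ncy) iy = ncy - 1;
    int c = iy * ncx + ix;
    cellof[a] = c;
    nxt[a] = head[c];
    head[c] = a;
  }
  // half stencil: same cell (a<b) + 4 forward neighbor cells
  const int stx[4] = {1, 1, 0, -1};
  const int sty[4] = {0, 1, 1, 1};
  for (int iy = 0; iy < ncy; ++iy) {
    for (int ix = 0; ix < ncx; ++ix) {
      int c = iy * ncx + ix;
      for (int a = head[c]; a != -1; a = nxt[a]) {
        for (int b = nxt[a]; b != -1; b = nxt[b]) {
          double ddx = min_image(x[a] - x[b], Lx, periodic);
          double ddy = y[a] - y[b];
          double r2 = ddx * ddx + ddy * ddy;
          if (r2 < sup2) {
            if (a < b) out.push(a, b, ddx, ddy, std::sqrt(r2));
            else out.push(b, a, -ddx, -ddy, std::sqrt(r2));
          }
        }
        for (int s = 0; s < 4; ++s) {
          int jx = ix + stx[s], jy = iy + sty[s];
          if (jy < 0 || jy >= ncy) continue;
          if (periodic) { if (jx < 0) jx += ncx; if (jx >= ncx) jx -= ncx; }
          else if (jx < 0 || jx >= ncx) continue;
          int c2 = jy * ncx + jx;
          if (c2 == c) continue;
          for (int a2 = head[c2]; a2 != -1; a2 = nxt[a2]) {
            double ddx = min_image(x[a] - x[a2], Lx, periodic);
            double ddy = y[a] - y[a2];
            double r2 = ddx * ddx + ddy * ddy;
            if (r2 < sup2) {
              if (a < a2) out.push(a, a2, ddx, ddy, std::sqrt(r2));
              else out.push(a2, a, -ddx, -ddy, std::sqrt(r2));
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_pairs(NumericVector x, NumericVector y, double support,
               double xlo, double xhi, bool periodic) {
  int n = x.size();
  Pairs p;
  build_pairs(REAL(x), REAL(y), n, support, xlo, xhi, periodic, p);
  int m = p.i.size();
  IntegerVector I(m), J(m);
  NumericVector DX(m), DY(m), R(m);
  for (int k = 0; k < m; ++k) {
    I[k] = p.i[k] + 1; J[k] = p.j[k] + 1;
    DX[k] = p.dx[k]; DY[k] = p.dy[k]; R[k] = p.r[k];
  }
  return List::create(_["i"] = I, _["j"] = J, _["dx"] = DX, _["dy"] = DY, _["r"] = R);
}

// [[Rcpp::export]]
NumericVector cpp_density(IntegerVector pi, IntegerVector pj, NumericVector pr,
                          NumericVector mass, double h, int n) {
  NumericVector rho(n);
  double w0 = w_cubic(0.0, h);
  for (int a = 0; a < n; ++a) rho[a] = mass[a] * w0; // self term
  int m = pi.size();
  for (int k = 0; k < m; ++k) {
    int a = pi[k] - 1, b = pj[k] - 1;
    double w = w_cubic(pr[k], h);
    rho[a] += mass[b] * w;
    rho[b] += mass[a] * w;
  }
  return rho;
}

// ---------------------------------------------------------------------------
// Force evaluation

struct ForceDiag {
  double sum_abs = 0.0;   // sum of |pairwise contributions| (denominator)
  double net_x = 0.0, net_y = 0.0;
};

static inline uint64_t pair_key(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (uint64_t)lo * (uint64_t)n + (uint64_t)hi;
}

// Pressure (symmetric) + Morris laminar viscosity on pairs with >= 1 fluid.
static void accum_pv(const Pairs& P, const int* kind,
                     const double* vx, const double* vy,
                     const double* mass, const double* rho, const double* p,
                     double mu, double h,
                     double* fx, double* fy, ForceDiag& dg) {
  int m = P.i.size();
  double eps = 0.01 * h * h;
  for (int k = 0; k < m; ++k) {
    int a = P.i[k], b = P.j[k];
    if (kind[a] != 0 && kind[b] != 0) continue;
    double r = P.r[k];
    if (r <= 0.0) stop("coincident particles in pressure/viscous evaluation");
    double dwdr = dw_cubic(r, h);
    if (dwdr == 0.0) continue;
    double ex = P.dx[k] / r, ey = P.dy[k] / r;
    if (rho[a] <= 0.0 || rho[b] <= 0.0) stop("zero density in force evaluation");
    // pressure
    double cp = -mass[a] * mass[b] * (p[a] / (rho[a] * rho[a]) + p[b] / (rho[b] * rho[b])) * dwdr;
    double fpx = cp * ex, fpy = cp * ey;
    // Morris viscosity, dynamic viscosity mu for both phases
    double rdw = r * dwdr;
    double cv = mass[a] * mass[b] * (2.0 * mu) * rdw / (rho[a] * rho[b] * (r * r + eps));
    double dvx = vx[a] - vx[b], dvy = vy[a] - vy[b];
    double fvx = cv * dvx, fvy = cv * dvy;
    double gx = fpx + fvx, gy = fpy + fvy;
    fx[a] += gx; fy[a] += gy;
    fx[b] -= gx; fy[b] -= gy;
    dg.sum_abs += 2.0 * (std::fabs(gx) + std::fabs(gy));
  }
}

// Short-range no-penetration repulsion (Monaghan-type power law, cut at rc),
// fluid<->solid always; solid<->solid (non-bonded) optional.
static void accum_repulsion(const Pairs& P, const int* kind,
                            double rc, double strength, bool solid_solid,
                            const std::unordered_set<uint64_t>* bonded, int n,
                            double* fx, double* fy, ForceDiag& dg) {
  if (strength <= 0.0 || rc <= 0.0) return;
  int m = P.i.size();
  double rmin = 0.3 * rc; // force capped below rmin for stability
  for (int k = 0; k < m; ++k) {
    double r = P.r[k];
    if (r >= rc) continue;
    int a = P.i[k], b = P.j[k];
    bool afl = kind[a] == 0, bfl = kind[b] == 0;
    bool fs = (afl != bfl);
    bool ss = (!afl && !bfl);
    bool ff = (afl && bfl);
    if (!fs && !ff && !(ss && solid_solid)) continue;
    if (ss && bonded && bonded->count(pair_key(a, b, n))) continue;
    // fluid-fluid pairs: gentle anti-clumping guard against the tensile
    // pairing instability, active only well below the equilibrium spacing
    double rcp = ff ? 0.5 * rc : rc;
    double sp = ff ? 0.2 * strength : strength;
    if (r >= rcp) continue;
    double rmn = ff ? 0.3 * rcp : rmin;
    double re = r < rmn ? rmn : r;
    double q = rcp / re;
    double q2 = q * q;
    double f = sp * (q2 * q2 - q2);
    if (f <= 0.0) continue;
    double ex = P.dx[k] / (r > 0 ? r : rmin), ey = P.dy[k] / (r > 0 ? r : rmin);
    fx[a] += f * ex; fy[a] += f * ey;
    fx[b] -= f * ex; fy[b] -= f * ey;
    dg.sum_abs += 2.0 * (std::fabs(f * ex) + std::fabs(f * ey));
  }
}

// Harmonic springs; returns tensions (k*(r-rest), >0 stretched).
static void accum_springs(const double* x, const double* y,
                          const int* bi, const int* bj, const double* bk,
                          const double* brest, const int* bactive, int nb,
                          double Lx, bool periodic,
                          double* fx, double* fy, double* tension, ForceDiag& dg) {
  for (int k = 0; k < nb; ++k) {
    if (!bactive[k]) { if (tension) tension[k] = 0.0; continue; }
    int a = bi[k], b = bj[k];
    double ddx = min_image(x[a] - x[b], Lx, periodic);
    double ddy = y[a] - y[b];
    double r = std::sqrt(ddx * ddx + ddy * ddy);
    if (r < 1e-14) stop("coincident bonded particles");
    double t = bk[k] * (r - brest[k]);
    if (tension) tension[k] = t;
    double f = -t / r; // along (a-b): stretched pulls a toward b
    double gx = f * ddx, gy = f * ddy;
    fx[a] += gx; fy[a] += gy;
    fx[b] -= gx; fy[b] -= gy;
    dg.sum_abs += 2.0 * (std::fabs(gx) + std::fabs(gy));
  }
}

// Harmonic hinges U = 0.5*ka*(theta - theta0)^2, analytic gradient.
static void accum_hinges(const double* x, const double* y,
                         const int* hi, const int* hj, const int* hk,
                         const double* ka, const double* rest, int nh,
                         double Lx, bool periodic,
                         double* fx, double* fy, ForceDiag& dg) {
  for (int t = 0; t < nh; ++t) {
    int a = hi[t], j = hj[t], c = hk[t]; // j is the vertex
    double ax = min_image(x[a] - x[j], Lx, periodic), ay = y[a] - y[j];
    double bx = min_image(x[c] - x[j], Lx, periodic), by = y[c] - y[j];
    double la = std::sqrt(ax * ax + ay * ay), lb = std::sqrt(bx * bx + by * by);
    if (la < 1e-14 || lb < 1e-14) stop("degenerate hinge arm");
    double dot = ax * bx + ay * by;
    double crs = ax * by - ay * bx;
    double theta = std::atan2(std::fabs(crs), dot); // in [0, pi]
    double s = std::fabs(crs) / (la * lb);          // sin(theta)
    double dth = theta - rest[t];
    if (s < 1e-14) {
      if (std::fabs(dth) < 1e-12) continue; // straight at rest: zero force
      stop("collinear hinge with undefined angle derivative");
    }
    double cth = dot / (la * lb);
    // unsigned angle: dtheta/dr_i = -(1/s) dcos/dr_i, s = |cross|/(la*lb),
    // so F_i = -ka*dth*dtheta/dr_i = (ka*dth/s) * dcos/dr_i
    double fac = ka[t] * dth / s;
    double Fax = fac * (bx / (la * lb) - cth * ax / (la * la));
    double Fay = fac * (by / (la * lb) - cth * ay / (la * la));
    double Fcx = fac * (ax / (la * lb) - cth * bx / (lb * lb));
    double Fcy = fac * (ay / (la * lb) - cth * by / (lb * lb));
    fx[a] += Fax; fy[a] += Fay;
    fx[c] += Fcx; fy[c] += Fcy;
    fx[j] -= (Fax + Fcx); fy[j] -= (Fay + Fcy);
    dg.sum_abs += std::fabs(Fax) + std::fabs(Fay) + std::fabs(Fcx) + std::fabs(Fcy)
                + std::fabs(Fax + Fcx) + std::fabs(Fay + Fcy);
  }
}

// Tait equation of state.
static inline double tait(double rho, double rho0, double c0, double gamma) {
  return c0 * c0 * rho0 / gamma * (std::pow(rho / rho0, gamma) - 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_eos(NumericVector rho, double rho0, double c0, double gamma) {
  int n = rho.size();
  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = tait(rho[i], rho0, c0, gamma);
  return p;
}

// One-shot force evaluation for the R-level operations and tests.
// flags: pv (pressure+viscous), rep, springs, hinges.
// [[Rcpp::export]]
List cpp_forces(IntegerVector kind, NumericVector x, NumericVector y,
                NumericVector vx, NumericVector vy, NumericVector mass,
                NumericVector rho, NumericVector p,
                double h, double mu,
                double xlo, double xhi, bool periodic,
                double rc, double rep_strength, bool rep_solid,
                IntegerVector bi, IntegerVector bj, NumericVector bk,
                NumericVector brest, IntegerVector bactive,
                IntegerVector hi, IntegerVector hj, IntegerVector hk,
                NumericVector hka, NumericVector hrest,
                bool do_pv, bool do_rep, bool do_springs, bool do_hinges) {
  int n = x.size();
  NumericVector fx(n), fy(n);
  ForceDiag dg;
  double Lx = xhi - xlo;
  Pairs P;
  if (do_pv || do_rep) {
    double support = 2.0 * h;
    if (do_rep && rc > support) support = rc;
    build_pairs(REAL(x), REAL(y), n, support, xlo, xhi, periodic, P);
  }
  int nb = bi.size(), nh = hi.size();
  std::vector<int> b0i(nb), b0j(nb), bact(nb);
  for (int k = 0; k < nb; ++k) { b0i[k] = bi[k] - 1; b0j[k] = bj[k] - 1; bact[k] = bactive[k]; }
  std::vector<int> h0i(nh), h0j(nh), h0k(nh);
  for (int k = 0; k < nh; ++k) { h0i[k] = hi[k] - 1; h0j[k] = hj[k] - 1; h0k[k] = hk[k] - 1; }
  std::unordered_set<uint64_t> bonded;
  for (int k = 0; k < nb; ++k) if (bact[k]) bonded.insert(pair_key(b0i[k], b0j[k], n));
  if (do_pv)
    accum_pv(P, INTEGER(kind), REAL(vx), REAL(vy), REAL(mass), REAL(rho), REAL(p),
             mu, h, REAL(fx), REAL(fy), dg);
  if (do_rep)
    accum_repulsion(P, INTEGER(kind), rc, rep_strength, rep_solid, &bonded, n,
                    REAL(fx), REAL(fy), dg);
  NumericVector tension(nb);
  if (do_springs)
    accum_springs(REAL(x), REAL(y), b0i.data(), b0j.data(), REAL(bk), REAL(brest),
                  bact.data(), nb, Lx, periodic, REAL(fx), REAL(fy), REAL(tension), dg);
  if (do_hinges)
    accum_hinges(REAL(x), REAL(y), h0i.data(), h0j.data(), h0k.data(),
                 REAL(hka), REAL(hrest), nh, Lx, periodic, REAL(fx), REAL(fy), dg);
  double nx = 0, ny = 0;
  for (int a = 0; a < n; ++a) { nx += fx[a]; ny += fy[a]; }
  double imb = std::sqrt(nx * nx + ny * ny) / std::max(dg.sum_abs, 1e-300);
  return List::create(_["fx"] = fx, _["fy"] = fy,
                      _["tension"] = tension, _["imbalance"] = imb);
}

// ---------------------------------------------------------------------------
// Time integration: kick-drift-kick on SPH/repulsion/body forces with an
// inner sub-stepped loop (RESPA-style) for the stiff spring/hinge forces.

// [[Rcpp::export]]
List cpp_advance(List state, List par) {
  flush_denormals();
  IntegerVector kind = clone(as<IntegerVector>(state["kind"]));
  NumericVector x = clone(as<NumericVector>(state["x"]));
  NumericVector y = clone(as<NumericVector>(state["y"]));
  NumericVector vx = clone(as<NumericVector>(state["vx"]));
  NumericVector vy = clone(as<NumericVector>(state["vy"]));
  NumericVector mass = clone(as<NumericVector>(state["mass"]));
  IntegerVector anchored = clone(as<IntegerVector>(state["anchored"]));
  IntegerVector bi = as<IntegerVector>(state["bond_i"]);
  IntegerVector bj = as<IntegerVector>(state["bond_j"]);
  NumericVector bk = as<NumericVector>(state["bond_k"]);
  NumericVector brest = as<NumericVector>(state["bond_rest"]);
  NumericVector bthr = as<NumericVector>(state["bond_thr"]);
  IntegerVector bactive = clone(as<IntegerVector>(state["bond_active"]));
  NumericVector ext_fx = as<NumericVector>(state["ext_fx"]);
  NumericVector ext_fy = as<NumericVector>(state["ext_fy"]);
  IntegerVector hi = as<IntegerVector>(state["hinge_i"]);
  IntegerVector hj = as<IntegerVector>(state["hinge_j"]);
  IntegerVector hk = as<IntegerVector>(state["hinge_k"]);
  NumericVector hka = as<NumericVector>(state["hinge_ka"]);
  NumericVector hrest = as<NumericVector>(state["hinge_rest"]);

  const int n = x.size();
  const double h = par["h"];
  const double rho0 = par["rho0"], mu = par["mu"], c0 = par["c0"], gamma = par["gamma"];
  const double g0 = par["g0"], freq = par["freq"];
  const int waveform = par["waveform"]; // 0 constant, 1 sinusoidal
  const double gdx = par["gdir_x"], gdy = par["gdir_y"];
  const double rc = par["rc"], rep_strength = par["rep_strength"];
  const bool rep_solid = par["rep_solid"];
  const double damping = par["damping"];
  const double dt = par["dt"];
  const int nsteps = par["nsteps"];
  const double t0 = par["t0"];
  const double xlo = par["xlo"], xhi = par["xhi"];
  const bool periodic = par["periodic"];
  const bool break_check = par["break_check"];
  IntegerVector probe = par["probe"]; // 1-based fluid probes (may be empty)
  int nsub = par["nsub"];             // 0 = auto

  const double Lx = xhi - xlo;
  const double support = std::max(2.0 * h, rc);
  const int nb = bi.size(), nh = hi.size();

  std::vector<int> b0i(nb), b0j(nb);
  for (int k = 0; k < nb; ++k) { b0i[k] = bi[k] - 1; b0j[k] = bj[k] - 1; }
  std::vector<int> h0i(nh), h0j(nh), h0k(nh);
  for (int k = 0; k < nh; ++k) { h0i[k] = hi[k] - 1; h0j[k] = hj[k] - 1; h0k[k] = hk[k] - 1; }

  // auto sub-step count from stiffest spring / hinge and lightest solid mass
  bool has_fast = (nb > 0 || nh > 0);
  if (nsub <= 0) {
    if (!has_fast) nsub = 1;
    else {
      double kmax = 0.0, mmin = R_PosInf, rmin = R_PosInf;
      for (int k = 0; k < nb; ++k) if (bactive[k] && bk[k] > kmax) kmax = bk[k];
      double kamax = 0.0;
      for (int k = 0; k < nh; ++k) if (hka[k] > kamax) kamax = hka[k];
      for (int k = 0; k < nb; ++k) if (bactive[k] && brest[k] < rmin) rmin = brest[k];
      if (!R_FINITE(rmin) || rmin <= 0) rmin = h;
      double keff = kmax + 12.0 * kamax / (rmin * rmin);
      for (int a = 0; a < n; ++a)
        if (kind[a] >= 2 && mass[a] < mmin) mmin = mass[a];
      if (!R_FINITE(mmin)) mmin = 1.0;
      if (keff > 0) {
        double dtf = 0.25 * std::sqrt(mmin / (2.0 * keff));
        nsub = (int)std::ceil(dt / dtf);
      } else nsub = 1;
      if (nsub < 1) nsub = 1;
      if (nsub > 200000) stop("spring stiffness requires > 2e5 sub-steps per step");
    }
  }
  const double dtn = dt / nsub;

  // particles carrying fast (spring/hinge) forces: only these are
  // sub-stepped; everything else drifts once per outer step
  std::vector<int> fast_ids;
  {
    std::vector<char> isfast(n, 0);
    for (int k = 0; k < nb; ++k) { isfast[b0i[k]] = 1; isfast[b0j[k]] = 1; }
    for (int k = 0; k < nh; ++k) { isfast[h0i[k]] = 1; isfast[h0j[k]] = 1; isfast[h0k[k]] = 1; }
    for (int a = 0; a < n; ++a)
      if (isfast[a] && !anchored[a]) fast_ids.push_back(a);
  }
  std::vector<char> fast_mark(n, 0);
  for (size_t q = 0; q < fast_ids.size(); ++q) fast_mark[fast_ids[q]] = 1;

  std::vector<double> fsx(n), fsy(n), ffx(n), ffy(n), rho(n), prs(n), tension(nb);
  std::unordered_set<uint64_t> bonded;
  for (int k = 0; k < nb; ++k) if (bactive[k]) bonded.insert(pair_key(b0i[k], b0j[k], n));

  double max_imb = 0.0, max_drho = 0.0, max_speed_run = 0.0;
  double prof_slow = 0.0, prof_fast = 0.0; long prof_pairs = 0;
  NumericVector tr_time(nsteps), tr_maxspeed(nsteps), tr_probe(nsteps),
    tr_probe_max(nsteps), tr_drho(nsteps);
  std::vector<int> ev_step; std::vector<double> ev_time; std::vector<int> ev_bond, ev_i, ev_j;
  std::vector<double> ev_tension;

  double t = t0;

  // slow forces at current positions/velocities/time
  auto slow_forces = [&](double tt) {
    clock_t pc0 = clock();
    std::fill(fsx.begin(), fsx.end(), 0.0);
    std::fill(fsy.begin(), fsy.end(), 0.0);
    Pairs P;
    build_pairs(REAL(x), REAL(y), n, support, xlo, xhi, periodic, P);
    prof_pairs += (long)P.i.size();
    // density (direct summation, all kinds as neighbors)
    double w0 = w_cubic(0.0, h);
    for (int a = 0; a < n; ++a) rho[a] = mass[a] * w0;
    int m = P.i.size();
    for (int k = 0; k < m; ++k) {
      if (P.r[k] >= 2.0 * h) continue;
      double w = w_cubic(P.r[k], h);
      rho[P.i[k]] += mass[P.j[k]] * w;
      rho[P.j[k]] += mass[P.i[k]] * w;
    }
    for (int a = 0; a < n; ++a) prs[a] = tait(rho[a], rho0, c0, gamma);
    ForceDiag dg;
    accum_pv(P, INTEGER(kind), REAL(vx), REAL(vy), REAL(mass), rho.data(), prs.data(),
             mu, h, fsx.data(), fsy.data(), dg);
    accum_repulsion(P, INTEGER(kind), rc, rep_strength, rep_solid, &bonded, n,
                    fsx.data(), fsy.data(), dg);
    double nxs = 0, nys = 0;
    for (int a = 0; a < n; ++a) { nxs += fsx[a]; nys += fsy[a]; }
    double imb = std::sqrt(nxs * nxs + nys * nys) / std::max(dg.sum_abs, 1e-300);
    if (imb > max_imb) max_imb = imb;
    // external per-particle terms (not part of the momentum-balance check)
    double g = (waveform == 0) ? g0 : g0 * std::sin(2.0 * M_PI * freq * tt);
    bool has_ext = ext_fx.size() == n;
    for (int a = 0; a < n; ++a) {
      if (kind[a] == 0) { fsx[a] += mass[a] * g * gdx; fsy[a] += mass[a] * g * gdy; }
      if (has_ext) { fsx[a] += ext_fx[a]; fsy[a] += ext_fy[a]; }
      if (damping > 0 && !anchored[a]) { fsx[a] -= damping * vx[a]; fsy[a] -= damping * vy[a]; }
    }
    prof_slow += (double)(clock() - pc0) / CLOCKS_PER_SEC;
  };

  auto fast_forces = [&]() {
    clock_t pc0 = clock();
    std::fill(ffx.begin(), ffx.end(), 0.0);
    std::fill(ffy.begin(), ffy.end(), 0.0);
    ForceDiag dg;
    accum_springs(REAL(x), REAL(y), b0i.data(), b0j.data(), REAL(bk), REAL(brest),
                  INTEGER(bactive), nb, Lx, periodic, ffx.data(), ffy.data(),
                  tension.data(), dg);
    accum_hinges(REAL(x), REAL(y), h0i.data(), h0j.data(), h0k.data(),
                 REAL(hka), REAL(hrest), nh, Lx, periodic, ffx.data(), ffy.data(), dg);
    prof_fast += (double)(clock() - pc0) / CLOCKS_PER_SEC;
  };

  slow_forces(t);

  for (int step = 0; step < nsteps; ++step) {
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
    double hdt = 0.5 * dt;
    for (int a = 0; a < n; ++a) {
      if (anchored[a]) { vx[a] = 0; vy[a] = 0; continue; }
      vx[a] += hdt * fsx[a] / mass[a];
      vy[a] += hdt * fsy[a] / mass[a];
    }
    if (has_fast) {
      // non-fast particles drift once; fast particles are sub-stepped
      for (int a = 0; a < n; ++a) {
        if (anchored[a] || fast_mark[a]) continue;
        x[a] += dt * vx[a];
        y[a] += dt * vy[a];
      }
      fast_forces();
      double hs = 0.5 * dtn;
      for (int s = 0; s < nsub; ++s) {
        for (size_t q = 0; q < fast_ids.size(); ++q) {
          int a = fast_ids[q];
          vx[a] += hs * ffx[a] / mass[a];
          vy[a] += hs * ffy[a] / mass[a];
          x[a] += dtn * vx[a];
          y[a] += dtn * vy[a];
        }
        fast_forces();
        for (size_t q = 0; q < fast_ids.size(); ++q) {
          int a = fast_ids[q];
          vx[a] += hs * ffx[a] / mass[a];
          vy[a] += hs * ffy[a] / mass[a];
        }
      }
    } else {
      for (int a = 0; a < n; ++a) {
        if (anchored[a]) continue;
        x[a] += dt * vx[a];
        y[a] += dt * vy[a];
      }
    }
    if (periodic) {
      for (int a = 0; a < n; ++a) {
        if (x[a] >= xhi) x[a] -= Lx * std::floor((x[a] - xlo) / Lx);
        else if (x[a] < xlo) x[a] += Lx * std::ceil((xlo - x[a]) / Lx);
        if (x[a] == xhi) x[a] = xlo;
      }
    }
    t = t0 + (step + 1) * dt;
    slow_forces(t);
    for (int a = 0; a < n; ++a) {
      if (anchored[a]) { vx[a] = 0; vy[a] = 0; continue; }
      vx[a] += hdt * fsx[a] / mass[a];
      vy[a] += hdt * fsy[a] / mass[a];
    }
    // fragmentation: remove every breakable bond over threshold this step
    if (break_check && nb > 0) {
      if (!has_fast) fast_forces();
      for (int k = 0; k < nb; ++k) {
        if (!bactive[k] || !R_FINITE(bthr[k])) continue;
        if (tension[k] > bthr[k]) {
          bactive[k] = 0;
          bonded.erase(pair_key(b0i[k], b0j[k], n));
          ev_step.push_back(step + 1);
          ev_time.push_back(t);
          ev_bond.push_back(k + 1);
          ev_i.push_back(b0i[k] + 1);
          ev_j.push_back(b0j[k] + 1);
          ev_tension.push_back(tension[k]);
        }
      }
    }
    // diagnostics
    double ms = 0.0, dr = 0.0, pv = 0.0;
    for (int a = 0; a < n; ++a) {
      if (kind[a] != 0) continue;
      double sp = std::sqrt(vx[a] * vx[a] + vy[a] * vy[a]);
      if (sp > ms) ms = sp;
      double d = std::fabs(rho[a] - rho0) / rho0;
      if (d > dr) dr = d;
    }
    double pvm = 0.0;
    if (probe.size() > 0) {
      for (int q = 0; q < probe.size(); ++q) {
        double u = vx[probe[q] - 1];
        pv += u;
        if (std::fabs(u) > pvm) pvm = std::fabs(u);
      }
      pv /= probe.size();
    }
    tr_time[step] = t; tr_maxspeed[step] = ms; tr_probe[step] = pv;
    tr_probe_max[step] = pvm; tr_drho[step] = dr;
    if (ms > max_speed_run) max_speed_run = ms;
    if (dr > max_drho) max_drho = dr;
    if (step % 25 == 0 || step == nsteps - 1) {
      for (int a = 0; a < n; ++a)
        if (!R_FINITE(x[a]) || !R_FINITE(vx[a]) || !R_FINITE(y[a]) || !R_FINITE(vy[a]))
          stop("non-finite particle state at step %d", step + 1);
    }
  }

  int ne = ev_step.size();
  IntegerVector Es(ne), Eb(ne), Ei(ne), Ej(ne);
  NumericVector Et(ne), Etens(ne);
  for (int k = 0; k < ne; ++k) {
    Es[k] = ev_step[k]; Et[k] = ev_time[k]; Eb[k] = ev_bond[k];
    Ei[k] = ev_i[k]; Ej[k] = ev_j[k]; Etens[k] = ev_tension[k];
  }
  NumericVector rho_out(n), p_out(n), fx_out(n), fy_out(n);
  for (int a = 0; a < n; ++a) {
    rho_out[a] = rho[a]; p_out[a] = prs[a];
    fx_out[a] = fsx[a]; fy_out[a] = fsy[a];
  }
  return List::create(
    _["x"] = x, _["y"] = y, _["vx"] = vx, _["vy"] = vy,
    _["rho"] = rho_out, _["p"] = p_out, _["fx"] = fx_out, _["fy"] = fy_out,
    _["bond_active"] = bactive,
    _["t"] = t, _["nsub"] = nsub,
    _["prof"] = NumericVector::create(prof_slow, prof_fast, (double)prof_pairs / nsteps),
    _["max_imbalance"] = max_imb, _["max_drho"] = max_drho,
    _["max_speed"] = max_speed_run,
    _["trace"] = DataFrame::create(_["time"] = tr_time, _["max_speed"] = tr_maxspeed,
                                   _["probe_vx"] = tr_probe,
                                   _["probe_max_vx"] = tr_probe_max,
                                   _["max_drho"] = tr_drho),
    _["events"] = DataFrame::create(_["step"] = Es, _["time"] = Et, _["bond"] = Eb,
                                    _["i"] = Ei, _["j"] = Ej, _["tension"] = Etens));
}

// ---------------------------------------------------------------------------
// Grid field reconstruction: Shepard-normalized value + first-order
// moving-least-squares velocity gradient (exact for linear fields).

// [[Rcpp::export]]
List cpp_grid_interp(NumericVector x, NumericVector y,
                     NumericVector vx, NumericVector vy,
                     NumericVector mass, NumericVector rho,
                     double h, double ox, double oy, double gs,
                     int nx, int ny,
                     double xlo, double xhi, bool periodic,
                     double mask_rel) {
  int n = x.size();
  double Lx = xhi - xlo;
  double sup = 2.0 * h;
  int nn = nx * ny;
  std::vector<double> wsum(nn, 0.0), wraw(nn, 0.0), uxs(nn, 0.0), uys(nn, 0.0);
  // MLS moment matrix (symmetric 3x3) and rhs per node
  std::vector<double> M00(nn, 0), M01(nn, 0), M02(nn, 0), M11(nn, 0), M12(nn, 0), M22(nn, 0);
  std::vector<double> bu0(nn, 0), bu1(nn, 0), bu2(nn, 0), bv0(nn, 0), bv1(nn, 0), bv2(nn, 0);
  for (int a = 0; a < n; ++a) {
    double V = mass[a] / rho[a];
    // node index window covering the kernel support (account for periodicity
    // by testing shifted images when the support crosses the box edge)
    for (int im = (periodic ? -1 : 0); im <= (periodic ? 1 : 0); ++im) {
      double px = x[a] + im * Lx;
      int i0 = (int)std::ceil((px - sup - ox) / gs);
      int i1 = (int)std::floor((px + sup - ox) / gs);
      int j0 = (int)std::ceil((y[a] - sup - oy) / gs);
      int j1 = (int)std::floor((y[a] + sup - oy) / gs);
      if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
      if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;
      for (int jx = i0; jx <= i1; ++jx) {
        double gxp = ox + jx * gs;
        double ddx = px - gxp;
        for (int jy = j0; jy <= j1; ++jy) {
          double gyp = oy + jy * gs;
          double ddy = y[a] - gyp;
          double r = std::sqrt(ddx * ddx + ddy * ddy);
          if (r >= sup) continue;
          double w0r = w_cubic(r, h);
          double w = w0r * V;
          int idn = jy * nx + jx;
          wraw[idn] += w0r;
          wsum[idn] += w;
          uxs[idn] += w * vx[a];
          uys[idn] += w * vy[a];
          M00[idn] += w; M01[idn] += w * ddx; M02[idn] += w * ddy;
          M11[idn] += w * ddx * ddx; M12[idn] += w * ddx * ddy; M22[idn] += w * ddy * ddy;
          bu0[idn] += w * vx[a]; bu1[idn] += w * vx[a] * ddx; bu2[idn] += w * vx[a] * ddy;
          bv0[idn] += w * vy[a]; bv1[idn] += w * vy[a] * ddx; bv2[idn] += w * vy[a] * ddy;
        }
      }
    }
  }
  double w0 = w_cubic(0.0, h);
  NumericVector ux(nn, NA_REAL), uy(nn, NA_REAL);
  NumericVector dudx(nn, NA_REAL), dudy(nn, NA_REAL), dvdx(nn, NA_REAL), dvdy(nn, NA_REAL);
  LogicalVector mask(nn, true);
  for (int idn = 0; idn < nn; ++idn) {
    // masked when the raw kernel weight reaching the node is negligible
    if (wraw[idn] <= mask_rel * w0 || wsum[idn] <= 0.0) continue;
    mask[idn] = false;
    ux[idn] = uxs[idn] / wsum[idn];
    uy[idn] = uys[idn] / wsum[idn];
    // solve M beta = b (3x3 symmetric) for each velocity component
    double A[3][3] = {{M00[idn], M01[idn], M02[idn]},
                      {M01[idn], M11[idn], M12[idn]},
                      {M02[idn], M12[idn], M22[idn]}};
    double B[3][2] = {{bu0[idn], bv0[idn]}, {bu1[idn], bv1[idn]}, {bu2[idn], bv2[idn]}};
    // Gaussian elimination with partial pivoting
    bool ok = true;
    int piv[3] = {0, 1, 2};
    for (int c = 0; c < 3 && ok; ++c) {
      int pr = c;
      for (int r2 = c + 1; r2 < 3; ++r2)
        if (std::fabs(A[r2][c]) > std::fabs(A[pr][c])) pr = r2;
      if (std::fabs(A[pr][c]) < 1e-300) { ok = false; break; }
      if (pr != c) {
        for (int cc = 0; cc < 3; ++cc) std::swap(A[pr][cc], A[c][cc]);
        std::swap(B[pr][0], B[c][0]); std::swap(B[pr][1], B[c][1]);
        std::swap(piv[pr], piv[c]);
      }
      for (int r2 = c + 1; r2 < 3; ++r2) {
        double fct = A[r2][c] / A[c][c];
        for (int cc = c; cc < 3; ++cc) A[r2][cc] -= fct * A[c][cc];
        B[r2][0] -= fct * B[c][0]; B[r2][1] -= fct * B[c][1];
      }
    }
    if (!ok || std::fabs(A[2][2]) < 1e-300) continue; // value kept, gradient NA
    double beta[3][2];
    for (int r2 = 2; r2 >= 0; --r2) {
      for (int comp = 0; comp < 2; ++comp) {
        double sum = B[r2][comp];
        for (int cc = r2 + 1; cc < 3; ++cc) sum -= A[r2][cc] * beta[cc][comp];
        beta[r2][comp] = sum / A[r2][r2];
      }
    }
    // note: ddx,ddy were (particle - node), so beta1/beta2 are d/dx, d/dy
    dudx[idn] = beta[1][0]; dudy[idn] = beta[2][0];
    dvdx[idn] = beta[1][1]; dvdy[idn] = beta[2][1];
  }
  return List::create(_["ux"] = ux, _["uy"] = uy,
                      _["dudx"] = dudx, _["dudy"] = dudy,
                      _["dvdx"] = dvdx, _["dvdy"] = dvdy,
                      _["mask"] = mask);
}
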