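// Analog photon transport through constructive-solid-geometry quadric
// geometry, with track-length flux and collision-kerma estimators.
//
// Geometry model: surfaces are general quadrics
//   Q(p) = A x^2 + B y^2 + C z^2 + D xy + E yz + F zx + G x + H y + I z + J
// A cell is an intersection of half-spaces (signed surface indices: +s means
// Q < 0, -s means Q > 0), optionally minus the union of "excluded" cells
// (their raw half-space sets). Cells are pairwise disjoint by construction;
// point location is first-match in a fixed cell order.
//
// Tracking keeps the flight origin fixed and advances the ray parameter t so
// that segment lengths telescope exactly (no accumulation error from the
// boundary-crossing nudge, which only offsets the membership probe point).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double MEC2 = 0.51099895; // electron rest energy, MeV (CODATA)
static const double T_PUSH = 1e-7;      // cm, boundary-crossing nudge
static const double WORLD_R2 = 400.0 * 400.0;

struct Surface { double A,B,C,D,E,F,G,H,I,J; };

struct Geometry {
  std::vector<Surface> surf;
  std::vector< std::vector<int> > cells;   // signed 1-based surface ids
  std::vector< std::vector<int> > excl;    // 0-based excluded cell ids
  std::vector<int> mat;                    // 0-based material index per cell
  std::vector<double> vol, mass;
  int ncell;
};

struct XsTable {
  std::vector<double> e, pe, inc, pair, muen, tot;
  double density;
};

static Geometry parse_geometry(const List& g) {
  Geometry geo;
  NumericMatrix sm = g["surfaces"];
  geo.surf.resize(sm.nrow());
  for (int i = 0; i < sm.nrow(); ++i) {
    Surface& s = geo.surf[i];
    s.A=sm(i,0); s.B=sm(i,1); s.C=sm(i,2); s.D=sm(i,3); s.E=sm(i,4);
    s.F=sm(i,5); s.G=sm(i,6); s.H=sm(i,7); s.I=sm(i,8); s.J=sm(i,9);
  }
  List cl = g["cells"];
  List ex = g["exclusions"];
  geo.ncell = cl.size();
  geo.cells.resize(geo.ncell);
  geo.excl.resize(geo.ncell);
  for (int i = 0; i < geo.ncell; ++i) {
    IntegerVector v = cl[i];
    geo.cells[i] = std::vector<int>(v.begin(), v.end());
    IntegerVector e = ex[i];
    geo.excl[i].clear();
    for (int j = 0; j < e.size(); ++j) geo.excl[i].push_back(e[j] - 1);
  }
  IntegerVector m = g["material_id"];
  geo.mat = std::vector<int>(m.begin(), m.end());
  for (size_t i = 0; i < geo.mat.size(); ++i) geo.mat[i] -= 1;
  NumericVector vv = g["volume"], mm = g["mass"];
  geo.vol = std::vector<double>(vv.begin(), vv.end());
  geo.mass = std::vector<double>(mm.begin(), mm.end());
  return geo;
}

static std::vector<XsTable> parse_xs(const List& xs) {
  std::vector<XsTable> out(xs.size());
  for (int i = 0; i < xs.size(); ++i) {
    List one = xs[i];
    NumericVector e = one["energy"], pe = one["pe"], inc = one["incoherent"],
                  pr = one["pair"], mu = one["muen"];
    XsTable& t = out[i];
    t.e = std::vector<double>(e.begin(), e.end());
    t.pe = std::vector<double>(pe.begin(), pe.end());
    t.inc = std::vector<double>(inc.begin(), inc.end());
    t.pair = std::vector<double>(pr.begin(), pr.end());
    t.muen = std::vector<double>(mu.begin(), mu.end());
    t.tot.resize(t.e.size());
    for (size_t j = 0; j < t.e.size(); ++j)
      t.tot[j] = t.pe[j] + t.inc[j] + t.pair[j];
    t.density = as<double>(one["density"]);
  }
  return out;
}

// log-log interpolation with linear fallback around non-positive values
static double interp_xs(const std::vector<double>& x,
                        const std::vector<double>& y, double xq) {
  int n = x.size();
  if (xq <= x[0]) return y[0];
  if (xq >= x[n-1]) return y[n-1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; (x[mid] <= xq ? lo : hi) = mid; }
  double x0 = x[lo], x1 = x[hi], y0 = y[lo], y1 = y[hi];
  if (y0 <= 0.0 || y1 <= 0.0) {
    double f = (xq - x0) / (x1 - x0);
    double v = y0 + f * (y1 - y0);
    return v > 0.0 ? v : 0.0;
  }
  double f = (std::log(xq) - std::log(x0)) / (std::log(x1) - std::log(x0));
  return std::exp(std::log(y0) + f * (std::log(y1) - std::log(y0)));
}

static inline double qeval(const Surface& s, double x, double y, double z) {
  return s.A*x*x + s.B*y*y + s.C*z*z + s.D*x*y + s.E*y*z + s.F*z*x
       + s.G*x + s.H*y + s.I*z + s.J;
}

static bool raw_inside(const Geometry& geo, int cell,
                       double x, double y, double z) {
  const std::vector<int>& cs = geo.cells[cell];
  for (size_t i = 0; i < cs.size(); ++i) {
    int sid = cs[i];
    double q = qeval(geo.surf[std::abs(sid) - 1], x, y, z);
    if (sid > 0 ? (q >= 0.0) : (q <= 0.0)) return false;
  }
  return true;
}

static bool member(const Geometry& geo, int cell,
                   double x, double y, double z) {
  if (!raw_inside(geo, cell, x, y, z)) return false;
  const std::vector<int>& ex = geo.excl[cell];
  for (size_t i = 0; i < ex.size(); ++i)
    if (raw_inside(geo, ex[i], x, y, z)) return false;
  return true;
}

static int locate(const Geometry& geo, double x, double y, double z) {
  for (int c = 0; c < geo.ncell; ++c)
    if (member(geo, c, x, y, z)) return c;
  return -1;
}

// ---- ray/quadric interval machinery -------------------------------------

struct Iv { double lo, hi; };

// Intervals along the ray where the half-space constraint holds
// (appends at most 2 intervals to out).
static void halfspace_intervals(const Surface& s, int sense,
                                const double* o, const double* d,
                                std::vector<Iv>& out) {
  double a = s.A*d[0]*d[0] + s.B*d[1]*d[1] + s.C*d[2]*d[2]
           + s.D*d[0]*d[1] + s.E*d[1]*d[2] + s.F*d[2]*d[0];
  double b = 2.0*(s.A*o[0]*d[0] + s.B*o[1]*d[1] + s.C*o[2]*d[2])
           + s.D*(o[0]*d[1] + o[1]*d[0]) + s.E*(o[1]*d[2] + o[2]*d[1])
           + s.F*(o[2]*d[0] + o[0]*d[2])
           + s.G*d[0] + s.H*d[1] + s.I*d[2];
  double c = qeval(s, o[0], o[1], o[2]);
  if (sense < 0) { a = -a; b = -b; c = -c; }  // want Q > 0  <=>  -Q < 0
  const double tiny = 1e-14;
  if (std::fabs(a) < tiny) {
    if (std::fabs(b) < tiny) {
      if (c < 0.0) out.push_back({-INF, INF});
      return;
    }
    double t = -c / b;
    if (b > 0) out.push_back({-INF, t}); else out.push_back({t, INF});
    return;
  }
  double disc = b*b - 4.0*a*c;
  if (a > 0) {
    if (disc <= 0.0) return;                 // never negative
    double sd = std::sqrt(disc);
    out.push_back({(-b - sd) / (2.0*a), (-b + sd) / (2.0*a)});
  } else {
    if (disc <= 0.0) { out.push_back({-INF, INF}); return; }
    double sd = std::sqrt(disc);
    double t1 = (-b + sd) / (2.0*a), t2 = (-b - sd) / (2.0*a); // t1 < t2
    out.push_back({-INF, t1});
    out.push_back({t2, INF});
  }
}

static void intersect_ivs(std::vector<Iv>& A, const std::vector<Iv>& B,
                          std::vector<Iv>& scratch) {
  scratch.clear();
  for (size_t i = 0; i < A.size(); ++i)
    for (size_t j = 0; j < B.size(); ++j) {
      double lo = std::max(A[i].lo, B[j].lo);
      double hi = std::min(A[i].hi, B[j].hi);
      if (lo < hi) scratch.push_back({lo, hi});
    }
  A.swap(scratch);
}

// Interval set (along ray) where the raw cell region holds.
static void cell_intervals(const Geometry& geo, int cell,
                           const double* o, const double* d,
                           std::vector<Iv>& ivs) {
  static std::vector<Iv> tmp, scratch;
  ivs.clear();
  ivs.push_back({-INF, INF});
  const std::vector<int>& cs = geo.cells[cell];
  for (size_t i = 0; i < cs.size() && !ivs.empty(); ++i) {
    tmp.clear();
    int sid = cs[i];
    halfspace_intervals(geo.surf[std::abs(sid) - 1], sid > 0 ? 1 : -1,
                        o, d, tmp);
    intersect_ivs(ivs, tmp, scratch);
  }
}

// Next geometric event along the ray from parameter t0 inside `cell`:
// returns event t; *next_cell = entered child (>=0), -1 (exit: relocate),
// or -2 (membership glitch: relocate in place).
static double next_event(const Geometry& geo, int cell,
                         const double* o, const double* d, double t0,
                         int* next_cell) {
  static std::vector<Iv> ivs, civ;
  cell_intervals(geo, cell, o, d, ivs);
  double t_exit = t0;
  bool found = false;
  for (size_t i = 0; i < ivs.size(); ++i)
    if (ivs[i].lo <= t0 + 1e-9 && ivs[i].hi > t0) {
      t_exit = ivs[i].hi; found = true; break;
    }
  if (!found) { *next_cell = -2; return t0; }
  double t_best = t_exit;
  int child = -1;
  const std::vector<int>& ex = geo.excl[cell];
  for (size_t i = 0; i < ex.size(); ++i) {
    cell_intervals(geo, ex[i], o, d, civ);
    for (size_t j = 0; j < civ.size(); ++j) {
      double lo = civ[j].lo;
      if (lo > t0 + 1e-9 && lo < t_best) { t_best = lo; child = ex[i]; }
    }
  }
  *next_cell = child;
  return t_best;
}

// earliest entry into any cell from parameter t (for points located nowhere)
static double first_entry(const Geometry& geo, const double* o,
                          const double* d, double t) {
  static std::vector<Iv> civ;
  double t_in = INF;
  for (int c = 0; c < geo.ncell; ++c) {
    cell_intervals(geo, c, o, d, civ);
    for (size_t j = 0; j < civ.size(); ++j)
      if (civ[j].lo > t + 1e-9 && civ[j].lo < t_in) t_in = civ[j].lo;
  }
  return t_in;
}

// ---- physics --------------------------------------------------------------

// Klein-Nishina sampling of the scattered-energy fraction (standard
// two-branch rejection); returns eps, sets *cost to the scattering cosine.
static double sample_kn(double E, double* cost) {
  double k = E / MEC2;
  double eps0 = 1.0 / (1.0 + 2.0*k);
  double a1 = std::log(1.0/eps0), a2 = 0.5*(1.0 - eps0*eps0);
  double eps, sin2, q;
  do {
    if (unif_rand() * (a1 + a2) < a1) {
      eps = eps0 * std::exp(a1 * unif_rand());
    } else {
      eps = std::sqrt(eps0*eps0 + (1.0 - eps0*eps0) * unif_rand());
    }
    double ct = 1.0 + 1.0/k - 1.0/(k*eps);
    sin2 = 1.0 - ct*ct;
    if (sin2 < 0.0) sin2 = 0.0;
    q = 1.0 - eps*sin2/(1.0 + eps*eps);
    *cost = ct;
  } while (unif_rand() > q);
  return eps;
}

static void rotate_direction(double* u, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost*cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  double s = std::sqrt(std::max(0.0, 1.0 - uz*uz));
  double nx, ny, nz;
  if (s > 1e-10) {
    nx = cost*ux + sint*(ux*uz*cphi - uy*sphi)/s;
    ny = cost*uy + sint*(uy*uz*cphi + ux*sphi)/s;
    nz = cost*uz - sint*s*cphi;
  } else {
    nx = sint*cphi; ny = sint*sphi; nz = cost * (uz >= 0 ? 1.0 : -1.0);
  }
  double norm = std::sqrt(nx*nx + ny*ny + nz*nz);
  u[0] = nx/norm; u[1] = ny/norm; u[2] = nz/norm;
}

struct BankPhoton { double x,y,z,ux,uy,uz,E,w; int ncoll; };

// ---- exported functions ---------------------------------------------------

// [[Rcpp::export]]
IntegerVector pd_cpp_locate(List geom, NumericMatrix points) {
  Geometry geo = parse_geometry(geom);
  int n = points.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = locate(geo, points(i,0), points(i,1), points(i,2)) + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector pd_cpp_membership_count(List geom, NumericMatrix points) {
  Geometry geo = parse_geometry(geom);
  int n = points.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int c = 0; c < geo.ncell; ++c)
      if (member(geo, c, points(i,0), points(i,1), points(i,2))) ++cnt;
    out[i] = cnt;
  }
  return out;
}

// Trace a ray through the geometry: rows (cell id 1-based, 0 = nowhere,
// t0, t1) until tmax.
// [[Rcpp::export]]
NumericMatrix pd_cpp_trace(List geom, NumericVector origin,
                           NumericVector dir, double tmax) {
  Geometry geo = parse_geometry(geom);
  double o[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  for (int i = 0; i < 3; ++i) d[i] /= nrm;
  std::vector<double> c_out, t0_out, t1_out;
  double t = 0.0;
  int cell = locate(geo, o[0], o[1], o[2]);
  int guard = 0;
  while (t < tmax && ++guard < 100000) {
    if (cell < 0) {
      double t_in = first_entry(geo, o, d, t);
      if (!std::isfinite(t_in) || t_in >= tmax) {
        c_out.push_back(0); t0_out.push_back(t); t1_out.push_back(tmax);
        break;
      }
      c_out.push_back(0); t0_out.push_back(t); t1_out.push_back(t_in);
      t = t_in;
    } else {
      int nc;
      double t_ev = next_event(geo, cell, o, d, t, &nc);
      if (nc == -2) { cell = -1; continue; }
      double t_end = std::min(t_ev, tmax);
      c_out.push_back(cell + 1); t0_out.push_back(t); t1_out.push_back(t_end);
      if (t_ev >= tmax) break;
      t = t_ev;
    }
    double px = o[0] + (t + T_PUSH)*d[0], py = o[1] + (t + T_PUSH)*d[1],
           pz = o[2] + (t + T_PUSH)*d[2];
    cell = locate(geo, px, py, pz);
  }
  NumericMatrix out(c_out.size(), 3);
  for (size_t i = 0; i < c_out.size(); ++i) {
    out(i,0) = c_out[i]; out(i,1) = t0_out[i]; out(i,2) = t1_out[i];
  }
  colnames(out) = CharacterVector::create("cell", "t0", "t1");
  return out;
}

// [[Rcpp::export]]
NumericMatrix pd_cpp_sample_compton(double energy, int n) {
  RNGScope scope;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double ct;
    double eps = sample_kn(energy, &ct);
    out(i,0) = eps; out(i,1) = ct;
  }
  colnames(out) = CharacterVector::create("eps", "cos_theta");
  return out;
}

// [[Rcpp::export]]
NumericMatrix pd_cpp_sample_interaction(List xs_one, double energy, int n) {
  RNGScope scope;
  std::vector<XsTable> xs = parse_xs(List::create(xs_one));
  const XsTable& t = xs[0];
  double mu_pe = interp_xs(t.e, t.pe, energy);
  double mu_in = interp_xs(t.e, t.inc, energy);
  double mu_pr = energy > 2.0*MEC2 ? interp_xs(t.e, t.pair, energy) : 0.0;
  double mu = mu_pe + mu_in + mu_pr;
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * mu;
    if (u < mu_pe) {
      out(i,0) = 0; out(i,1) = 0.0; out(i,2) = 1.0; out(i,3) = energy;
    } else if (u < mu_pe + mu_in) {
      double ct;
      double eps = sample_kn(energy, &ct);
      out(i,0) = 1; out(i,1) = eps*energy; out(i,2) = ct;
      out(i,3) = energy*(1.0 - eps);
    } else {
      out(i,0) = 2; out(i,1) = MEC2; out(i,2) = 2.0*unif_rand() - 1.0;
      out(i,3) = energy - 2.0*MEC2;
    }
  }
  colnames(out) = CharacterVector::create("process", "energy_out",
                                          "cos_theta", "deposited");
  return out;
}

// Main transport loop. particles: columns x,y,z,ux,uy,uz,E,w and an
// optional 9th column "primary" (0/1; photons flagged 0, e.g. collimator
// leakage, never contribute to the uncollided-fluence tally);
// batch: 1-based batch index per particle. Returns per-cell x per-batch
// tallies (kerma MeV/g per source particle, flux and never-collided flux in
// cm^-2 per source particle) and per-batch energy bookkeeping
// (source, deposited, cutoff-terminated, escaped).
// [[Rcpp::export]]
List pd_cpp_transport(NumericMatrix particles, IntegerVector batch,
                      List geom, List xs, int nbatch, double cutoff) {
  RNGScope scope;
  Geometry geo = parse_geometry(geom);
  std::vector<XsTable> mats = parse_xs(xs);
  int np = particles.nrow();
  int nc = geo.ncell;
  NumericMatrix kerma(nc, nbatch), flux(nc, nbatch), primary(nc, nbatch);
  NumericMatrix ebal(4, nbatch);  // source, deposited, cutoff, escaped
  std::vector<BankPhoton> bank;

  for (int ip = 0; ip < np; ++ip) {
    if (ip % 65536 == 0) Rcpp::checkUserInterrupt();
    int ib = batch[ip] - 1;
    int ncoll0 = (particles.ncol() >= 9 && particles(ip,8) == 0.0) ? 1 : 0;
    BankPhoton ph = {particles(ip,0), particles(ip,1), particles(ip,2),
                     particles(ip,3), particles(ip,4), particles(ip,5),
                     particles(ip,6), particles(ip,7), ncoll0};
    ebal(0, ib) += ph.E * ph.w;
    bank.clear();
    bank.push_back(ph);
    while (!bank.empty()) {
      BankPhoton p = bank.back();
      bank.pop_back();
      bool alive = true;
      int guard = 0;
      while (alive && ++guard < 100000) {       // one iteration per flight
        if (p.E < cutoff) { ebal(2, ib) += p.E * p.w; break; }
        double o[3] = {p.x, p.y, p.z};
        double d[3] = {p.ux, p.uy, p.uz};
        int cell = locate(geo, o[0], o[1], o[2]);
        double tau = -std::log(unif_rand());
        double t = 0.0;
        bool collided = false;
        int fguard = 0;
        while (++fguard < 10000) {              // one iteration per segment
          if (cell < 0) {
            double t_in = first_entry(geo, o, d, t);
            if (!std::isfinite(t_in)) {
              ebal(3, ib) += p.E * p.w; alive = false; break;
            }
            t = t_in;
            double px = o[0] + (t + T_PUSH)*d[0],
                   py = o[1] + (t + T_PUSH)*d[1],
                   pz = o[2] + (t + T_PUSH)*d[2];
            cell = locate(geo, px, py, pz);
            continue;
          }
          int mi = geo.mat[cell];
          const XsTable& xt = mats[mi];
          double mpe = interp_xs(xt.e, xt.pe, p.E);
          double min_ = interp_xs(xt.e, xt.inc, p.E);
          double mpr = p.E > 2.0*MEC2 ? interp_xs(xt.e, xt.pair, p.E) : 0.0;
          double mu_lin = (mpe + min_ + mpr) * xt.density;
          double muen_rho = interp_xs(xt.e, xt.muen, p.E);

          int nxt;
          double t_ev = next_event(geo, cell, o, d, t, &nxt);
          if (nxt == -2) {
            double px = o[0] + (t + T_PUSH)*d[0],
                   py = o[1] + (t + T_PUSH)*d[1],
                   pz = o[2] + (t + T_PUSH)*d[2];
            int c2 = locate(geo, px, py, pz);
            if (c2 == cell) {  // truly stuck: terminate conservatively
              ebal(1, ib) += p.E * p.w; alive = false; break;
            }
            cell = c2;
            continue;
          }
          double seg = t_ev - t;
          double dcoll = mu_lin > 0.0 ? tau / mu_lin : INF;
          if (dcoll < seg) {
            double L = dcoll;
            if (geo.mass[cell] > 0.0) {
              kerma(cell, ib) += p.w * L * p.E * muen_rho / geo.mass[cell];
              flux(cell, ib) += p.w * L / geo.vol[cell];
              if (p.ncoll == 0) primary(cell, ib) += p.w * L / geo.vol[cell];
            }
            t += dcoll;
            p.x = o[0] + t*d[0]; p.y = o[1] + t*d[1]; p.z = o[2] + t*d[2];
            collided = true;
            double u = unif_rand() * (mpe + min_ + mpr);
            if (u < mpe) {
              ebal(1, ib) += p.E * p.w;
              alive = false;
            } else if (u < mpe + min_) {
              double ct;
              double eps = sample_kn(p.E, &ct);
              ebal(1, ib) += p.E * (1.0 - eps) * p.w;
              p.E *= eps;
              double dir[3] = {p.ux, p.uy, p.uz};
              rotate_direction(dir, ct, 2.0*M_PI*unif_rand());
              p.ux = dir[0]; p.uy = dir[1]; p.uz = dir[2];
              p.ncoll += 1;
            } else {
              ebal(1, ib) += (p.E - 2.0*MEC2) * p.w;
              double ct = 2.0*unif_rand() - 1.0;
              double st = std::sqrt(std::max(0.0, 1.0 - ct*ct));
              double phi = 2.0*M_PI*unif_rand();
              double dir[3] = {st*std::cos(phi), st*std::sin(phi), ct};
              BankPhoton q = {p.x, p.y, p.z, -dir[0], -dir[1], -dir[2],
                              MEC2, p.w, p.ncoll + 1};
              bank.push_back(q);
              p.E = MEC2;
              p.ux = dir[0]; p.uy = dir[1]; p.uz = dir[2];
              p.ncoll += 1;
            }
            break;
          } else {
            if (geo.mass[cell] > 0.0) {
              kerma(cell, ib) += p.w * seg * p.E * muen_rho / geo.mass[cell];
              flux(cell, ib) += p.w * seg / geo.vol[cell];
              if (p.ncoll == 0)
                primary(cell, ib) += p.w * seg / geo.vol[cell];
            }
            tau -= mu_lin * seg;
            t = t_ev;
            double px = o[0] + (t + T_PUSH)*d[0],
                   py = o[1] + (t + T_PUSH)*d[1],
                   pz = o[2] + (t + T_PUSH)*d[2];
            if (px*px + py*py + pz*pz > WORLD_R2) {
              ebal(3, ib) += p.E * p.w; alive = false; break;
            }
            cell = (nxt >= 0 && member(geo, nxt, px, py, pz))
                     ? nxt : locate(geo, px, py, pz);
          }
        }
        if (!alive || !collided) break;
      }
    }
  }
  return List::create(
    _["kerma"] = kerma, _["flux"] = flux, _["primary_flux"] = primary,
    _["energy_balance"] = ebal
  );
}
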