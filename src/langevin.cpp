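// Coarse-grained Langevin dynamics of semiflexible bead-spring filaments
// coupled by breakable catch-slip bonds. Reduced units throughout:
// lengths in sigma, energies in kBT, time in tau = alpha*sigma^2/kBT.
// Single-threaded; randomness comes from R's RNG so trajectories are
// bitwise reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Topology {
  std::vector<int> chain_start, chain_len;   // contiguous bead ranges
  // breakable inter-filament bonds
  std::vector<int> bb_i, bb_j;
  std::vector<double> bb_r0;
  // permanent links (cross-links, end ties)
  std::vector<int> pl_i, pl_j;
  std::vector<double> pl_r0, pl_k;
  std::vector<int> fixed;                    // tethered beads
  std::vector<int> pull_i;                   // beads under external force
  std::vector<double> pull_fx, pull_fy;      // per-bead force (unit F_e)
};

struct Params {
  double A, kappa, eps, sigma, km;
  double om1, om2, fd1, fd2;
  double dt, alpha, kBT, mass;
};

inline double sq(double x) { return x * x; }

// WCA cutoff
inline double wca_cut(double sigma) { return std::pow(2.0, 1.0 / 6.0) * sigma; }

class System {
public:
  int n;
  std::vector<double> x, y, vx, vy, fx, fy;
  std::vector<char> alive;       // breakable bond state
  Topology topo;
  Params p;
  // neighbor list
  std::vector<std::pair<int,int>> nlist;
  std::vector<double> x0, y0;    // positions at last list build
  double skin = 0.8;
  std::vector<char> excl;        // consecutive same-chain pair exclusion, n*n

  System(NumericMatrix pos, const Topology& t, const Params& par)
      : n(pos.nrow()), x(n), y(n), vx(n, 0.0), vy(n, 0.0),
        fx(n), fy(n), topo(t), p(par), x0(n), y0(n) {
    for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
    alive.assign(topo.bb_i.size(), 1);
    excl.assign((size_t)n * n, 0);
    for (size_t c = 0; c < topo.chain_start.size(); ++c) {
      int s = topo.chain_start[c], L = topo.chain_len[c];
      for (int i = 0; i < L - 1; ++i) {
        excl[(size_t)(s + i) * n + (s + i + 1)] = 1;
        excl[(size_t)(s + i + 1) * n + (s + i)] = 1;
      }
    }
    build_nlist();
  }

  void build_nlist() {
    nlist.clear();
    double rl = wca_cut(p.sigma) + skin;
    double rl2 = rl * rl;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (excl[(size_t)i * n + j]) continue;
        if (sq(x[i] - x[j]) + sq(y[i] - y[j]) < rl2)
          nlist.emplace_back(i, j);
      }
    x0 = x; y0 = y;
  }

  void maybe_rebuild() {
    double half = 0.5 * skin, max2 = sq(half);
    for (int i = 0; i < n; ++i)
      if (sq(x[i] - x0[i]) + sq(y[i] - y0[i]) > max2) { build_nlist(); return; }
  }

  // total potential energy split; fills fx, fy with -grad E (+ external)
  void forces(double Fe, double* e_stretch = nullptr, double* e_bend = nullptr,
              double* e_wca = nullptr, double* e_bond = nullptr) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    double Es = 0, Eb = 0, Ew = 0, Ebd = 0;

    // stretching: A/(2 sigma) (|b| - sigma)^2 per chain bond
    for (size_t c = 0; c < topo.chain_start.size(); ++c) {
      int s = topo.chain_start[c], L = topo.chain_len[c];
      for (int i = s; i < s + L - 1; ++i) {
        double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i];
        double b = std::sqrt(dx * dx + dy * dy);
        if (b < 1e-12) stop("coincident consecutive beads: tangent undefined");
        double ext = b - p.sigma;
        Es += 0.5 * (p.A / p.sigma) * ext * ext;
        double fmag = -(p.A / p.sigma) * ext / b;   // along bond, on bead i+1
        fx[i + 1] += fmag * dx; fy[i + 1] += fmag * dy;
        fx[i] -= fmag * dx;     fy[i] -= fmag * dy;
      }
      // bending: kappa/(2 sigma) |t_{i+1} - t_i|^2 = (kappa/sigma)(1 - t.t')
      for (int i = s; i < s + L - 2; ++i) {
        double ux = x[i + 1] - x[i], uy = y[i + 1] - y[i];
        double wx = x[i + 2] - x[i + 1], wy = y[i + 2] - y[i + 1];
        double bu = std::sqrt(ux * ux + uy * uy);
        double bw = std::sqrt(wx * wx + wy * wy);
        if (bu < 1e-12 || bw < 1e-12)
          stop("coincident consecutive beads: tangent undefined");
        double iu = 1.0 / bu, iw = 1.0 / bw;
        double tux = ux * iu, tuy = uy * iu, twx = wx * iw, twy = wy * iw;
        double ct = tux * twx + tuy * twy;
        double kb = p.kappa / p.sigma;
        Eb += kb * (1.0 - ct);
        // d(ct)/d(u) = (t_w - ct t_u)/|u| ; d(ct)/d(w) = (t_u - ct t_w)/|w|
        double dux = (twx - ct * tux) * iu, duy = (twy - ct * tuy) * iu;
        double dwx = (tux - ct * twx) * iw, dwy = (tuy - ct * twy) * iw;
        // E = kb(1 - ct): F = -dE/dr = +kb * d(ct)/dr
        fx[i]     -= kb * dux;        fy[i]     -= kb * duy;
        fx[i + 1] += kb * (dux - dwx); fy[i + 1] += kb * (duy - dwy);
        fx[i + 2] += kb * dwx;        fy[i + 2] += kb * dwy;
      }
    }

    // WCA on neighbor list
    double rc2 = sq(wca_cut(p.sigma));
    for (auto& pr : nlist) {
      int i = pr.first, j = pr.second;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double r2 = dx * dx + dy * dy;
      if (r2 >= rc2) continue;
      if (r2 < 1e-20) stop("overlapping beads in WCA pair");
      double s2 = sq(p.sigma) / r2, s6 = s2 * s2 * s2;
      Ew += 4.0 * p.eps * (s6 * s6 - s6 + 0.25);
      double fmag = 24.0 * p.eps * (2.0 * s6 * s6 - s6) / r2;  // repulsive
      fx[j] += fmag * dx; fy[j] += fmag * dy;
      fx[i] -= fmag * dx; fy[i] -= fmag * dy;
    }

    // elastic inter-filament bonds (breakable + permanent)
    for (size_t b = 0; b < topo.bb_i.size(); ++b) {
      if (!alive[b]) continue;
      bond_force(topo.bb_i[b], topo.bb_j[b], topo.bb_r0[b], p.km, Ebd);
    }
    for (size_t b = 0; b < topo.pl_i.size(); ++b)
      bond_force(topo.pl_i[b], topo.pl_j[b], topo.pl_r0[b], topo.pl_k[b], Ebd);

    // constant external pulling force
    for (size_t q = 0; q < topo.pull_i.size(); ++q) {
      fx[topo.pull_i[q]] += Fe * topo.pull_fx[q];
      fy[topo.pull_i[q]] += Fe * topo.pull_fy[q];
    }
    // tethered beads feel nothing
    for (int i : topo.fixed) { fx[i] = 0.0; fy[i] = 0.0; }

    if (e_stretch) { *e_stretch = Es; *e_bend = Eb; *e_wca = Ew; *e_bond = Ebd; }
  }

  void bond_force(int i, int j, double r0, double k, double& E) {
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) stop("zero-length inter-filament bond");
    double ext = r - r0;
    E += 0.5 * k * ext * ext;
    double fmag = -k * ext / r;
    fx[j] += fmag * dx; fy[j] += fmag * dy;
    fx[i] -= fmag * dx; fy[i] -= fmag * dy;
  }

  double bond_load(size_t b) const {
    int i = topo.bb_i[b], j = topo.bb_j[b];
    double r = std::sqrt(sq(x[j] - x[i]) + sq(y[j] - y[i]));
    return p.km * std::fabs(r - topo.bb_r0[b]);
  }

  // BAOAB step; forces must be current on entry and are current on exit
  void step(double Fe) {
    double hdt = 0.5 * p.dt;
    double c1 = std::exp(-p.alpha * p.dt / p.mass);
    double c2 = std::sqrt(p.kBT * (1.0 - c1 * c1) / p.mass);
    for (int i = 0; i < n; ++i) {
      vx[i] += hdt * fx[i] / p.mass; vy[i] += hdt * fy[i] / p.mass;
      x[i] += hdt * vx[i];           y[i] += hdt * vy[i];
      vx[i] = c1 * vx[i] + c2 * norm_rand();
      vy[i] = c1 * vy[i] + c2 * norm_rand();
      x[i] += hdt * vx[i];           y[i] += hdt * vy[i];
    }
    for (int i : topo.fixed) {
      x[i] = x0_fixed_x(i); y[i] = x0_fixed_y(i);
      vx[i] = 0.0; vy[i] = 0.0;
    }
    maybe_rebuild();
    forces(Fe);
    for (int i = 0; i < n; ++i) {
      vx[i] += hdt * fx[i] / p.mass; vy[i] += hdt * fy[i] / p.mass;
    }
    for (int i : topo.fixed) { vx[i] = 0.0; vy[i] = 0.0; }
  }

  // tether anchor positions (recorded at construction)
  std::vector<double> fx_anchor, fy_anchor;
  void record_anchors() {
    fx_anchor.assign(n, 0.0); fy_anchor.assign(n, 0.0);
    for (int i : topo.fixed) { fx_anchor[i] = x[i]; fy_anchor[i] = y[i]; }
  }
  double x0_fixed_x(int i) const { return fx_anchor[i]; }
  double x0_fixed_y(int i) const { return fy_anchor[i]; }

  double kinetic_energy_free() const {
    // kinetic energy of unconstrained beads
    std::vector<char> isfix(n, 0);
    for (int i : topo.fixed) isfix[i] = 1;
    double ke = 0;
    for (int i = 0; i < n; ++i)
      if (!isfix[i]) ke += 0.5 * p.mass * (vx[i] * vx[i] + vy[i] * vy[i]);
    return ke;
  }
};

Topology parse_topo(List sys) {
  Topology t;
  IntegerVector cs = sys["chain_starts"], cl = sys["chain_lengths"];
  t.chain_start = as<std::vector<int>>(cs);
  t.chain_len = as<std::vector<int>>(cl);
  NumericMatrix bb = sys["breakable"];
  for (int r = 0; r < bb.nrow(); ++r) {
    t.bb_i.push_back((int)bb(r, 0)); t.bb_j.push_back((int)bb(r, 1));
    t.bb_r0.push_back(bb(r, 2));
  }
  NumericMatrix pl = sys["permanent"];
  for (int r = 0; r < pl.nrow(); ++r) {
    t.pl_i.push_back((int)pl(r, 0)); t.pl_j.push_back((int)pl(r, 1));
    t.pl_r0.push_back(pl(r, 2)); t.pl_k.push_back(pl(r, 3));
  }
  t.fixed = as<std::vector<int>>(IntegerVector(sys["fixed"]));
  NumericMatrix pu = sys["pulled"];
  for (int r = 0; r < pu.nrow(); ++r) {
    t.pull_i.push_back((int)pu(r, 0));
    t.pull_fx.push_back(pu(r, 1)); t.pull_fy.push_back(pu(r, 2));
  }
  for (size_t b = 0; b < t.bb_i.size(); ++b)
    if (t.bb_i[b] == t.bb_j[b]) stop("bond connects a bead to itself");
  for (size_t b = 0; b < t.pl_i.size(); ++b)
    if (t.pl_i[b] == t.pl_j[b]) stop("link connects a bead to itself");
  return t;
}

Params parse_params(List par) {
  Params p;
  p.A = par["A"]; p.kappa = par["kappa"]; p.eps = par["eps_wca"];
  p.sigma = par["sigma"]; p.km = par["k_m"];
  p.om1 = par["omega0_1"]; p.om2 = par["omega0_2"];
  p.fd1 = par["f_d1"]; p.fd2 = par["f_d2"];
  p.dt = par["dt"]; p.alpha = par["alpha"]; p.kBT = par["kBT"];
  p.mass = par["mass"];
  if (p.dt <= 0 || p.dt >= 1) stop("need 0 < dt << 1 tau");
  return p;
}

inline double omega_off(double f1, const Params& p) {
  return p.om1 * std::exp(f1 / p.fd1) + p.om2 * std::exp(-f1 / p.fd2);
}

void check_blowup(const System& S, const std::vector<double>& px,
                  const std::vector<double>& py) {
  for (int i = 0; i < S.n; ++i)
    if (sq(S.x[i] - px[i]) + sq(S.y[i] - py[i]) > sq(S.p.sigma))
      stop("numerical blow-up: bead %d moved more than sigma in one step", i);
}

} // namespace

// [[Rcpp::export(name = ".lgv_energy_forces")]]
List lgv_energy_forces(NumericMatrix pos, List sys, List par) {
  Topology t = parse_topo(sys);
  Params p = parse_params(par);
  System S(pos, t, p);
  S.record_anchors();
  double es, eb, ew, ebd;
  // external force excluded here: pure potential-energy gradient check
  S.forces(0.0, &es, &eb, &ew, &ebd);
  NumericMatrix F(S.n, 2);
  for (int i = 0; i < S.n; ++i) { F(i, 0) = S.fx[i]; F(i, 1) = S.fy[i]; }
  return List::create(_["stretch"] = es, _["bend"] = eb, _["wca"] = ew,
                      _["bonds"] = ebd, _["total"] = es + eb + ew + ebd,
                      _["forces"] = F);
}

// [[Rcpp::export(name = ".lgv_run")]]
List lgv_run(NumericMatrix pos, List sys, List par, double Fe,
             double t_max, bool stop_when_all_broken, int n_equil,
             int sample_every, bool record_ke, int ke_burnin) {
  RNGScope scope;
  Topology t = parse_topo(sys);
  Params p = parse_params(par);
  System S(pos, t, p);
  S.record_anchors();

  // Maxwell-Boltzmann initial velocities
  double vsd = std::sqrt(p.kBT / p.mass);
  for (int i = 0; i < S.n; ++i) { S.vx[i] = vsd * norm_rand(); S.vy[i] = vsd * norm_rand(); }
  for (int i : S.topo.fixed) { S.vx[i] = 0.0; S.vy[i] = 0.0; }

  S.forces(Fe);
  // equilibration under load, ruptures disabled
  std::vector<double> px = S.x, py = S.y;
  for (int k = 0; k < n_equil; ++k) {
    px = S.x; py = S.y;
    S.step(Fe);
    if ((k & 1023) == 0) check_blowup(S, px, py);
  }

  long n_steps = (long)std::ceil(t_max / p.dt);
  int n_bonds = (int)S.topo.bb_i.size();
  int alive_count = n_bonds;
  std::vector<double> break_times(n_bonds, NA_REAL);
  double lifetime = NA_REAL;
  bool censored = false;

  std::vector<double> ke_samples;
  std::vector<double> snaps;   // flattened snapshots (x0..xn-1, y0..yn-1)
  long step_count = 0;
  if (alive_count == 0 && stop_when_all_broken) lifetime = 0.0;

  if (!(alive_count == 0 && stop_when_all_broken)) {
    for (long k = 0; k < n_steps; ++k) {
      px = S.x; py = S.y;
      S.step(Fe);
      ++step_count;
      if ((k & 255) == 0) check_blowup(S, px, py);
      if ((k & 4095) == 0) Rcpp::checkUserInterrupt();
      // stochastic rupture of surviving bonds
      if (alive_count > 0) {
        for (int b = 0; b < n_bonds; ++b) {
          if (!S.alive[b]) continue;
          double w = omega_off(S.bond_load(b), p);
          double pr = 1.0 - std::exp(-w * p.dt);
          if (unif_rand() < pr) {
            S.alive[b] = 0;
            --alive_count;
            break_times[b] = (k + 1) * p.dt;
          }
        }
        if (alive_count == 0 && stop_when_all_broken) {
          lifetime = (k + 1) * p.dt;
          break;
        }
      }
      if (record_ke && k >= ke_burnin && (k & 15) == 0)
        ke_samples.push_back(S.kinetic_energy_free());
      if (sample_every > 0 && (k + 1) % sample_every == 0) {
        for (int i = 0; i < S.n; ++i) snaps.push_back(S.x[i]);
        for (int i = 0; i < S.n; ++i) snaps.push_back(S.y[i]);
      }
    }
  }
  if (stop_when_all_broken && !R_finite(lifetime)) {
    lifetime = t_max; censored = true;
  }

  NumericMatrix fin(S.n, 2), vel(S.n, 2);
  for (int i = 0; i < S.n; ++i) {
    fin(i, 0) = S.x[i]; fin(i, 1) = S.y[i];
    vel(i, 0) = S.vx[i]; vel(i, 1) = S.vy[i];
  }
  List out = List::create(
    _["lifetime"] = lifetime, _["censored"] = censored,
    _["n_steps"] = (double)step_count,
    _["break_times"] = NumericVector(break_times.begin(), break_times.end()),
    _["alive"] = IntegerVector(S.alive.begin(), S.alive.end()),
    _["positions"] = fin, _["velocities"] = vel);
  if (record_ke)
    out["ke_samples"] = NumericVector(ke_samples.begin(), ke_samples.end());
  if (sample_every > 0) {
    int ns = (int)(snaps.size() / (2 * S.n));
    NumericVector sn(snaps.begin(), snaps.end());
    sn.attr("dim") = IntegerVector::create(S.n, 2 * ns);
    out["snapshots"] = sn;
    out["n_snapshots"] = ns;
  }
  return out;
}
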