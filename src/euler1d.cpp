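// Quasi-1D compressible Euler finite-volume kernel.
//
// Conserved variables per unit volume: rho, rho*u, E, rho*s (s = passive
// scalar marking driver gas). Geometry enters through face areas A(x);
// cell volume V_i = 0.5*(A_L + A_R)*dx and the momentum equation carries
// the p*dA source so a uniform state at rest is an exact equilibrium.
//
// Numerics: minmod-limited linear reconstruction of primitives, HLLC flux,
// SSP-RK2 time stepping at a fixed CFL number. A single interior face may
// act as a frangible diaphragm: its open fraction ramps linearly over the
// petal duration, and the closed fraction contributes a wall pressure flux
// on each side (mass/energy through the closed part are exactly zero).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Prim { double rho, u, p, s; };

inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return (std::fabs(a) < std::fabs(b)) ? a : b;
}

// HLLC flux for (rho, rho u, E, rho s); gamma-law gas.
inline void hllc_flux(const Prim& L, const Prim& R, double g, double* F) {
  const double aL = std::sqrt(g * L.p / L.rho);
  const double aR = std::sqrt(g * R.p / R.rho);
  const double EL = L.p / (g - 1.0) + 0.5 * L.rho * L.u * L.u;
  const double ER = R.p / (g - 1.0) + 0.5 * R.rho * R.u * R.u;

  const double SL = std::min(L.u - aL, R.u - aR);
  const double SR = std::max(L.u + aL, R.u + aR);

  if (SL >= 0.0) {
    F[0] = L.rho * L.u;
    F[1] = L.rho * L.u * L.u + L.p;
    F[2] = (EL + L.p) * L.u;
    F[3] = L.rho * L.s * L.u;
    return;
  }
  if (SR <= 0.0) {
    F[0] = R.rho * R.u;
    F[1] = R.rho * R.u * R.u + R.p;
    F[2] = (ER + R.p) * R.u;
    F[3] = R.rho * R.s * R.u;
    return;
  }

  const double dL = L.rho * (SL - L.u);
  const double dR = R.rho * (SR - R.u);
  const double Sstar = (R.p - L.p + L.u * dL - R.u * dR) / (dL - dR);

  if (Sstar >= 0.0) {
    const double rhoS = L.rho * (SL - L.u) / (SL - Sstar);
    const double eS = EL / L.rho +
      (Sstar - L.u) * (Sstar + L.p / (L.rho * (SL - L.u)));
    const double U0 = L.rho, U1 = L.rho * L.u, U2 = EL, U3 = L.rho * L.s;
    F[0] = L.rho * L.u          + SL * (rhoS          - U0);
    F[1] = L.rho * L.u * L.u + L.p + SL * (rhoS * Sstar - U1);
    F[2] = (EL + L.p) * L.u     + SL * (rhoS * eS      - U2);
    F[3] = L.rho * L.s * L.u    + SL * (rhoS * L.s     - U3);
  } else {
    const double rhoS = R.rho * (SR - R.u) / (SR - Sstar);
    const double eS = ER / R.rho +
      (Sstar - R.u) * (Sstar + R.p / (R.rho * (SR - R.u)));
    const double U0 = R.rho, U1 = R.rho * R.u, U2 = ER, U3 = R.rho * R.s;
    F[0] = R.rho * R.u          + SR * (rhoS          - U0);
    F[1] = R.rho * R.u * R.u + R.p + SR * (rhoS * Sstar - U1);
    F[2] = (ER + R.p) * R.u     + SR * (rhoS * eS      - U2);
    F[3] = R.rho * R.s * R.u    + SR * (rhoS * R.s     - U3);
  }
}

class Euler1D {
public:
  int n;                       // cells
  double g;                    // gamma
  std::vector<double> xf, Af;  // faces: n+1
  std::vector<double> xc, vol; // cells
  std::vector<double> fric_f;  // quadratic loss coefficient, u > 0, 1/m
  std::vector<double> fric_r;  // quadratic loss coefficient, u < 0, 1/m
  std::vector<double> U;       // 4*n conserved densities
  int diaph;                   // face index of diaphragm, -1 none
  double petal;                // opening duration (s)

  Euler1D(int n_, double g_) : n(n_), g(g_), diaph(-1), petal(0.0) {}

  double ramp(double t) const {
    if (diaph < 0) return 1.0;
    if (petal <= 0.0) return t >= 0.0 ? 1.0 : 0.0;
    return std::max(0.0, std::min(1.0, t / petal));
  }

  void primitives(const std::vector<double>& Uv, std::vector<Prim>& W) const {
    for (int i = 0; i < n; ++i) {
      double rho = Uv[4 * i];
      double u = Uv[4 * i + 1] / rho;
      double p = (g - 1.0) * (Uv[4 * i + 2] - 0.5 * rho * u * u);
      double s = Uv[4 * i + 3] / rho;
      W[i] = {rho, u, p, s};
    }
  }

  // Residual L(U): dU/dt for all cells, at diaphragm ramp value `rmp`.
  void rhs(const std::vector<Prim>& W, double rmp,
           std::vector<double>& dU) const {
    // limited slopes on primitives (ghost cells mirror u)
    std::vector<Prim> dW(n);
    for (int i = 0; i < n; ++i) {
      Prim lo = (i > 0) ? W[i - 1] : Prim{W[0].rho, -W[0].u, W[0].p, W[0].s};
      Prim hi = (i < n - 1) ? W[i + 1]
                            : Prim{W[n - 1].rho, -W[n - 1].u, W[n - 1].p,
                                   W[n - 1].s};
      dW[i].rho = minmod(W[i].rho - lo.rho, hi.rho - W[i].rho);
      dW[i].u   = minmod(W[i].u   - lo.u,   hi.u   - W[i].u);
      dW[i].p   = minmod(W[i].p   - lo.p,   hi.p   - W[i].p);
      dW[i].s   = minmod(W[i].s   - lo.s,   hi.s   - W[i].s);
    }
    std::fill(dU.begin(), dU.end(), 0.0);

    double F[4];
    // interior faces f = 1..n-1 between cells f-1 and f
    for (int f = 1; f < n; ++f) {
      const Prim& wl = W[f - 1];
      const Prim& wr = W[f];
      Prim L = {wl.rho + 0.5 * dW[f - 1].rho, wl.u + 0.5 * dW[f - 1].u,
                wl.p + 0.5 * dW[f - 1].p, wl.s + 0.5 * dW[f - 1].s};
      Prim R = {wr.rho - 0.5 * dW[f].rho, wr.u - 0.5 * dW[f].u,
                wr.p - 0.5 * dW[f].p, wr.s - 0.5 * dW[f].s};
      if (L.rho <= 0.0 || L.p <= 0.0) L = wl;
      if (R.rho <= 0.0 || R.p <= 0.0) R = wr;

      double Aop = Af[f];
      double wallL = 0.0, wallR = 0.0;
      if (f == diaph && rmp < 1.0) {
        Aop = Af[f] * rmp;
        // closed fraction acts as a wall: pressure force only
        wallL = Af[f] * (1.0 - rmp) * L.p;
        wallR = Af[f] * (1.0 - rmp) * R.p;
      }
      hllc_flux(L, R, g, F);
      for (int k = 0; k < 4; ++k) {
        double phi = Aop * F[k];
        dU[4 * (f - 1) + k] -= phi;
        dU[4 * f + k]       += phi;
      }
      dU[4 * (f - 1) + 1] -= wallL;
      dU[4 * f + 1]       += wallR;
    }
    // reflective ends: zero mass/energy flux, wall pressure on momentum
    {
      const Prim& w0 = W[0];
      dU[1] += Af[0] * w0.p;
      const Prim& wn = W[n - 1];
      dU[4 * (n - 1) + 1] -= Af[n] * wn.p;
    }
    // quasi-1D area source on momentum, and divide by cell volume
    for (int i = 0; i < n; ++i) {
      dU[4 * i + 1] += W[i].p * (Af[i + 1] - Af[i]);
      for (int k = 0; k < 4; ++k) dU[4 * i + k] /= vol[i];
      // sudden-enlargement / jet-mixing loss: quadratic momentum sink,
      // total energy untouched, so lost kinetic energy becomes heat;
      // directional, since each side dissipates when it receives the jet
      const double fr = (W[i].u > 0.0) ? fric_f[i] : fric_r[i];
      if (fr != 0.0)
        dU[4 * i + 1] -= 0.5 * fr * W[i].rho *
                         W[i].u * std::fabs(W[i].u);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".euler1d_run")]]
List euler1d_run(NumericVector x_face, NumericVector A_face,
                 NumericVector rho0, NumericVector u0, NumericVector p0,
                 NumericVector s0, double gamma, double t_end, double cfl,
                 int diaph_face, double petal_duration,
                 NumericVector fric_fwd, NumericVector fric_rev,
                 IntegerVector probe_cells, double snap_dt,
                 double track_x_from, double track_x_to,
                 double track_t_max, double R_air) {
  const int n = rho0.size();
  if (x_face.size() != n + 1 || A_face.size() != n + 1)
    stop("faces must have length n_cells + 1");
  if (cfl <= 0.0 || cfl > 1.0) stop("cfl must be in (0, 1]");

  Euler1D sim(n, gamma);
  sim.xf.assign(x_face.begin(), x_face.end());
  sim.Af.assign(A_face.begin(), A_face.end());
  sim.xc.resize(n);
  sim.vol.resize(n);
  for (int i = 0; i < n; ++i) {
    sim.xc[i] = 0.5 * (sim.xf[i] + sim.xf[i + 1]);
    sim.vol[i] = 0.5 * (sim.Af[i] + sim.Af[i + 1]) *
                 (sim.xf[i + 1] - sim.xf[i]);
  }
  sim.diaph = diaph_face; // 0-based face index (-1: none)
  sim.petal = petal_duration;
  if (fric_fwd.size() == 0) sim.fric_f.assign(n, 0.0);
  else if (fric_fwd.size() == n)
    sim.fric_f.assign(fric_fwd.begin(), fric_fwd.end());
  else stop("friction profile must have one value per cell");
  if (fric_rev.size() == 0) sim.fric_r.assign(n, 0.0);
  else if (fric_rev.size() == n)
    sim.fric_r.assign(fric_rev.begin(), fric_rev.end());
  else stop("friction profile must have one value per cell");

  sim.U.resize(4 * n);
  for (int i = 0; i < n; ++i) {
    if (rho0[i] <= 0.0 || p0[i] <= 0.0) stop("initial state must be positive");
    sim.U[4 * i]     = rho0[i];
    sim.U[4 * i + 1] = rho0[i] * u0[i];
    sim.U[4 * i + 2] = p0[i] / (gamma - 1.0) + 0.5 * rho0[i] * u0[i] * u0[i];
    sim.U[4 * i + 3] = rho0[i] * s0[i];
  }

  const int np = probe_cells.size();
  std::vector<double> pt_t;
  std::vector<std::vector<double>> pt_p(np), pt_rho(np), pt_u(np), pt_s(np);

  std::vector<double> sn_t, sn_mass, sn_energy;
  std::vector<std::vector<double>> sn_rho, sn_u, sn_p, sn_s;

  std::vector<double> arrival(n, NA_REAL);
  double minT = R_PosInf, minT_t = NA_REAL, minT_x = NA_REAL;
  double maxu = 0.0, maxu_t = NA_REAL, maxu_x = NA_REAL;

  std::vector<Prim> W(n), W1(n);
  std::vector<double> dU(4 * n), U1(4 * n);

  double t = 0.0;
  double next_snap = 0.0;
  long nsteps = 0;

  auto record_probe = [&](double tt) {
    pt_t.push_back(tt);
    for (int k = 0; k < np; ++k) {
      const Prim& w = W[probe_cells[k]];
      pt_p[k].push_back(w.p);
      pt_rho[k].push_back(w.rho);
      pt_u[k].push_back(w.u);
      pt_s[k].push_back(w.s);
    }
  };
  auto record_snap = [&](double tt) {
    sn_t.push_back(tt);
    std::vector<double> r(n), uu(n), pp(n), ss(n);
    double m = 0.0, e = 0.0;
    for (int i = 0; i < n; ++i) {
      r[i] = W[i].rho; uu[i] = W[i].u; pp[i] = W[i].p; ss[i] = W[i].s;
      m += sim.U[4 * i] * sim.vol[i];
      e += sim.U[4 * i + 2] * sim.vol[i];
    }
    sn_rho.push_back(r); sn_u.push_back(uu);
    sn_p.push_back(pp);  sn_s.push_back(ss);
    sn_mass.push_back(m); sn_energy.push_back(e);
  };
  auto track_extremes = [&](double tt) {
    for (int i = 0; i < n; ++i) {
      if (sim.xc[i] < track_x_from) continue;
      if (ISNA(arrival[i]) && W[i].s >= 0.5) arrival[i] = tt;
      if (sim.xc[i] > track_x_to) continue;
      if (tt <= track_t_max) {
        double T = W[i].p / (W[i].rho * R_air);
        if (T < minT) { minT = T; minT_t = tt; minT_x = sim.xc[i]; }
      }
      double au = std::fabs(W[i].u);
      if (au > maxu) { maxu = au; maxu_t = tt; maxu_x = sim.xc[i]; }
    }
  };

  sim.primitives(sim.U, W);
  record_probe(0.0);
  record_snap(0.0);
  next_snap = snap_dt;

  while (t < t_end) {
    // CFL time step
    double dt = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double a = std::sqrt(gamma * W[i].p / W[i].rho);
      double sp = std::fabs(W[i].u) + a;
      double h = (sim.xf[i + 1] - sim.xf[i]) / sp;
      if (h < dt) dt = h;
    }
    dt *= cfl;
    if (t + dt > t_end) dt = t_end - t;

    // SSP-RK2
    sim.rhs(W, sim.ramp(t), dU);
    for (int j = 0; j < 4 * n; ++j) U1[j] = sim.U[j] + dt * dU[j];
    for (int i = 0; i < n; ++i)
      if (U1[4 * i] <= 0.0 ||
          (gamma - 1.0) * (U1[4 * i + 2] -
            0.5 * U1[4 * i + 1] * U1[4 * i + 1] / U1[4 * i]) <= 0.0)
        stop("solver failure: non-physical state in cell %d (x = %g m) "
             "at t = %g s", i + 1, sim.xc[i], t + dt);
    sim.primitives(U1, W1);
    sim.rhs(W1, sim.ramp(t + dt), dU);
    for (int j = 0; j < 4 * n; ++j)
      sim.U[j] = 0.5 * (sim.U[j] + U1[j] + dt * dU[j]);

    t += dt;
    ++nsteps;
    for (int i = 0; i < n; ++i) {
      double rho = sim.U[4 * i];
      double pe = (gamma - 1.0) * (sim.U[4 * i + 2] -
        0.5 * sim.U[4 * i + 1] * sim.U[4 * i + 1] / rho);
      if (!std::isfinite(rho) || !std::isfinite(pe) || rho <= 0.0 || pe <= 0.0)
        stop("solver failure: non-physical state in cell %d (x = %g m) "
             "at t = %g s", i + 1, sim.xc[i], t);
    }
    sim.primitives(sim.U, W);
    record_probe(t);
    track_extremes(t);
    if (t >= next_snap - 1e-15 || t >= t_end) {
      record_snap(t);
      next_snap += snap_dt;
    }
    if (nsteps % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  auto to_mat = [&](std::vector<std::vector<double>>& v, int nrow) {
    NumericMatrix m(nrow, (int)v.size());
    for (size_t j = 0; j < v.size(); ++j)
      std::copy(v[j].begin(), v[j].end(), m.column((int)j).begin());
    return m;
  };

  return List::create(
    _["probe_times"] = NumericVector(pt_t.begin(), pt_t.end()),
    _["probe_p"] = to_mat(pt_p, (int)pt_t.size()),
    _["probe_rho"] = to_mat(pt_rho, (int)pt_t.size()),
    _["probe_u"] = to_mat(pt_u, (int)pt_t.size()),
    _["probe_s"] = to_mat(pt_s, (int)pt_t.size()),
    _["snap_times"] = NumericVector(sn_t.begin(), sn_t.end()),
    _["snap_rho"] = to_mat(sn_rho, n),
    _["snap_u"] = to_mat(sn_u, n),
    _["snap_p"] = to_mat(sn_p, n),
    _["snap_s"] = to_mat(sn_s, n),
    _["mass"] = NumericVector(sn_mass.begin(), sn_mass.end()),
    _["energy"] = NumericVector(sn_energy.begin(), sn_energy.end()),
    _["x_center"] = NumericVector(sim.xc.begin(), sim.xc.end()),
    _["cell_volume"] = NumericVector(sim.vol.begin(), sim.vol.end()),
    _["arrival_time"] = NumericVector(arrival.begin(), arrival.end()),
    _["min_T"] = (minT == R_PosInf) ? NA_REAL : minT,
    _["min_T_time"] = minT_t, _["min_T_x"] = minT_x,
    _["max_speed"] = maxu, _["max_speed_time"] = maxu_t,
    _["max_speed_x"] = maxu_x,
    _["n_steps"] = (double)nsteps);
}
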