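// Self-organized polymer (SOP) model: potential energy, forces, energy
// minimization and overdamped Langevin dynamics with an optional
// constant-velocity pulling spring.
//
// Units: energies kcal/mol, lengths Angstrom, time ps, forces kcal/mol/A.
// The thermal noise uses an internal Mersenne Twister with Box-Muller
// normals so trajectories are bit-reproducible for a given seed on any
// platform.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static const double KB_KCAL = 0.0019872041; // kcal/mol/K

struct Topology {
  int n;
  std::vector<double> bond_r0;          // n-1 consecutive bonds
  std::vector<int> nat_i, nat_j;        // native pairs (0-based)
  std::vector<double> nat_r0;
  std::vector<unsigned char> is_native; // n*n lookup
  double kfene, R0, eh, el, sigma6, sigma13_6;
};

static Topology make_topology(const NumericMatrix& coords,
                              const IntegerVector& nat_i,
                              const IntegerVector& nat_j,
                              const NumericVector& nat_r0,
                              const List& params) {
  Topology top;
  top.n = coords.nrow();
  top.kfene = as<double>(params["k_fene"]);
  top.R0 = as<double>(params["R0_fene"]);
  top.eh = as<double>(params["eh"]);
  top.el = as<double>(params["el"]);
  double s = as<double>(params["sigma"]);
  double s13 = as<double>(params["sigma13"]);
  top.sigma6 = std::pow(s, 6);
  top.sigma13_6 = std::pow(s13, 6);
  NumericVector br = as<NumericVector>(params["bond_r0"]);
  top.bond_r0.assign(br.begin(), br.end());
  top.is_native.assign((size_t)top.n * top.n, 0);
  for (int k = 0; k < nat_i.size(); ++k) {
    int i = nat_i[k] - 1, j = nat_j[k] - 1;
    top.nat_i.push_back(i); top.nat_j.push_back(j);
    top.nat_r0.push_back(nat_r0[k]);
    top.is_native[(size_t)i * top.n + j] = 1;
    top.is_native[(size_t)j * top.n + i] = 1;
  }
  return top;
}

// returns total energy; fills component energies and forces (if not null)
static double energy_forces(const Topology& top, const std::vector<double>& x,
                            double* e_fene, double* e_att, double* e_rep,
                            std::vector<double>* force, int* bad_bond) {
  int n = top.n;
  double Ef = 0, Ea = 0, Er = 0;
  if (force) std::fill(force->begin(), force->end(), 0.0);
  if (bad_bond) *bad_bond = -1;
  // FENE bonds
  for (int i = 0; i < n - 1; ++i) {
    double dx = x[3*(i+1)] - x[3*i];
    double dy = x[3*(i+1)+1] - x[3*i+1];
    double dz = x[3*(i+1)+2] - x[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - top.bond_r0[i];
    double u = 1.0 - dr*dr/(top.R0*top.R0);
    if (u <= 0) { if (bad_bond) { *bad_bond = i + 1; } return R_PosInf; }
    Ef += -0.5 * top.kfene * top.R0 * top.R0 * std::log(u);
    if (force) {
      double fmag = -top.kfene * dr / u; // dV/dr = k*dr/u; force = -dV/dr
      double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
      (*force)[3*(i+1)]   += fx; (*force)[3*(i+1)+1] += fy; (*force)[3*(i+1)+2] += fz;
      (*force)[3*i]       -= fx; (*force)[3*i+1]     -= fy; (*force)[3*i+2]     -= fz;
    }
  }
  // pair terms
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = x[3*j] - x[3*i];
      double dy = x[3*j+1] - x[3*i+1];
      double dz = x[3*j+2] - x[3*i+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      double dVdr = 0;
      if (j == i + 2) {
        double s6 = top.sigma13_6 / (r2*r2*r2);
        Er += top.el * s6;
        dVdr = -6.0 * top.el * s6 / r;
      } else if (top.is_native[(size_t)i * n + j]) {
        // handled in native loop below (need r0); skip here
        continue;
      } else {
        double s6 = top.sigma6 / (r2*r2*r2);
        Er += top.el * s6;
        dVdr = -6.0 * top.el * s6 / r;
      }
      if (force) {
        double fmag = -dVdr;
        double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
        (*force)[3*j]   += fx; (*force)[3*j+1] += fy; (*force)[3*j+2] += fz;
        (*force)[3*i]   -= fx; (*force)[3*i+1] -= fy; (*force)[3*i+2] -= fz;
      }
    }
  }
  // native attractive pairs
  for (size_t k = 0; k < top.nat_i.size(); ++k) {
    int i = top.nat_i[k], j = top.nat_j[k];
    double dx = x[3*j] - x[3*i];
    double dy = x[3*j+1] - x[3*i+1];
    double dz = x[3*j+2] - x[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double q = top.nat_r0[k] / r;
    double q6 = q*q*q*q*q*q;
    Ea += top.eh * (q6*q6 - 2.0*q6);
    double dVdr = -12.0 * top.eh * (q6*q6 - q6) / r;
    if (force) {
      double fmag = -dVdr;
      double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
      (*force)[3*j]   += fx; (*force)[3*j+1] += fy; (*force)[3*j+2] += fz;
      (*force)[3*i]   -= fx; (*force)[3*i+1] -= fy; (*force)[3*i+2] -= fz;
    }
  }
  if (e_fene) *e_fene = Ef;
  if (e_att)  *e_att = Ea;
  if (e_rep)  *e_rep = Er;
  return Ef + Ea + Er;
}

// [[Rcpp::export(name = ".sop_energy")]]
List sop_energy_cpp(NumericMatrix coords, IntegerVector nat_i,
                    IntegerVector nat_j, NumericVector nat_r0, List params,
                    bool forces = false) {
  Topology top = make_topology(coords, nat_i, nat_j, nat_r0, params);
  std::vector<double> x(3 * top.n);
  for (int i = 0; i < top.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);
  double Ef, Ea, Er;
  std::vector<double> f;
  int bad = -1;
  if (forces) f.resize(3 * top.n);
  double Et = energy_forces(top, x, &Ef, &Ea, &Er, forces ? &f : nullptr, &bad);
  if (!R_finite(Et))
    stop("bond %d exceeded the FENE tolerance (infinite energy)", bad);
  List out = List::create(_["V_total"] = Et, _["V_fene"] = Ef,
                          _["V_att"] = Ea, _["V_rep"] = Er);
  if (forces) {
    NumericMatrix fm(top.n, 3);
    for (int i = 0; i < top.n; ++i)
      for (int d = 0; d < 3; ++d) fm(i, d) = f[3*i+d];
    out["forces"] = fm;
  }
  return out;
}

// [[Rcpp::export(name = ".sop_minimize")]]
NumericMatrix sop_minimize_cpp(NumericMatrix coords, IntegerVector nat_i,
                               IntegerVector nat_j, NumericVector nat_r0,
                               List params, int max_steps = 20000,
                               double ftol = 1e-8, double step0 = 1e-3) {
  Topology top = make_topology(coords, nat_i, nat_j, nat_r0, params);
  int n = top.n;
  std::vector<double> x(3 * n), f(3 * n), xn(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);
  double step = step0;
  double E = energy_forces(top, x, nullptr, nullptr, nullptr, nullptr, nullptr);
  for (int it = 0; it < max_steps; ++it) {
    energy_forces(top, x, nullptr, nullptr, nullptr, &f, nullptr);
    double fmax = 0;
    for (double v : f) fmax = std::max(fmax, std::fabs(v));
    if (fmax < ftol) break;
    // steepest descent with backtracking
    for (;;) {
      for (size_t k = 0; k < x.size(); ++k) {
        double dx = step * f[k];
        if (dx > 0.2) dx = 0.2; else if (dx < -0.2) dx = -0.2;
        xn[k] = x[k] + dx;
      }
      double En = energy_forces(top, xn, nullptr, nullptr, nullptr, nullptr, nullptr);
      if (R_finite(En) && En <= E) { x = xn; E = En; step *= 1.2; break; }
      step *= 0.5;
      if (step < 1e-12) break;
    }
    if (step < 1e-12) break;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3*i+d];
  return out;
}

// [[Rcpp::export(name = ".sop_run")]]
List sop_run_cpp(NumericMatrix coords, IntegerVector nat_i,
                 IntegerVector nat_j, NumericVector nat_r0, List params,
                 List sim) {
  Topology top = make_topology(coords, nat_i, nat_j, nat_r0, params);
  int n = top.n;
  long nsteps = (long)as<double>(sim["n_steps"]);
  double dt = as<double>(sim["dt"]);
  double zeta = as<double>(sim["zeta"]);
  double temperature = as<double>(sim["temperature"]);
  unsigned int seed = (unsigned int)as<double>(sim["seed"]);
  int stride_sample = as<int>(sim["stride_sample"]);
  int stride_frames = as<int>(sim["stride_frames"]); // 0 = no frames
  bool pull = as<bool>(sim["pull"]);
  double ks = 0, speed = 0;
  int fixed_bead = -1, pulled_bead = -1;
  std::vector<double> axis(3, 0.0);
  if (pull) {
    ks = as<double>(sim["k_spring"]);          // kcal/mol/A^2
    speed = as<double>(sim["speed"]);          // A/ps
    fixed_bead = as<int>(sim["fixed_bead"]) - 1;
    pulled_bead = as<int>(sim["pulled_bead"]) - 1;
    NumericVector ax = as<NumericVector>(sim["axis"]);
    double norm = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
    for (int d = 0; d < 3; ++d) axis[d] = ax[d] / norm;
  }

  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  bool have_spare = false; double spare = 0;
  auto rnorm1 = [&]() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 1.0 - unif(rng), u2 = unif(rng);
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  };

  double mob = dt / zeta;
  double noise_amp = std::sqrt(2.0 * KB_KCAL * temperature * dt / zeta);
  double anchor0 = 0;
  if (pull)
    anchor0 = x[3*pulled_bead]*axis[0] + x[3*pulled_bead+1]*axis[1] +
              x[3*pulled_bead+2]*axis[2];

  long n_samp = nsteps / std::max(stride_sample, 1) + 1;
  std::vector<double> samp_t, samp_force, samp_e2e;
  samp_t.reserve(n_samp); samp_force.reserve(n_samp); samp_e2e.reserve(n_samp);
  List frames;
  if (stride_frames > 0) frames = List(nsteps / stride_frames + 1);
  int frame_count = 0;

  auto record = [&](long step) {
    double t = step * dt;
    double fc = 0;
    if (pull) {
      double proj = x[3*pulled_bead]*axis[0] + x[3*pulled_bead+1]*axis[1] +
                    x[3*pulled_bead+2]*axis[2];
      fc = ks * (anchor0 + speed * t - proj);
    }
    double e2e = 0;
    {
      int i0 = pull ? fixed_bead : 0, i1 = pull ? pulled_bead : n - 1;
      double dx = x[3*i1]-x[3*i0], dy = x[3*i1+1]-x[3*i0+1], dz = x[3*i1+2]-x[3*i0+2];
      e2e = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
    samp_t.push_back(t); samp_force.push_back(fc); samp_e2e.push_back(e2e);
  };
  auto snap = [&](long step) {
    if (stride_frames <= 0) return;
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fr(i, d) = x[3*i+d];
    frames[frame_count++] = fr;
  };

  record(0); snap(0);
  int bad = -1;
  for (long step = 1; step <= nsteps; ++step) {
    double Et = energy_forces(top, x, nullptr, nullptr, nullptr, &f, &bad);
    if (!R_finite(Et))
      stop("integrator blow-up at step %ld: bond %d exceeded the FENE "
           "tolerance; reduce dt or pulling speed", step, bad);
    double t = step * dt;
    if (pull) {
      double proj = x[3*pulled_bead]*axis[0] + x[3*pulled_bead+1]*axis[1] +
                    x[3*pulled_bead+2]*axis[2];
      double fs = ks * (anchor0 + speed * t - proj);
      for (int d = 0; d < 3; ++d) f[3*pulled_bead+d] += fs * axis[d];
    }
    for (int i = 0; i < n; ++i) {
      if (pull && i == fixed_bead) continue;
      for (int d = 0; d < 3; ++d) {
        double disp = mob * f[3*i+d];
        if (temperature > 0) disp += noise_amp * rnorm1();
        if (std::fabs(disp) > 2.0)
          stop("integrator blow-up at step %ld: bead %d moved %.2f A in one "
               "step; reduce dt", step, i + 1, std::fabs(disp));
        x[3*i+d] += disp;
      }
    }
    if (step % stride_sample == 0) record(step);
    if (stride_frames > 0 && step % stride_frames == 0) snap(step);
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) final_coords(i, d) = x[3*i+d];
  List out = List::create(
    _["time_ps"] = NumericVector(samp_t.begin(), samp_t.end()),
    _["force_kcal"] = NumericVector(samp_force.begin(), samp_force.end()),
    _["e2e_A"] = NumericVector(samp_e2e.begin(), samp_e2e.end()),
    _["final"] = final_coords);
  if (stride_frames > 0) {
    List fr(frame_count);
    for (int i = 0; i < frame_count; ++i) fr[i] = frames[i];
    out["frames"] = fr;
  }
  return out;
}
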