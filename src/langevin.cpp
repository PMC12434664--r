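// Coarse-grained Langevin engine: structure-based (Go-like) potential with
// harmonic bonds/angles, Gaussian native-contact wells over a purely
// repulsive (WCA-style) core, Debye-Hueckel electrostatics over charged
// sites, and explicit divalent point-charge ions in a periodic box. The RNA
// chain is kept whole (no wrapping); ions are wrapped and interact through
// the minimum-image convention. BAOAB Langevin integration. The RNG is an
// in-file mt19937_64 + Box-Muller pair so trajectories are bit-identical
// for a given seed regardless of the compiler's distribution
// implementations.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {  // in (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Box-Muller, explicit for cross-compiler determinism
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct Model {
  int nb = 0, ni = 0;
  std::vector<int> bond_i, bond_j;
  std::vector<double> bond_r0;
  double k_bond = 0.0;
  std::vector<int> ang_i, ang_j, ang_k;
  std::vector<double> ang_th0;
  double k_angle = 0.0;
  std::vector<int> con_i, con_j;
  std::vector<double> con_r0, con_eps, con_sig, con_w;
  std::vector<double> ev_sigma;      // nb*nb, 0 => skip pair
  std::vector<double> charge;        // per bead
  std::vector<double> bead_radius;   // per bead
  double ion_charge = 2.0, ion_radius = 3.5, ev_eps = 1.0;
  double k_e = 7.1, debye = 10.0, dh_cut = 40.0;
  double box = 0.0;                  // <=0 disables PBC
  // umbrella bias on smoothed Q over the contact list
  double k_q = 0.0, q0 = 0.0, qbeta = 5.0, qlambda = 1.2;
};

inline double wrap_d(double d, double box) {
  if (box > 0.0) d -= box * std::nearbyint(d / box);
  return d;
}

inline void wca(double r, double sigma, double ev_eps, double& V,
                double& dVdr) {
  if (r >= sigma || sigma <= 0.0) return;
  double sr = sigma / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  V += ev_eps * (sr6 * sr6 - 2.0 * sr6 + 1.0);
  dVdr += -12.0 * ev_eps * (sr6 * sr6 - sr6) / r;
}

inline void debye(double r, double qq, const Model& m, double& V,
                  double& dVdr) {
  if (qq == 0.0 || r >= m.dh_cut) return;
  double e = m.k_e * qq * std::exp(-r / m.debye) / r;
  V += e;
  dVdr += -e * (1.0 / m.debye + 1.0 / r);
}

Model build_model(const List& par) {
  Model m;
  IntegerMatrix bonds = par["bonds"];
  NumericVector bond_r0 = par["bond_r0"];
  IntegerMatrix angles = par["angles"];
  NumericVector ang_th0 = par["angle_theta0"];
  IntegerMatrix contacts = par["contacts"];
  NumericVector con_r0 = par["contact_r0"], con_eps = par["contact_eps"],
                con_sig = par["contact_sigma"], con_w = par["contact_width"];
  NumericMatrix ev = par["ev_sigma"];
  NumericVector charge = par["charge"], brad = par["bead_radius"];
  m.nb = ev.nrow();
  m.k_bond = as<double>(par["k_bond"]);
  m.k_angle = as<double>(par["k_angle"]);
  m.ev_eps = as<double>(par["ev_eps"]);
  m.ion_charge = as<double>(par["ion_charge"]);
  m.ion_radius = as<double>(par["ion_radius"]);
  m.k_e = as<double>(par["coulomb_k"]);
  m.debye = as<double>(par["debye_length"]);
  m.dh_cut = as<double>(par["dh_cutoff"]);
  m.box = as<double>(par["box_edge"]);
  for (int b = 0; b < bonds.nrow(); ++b) {
    m.bond_i.push_back(bonds(b, 0)); m.bond_j.push_back(bonds(b, 1));
    m.bond_r0.push_back(bond_r0[b]);
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    m.ang_i.push_back(angles(a, 0)); m.ang_j.push_back(angles(a, 1));
    m.ang_k.push_back(angles(a, 2)); m.ang_th0.push_back(ang_th0[a]);
  }
  for (int c = 0; c < contacts.nrow(); ++c) {
    m.con_i.push_back(contacts(c, 0)); m.con_j.push_back(contacts(c, 1));
    m.con_r0.push_back(con_r0[c]); m.con_eps.push_back(con_eps[c]);
    m.con_sig.push_back(con_sig[c]); m.con_w.push_back(con_w[c]);
  }
  m.ev_sigma.assign(ev.begin(), ev.end());
  m.charge.assign(charge.begin(), charge.end());
  m.bead_radius.assign(brad.begin(), brad.end());
  if (par.containsElementNamed("k_q")) {
    m.k_q = as<double>(par["k_q"]);
    m.q0 = as<double>(par["q0"]);
    m.qbeta = as<double>(par["qbeta"]);
    m.qlambda = as<double>(par["qlambda"]);
  }
  return m;
}

// Potential energy and forces. x: beads then ions, flat [n][3].
// Returns total energy; fills forces and (optionally) per-term energies and
// the smoothed Q.
double eval_forces(const Model& m, const std::vector<double>& x,
                   std::vector<double>& f, double* terms, double* q_out) {
  const int nb = m.nb, ni = m.ni, n = nb + ni;
  std::fill(f.begin(), f.end(), 0.0);
  double Vb = 0, Va = 0, Vc = 0, Vev = 0, Vdh = 0, Vbias = 0;

  // bonds
  for (size_t b = 0; b < m.bond_i.size(); ++b) {
    int i = m.bond_i[b], j = m.bond_j[b];
    double d[3], r2 = 0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
    double r = std::sqrt(r2);
    double dr = r - m.bond_r0[b];
    Vb += m.k_bond * dr * dr;
    double c = -2.0 * m.k_bond * dr / r;
    for (int k = 0; k < 3; ++k) { f[3*i+k] += c * d[k]; f[3*j+k] -= c * d[k]; }
  }
  // angles (j is the vertex)
  for (size_t a = 0; a < m.ang_i.size(); ++a) {
    int i = m.ang_i[a], j = m.ang_j[a], k2 = m.ang_k[a];
    double u[3], v[3], lu2 = 0, lv2 = 0, uv = 0;
    for (int k = 0; k < 3; ++k) {
      u[k] = x[3*i+k] - x[3*j+k];
      v[k] = x[3*k2+k] - x[3*j+k];
      lu2 += u[k]*u[k]; lv2 += v[k]*v[k]; uv += u[k]*v[k];
    }
    double lu = std::sqrt(lu2), lv = std::sqrt(lv2);
    double ct = uv / (lu * lv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    double dth = th - m.ang_th0[a];
    Va += m.k_angle * dth * dth;
    double pref = 2.0 * m.k_angle * dth / st;  // -dV/dcos(theta)
    for (int k = 0; k < 3; ++k) {
      double dci = (v[k] / (lu * lv)) - ct * u[k] / lu2;
      double dck = (u[k] / (lu * lv)) - ct * v[k] / lv2;
      f[3*i+k]  += pref * dci;
      f[3*k2+k] += pref * dck;
      f[3*j+k]  -= pref * (dci + dck);
    }
  }
  // native contacts: WCA core + Gaussian well, optionally the Q bias
  const size_t nc = m.con_i.size();
  std::vector<double> con_r(nc), con_fq(nc);
  double q_smooth = 0.0;
  for (size_t c = 0; c < nc; ++c) {
    int i = m.con_i[c], j = m.con_j[c];
    double d[3], r2 = 0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
    double r = std::sqrt(r2);
    con_r[c] = r;
    double V = 0, dVdr = 0;
    wca(r, m.con_sig[c], m.ev_eps, V, dVdr);
    double dr = r - m.con_r0[c];
    double w2 = m.con_w[c] * m.con_w[c];
    double g = std::exp(-dr * dr / (2.0 * w2));
    V += -m.con_eps[c] * g;
    dVdr += m.con_eps[c] * g * dr / w2;
    Vc += V;
    {
      double e = std::exp(m.qbeta * (r - m.qlambda * m.con_r0[c]));
      double fq = 1.0 / (1.0 + e);
      con_fq[c] = fq;
      q_smooth += fq;
    }
    double cc = -dVdr / r;
    for (int k = 0; k < 3; ++k) { f[3*i+k] += cc * d[k]; f[3*j+k] -= cc * d[k]; }
  }
  if (nc > 0) q_smooth /= (double)nc;
  if (m.k_q > 0.0 && nc > 0) {
    Vbias = 0.5 * m.k_q * (q_smooth - m.q0) * (q_smooth - m.q0);
    double dVdq = m.k_q * (q_smooth - m.q0);
    for (size_t c = 0; c < nc; ++c) {
      int i = m.con_i[c], j = m.con_j[c];
      double dfdr = -m.qbeta * con_fq[c] * (1.0 - con_fq[c]);
      double dVdr = dVdq * dfdr / (double)nc;
      double r = con_r[c];
      double cc = -dVdr / r;
      for (int k = 0; k < 3; ++k) {
        double d = x[3*i+k] - x[3*j+k];
        f[3*i+k] += cc * d; f[3*j+k] -= cc * d;
      }
    }
  }
  // RNA-RNA nonbonded (no PBC: the chain stays whole and the box is large)
  for (int i = 0; i < nb; ++i) {
    for (int j = i + 1; j < nb; ++j) {
      double sig = m.ev_sigma[i + (size_t)nb * j];
      double qq = m.charge[i] * m.charge[j];
      if (sig <= 0.0 && qq == 0.0) continue;
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
      double r = std::sqrt(r2);
      double V = 0, dVdr = 0;
      if (sig > 0.0) wca(r, sig, m.ev_eps, V, dVdr);
      double Ve = 0, dVe = 0;
      debye(r, qq, m, Ve, dVe);
      Vev += V; Vdh += Ve;
      double cc = -(dVdr + dVe) / r;
      if (cc != 0.0)
        for (int k = 0; k < 3; ++k) { f[3*i+k] += cc * d[k]; f[3*j+k] -= cc * d[k]; }
    }
  }
  // RNA-ion and ion-ion (minimum image)
  for (int a = 0; a < ni; ++a) {
    int ia = nb + a;
    for (int i = 0; i < nb; ++i) {
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = wrap_d(x[3*i+k] - x[3*ia+k], m.box); r2 += d[k]*d[k];
      }
      double r = std::sqrt(r2);
      double V = 0, dVdr = 0;
      wca(r, m.bead_radius[i] + m.ion_radius, m.ev_eps, V, dVdr);
      double Ve = 0, dVe = 0;
      debye(r, m.charge[i] * m.ion_charge, m, Ve, dVe);
      Vev += V; Vdh += Ve;
      double cc = -(dVdr + dVe) / r;
      if (cc != 0.0)
        for (int k = 0; k < 3; ++k) { f[3*i+k] += cc * d[k]; f[3*ia+k] -= cc * d[k]; }
    }
    for (int b = a + 1; b < ni; ++b) {
      int ib = nb + b;
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = wrap_d(x[3*ia+k] - x[3*ib+k], m.box); r2 += d[k]*d[k];
      }
      double r = std::sqrt(r2);
      double V = 0, dVdr = 0;
      wca(r, 2.0 * m.ion_radius, m.ev_eps, V, dVdr);
      double Ve = 0, dVe = 0;
      debye(r, m.ion_charge * m.ion_charge, m, Ve, dVe);
      Vev += V; Vdh += Ve;
      double cc = -(dVdr + dVe) / r;
      if (cc != 0.0)
        for (int k = 0; k < 3; ++k) { f[3*ia+k] += cc * d[k]; f[3*ib+k] -= cc * d[k]; }
    }
  }
  if (terms) {
    terms[0] = Vb; terms[1] = Va; terms[2] = Vc; terms[3] = Vev;
    terms[4] = Vdh; terms[5] = Vbias;
  }
  if (q_out) *q_out = q_smooth;
  return Vb + Va + Vc + Vev + Vdh + Vbias;
}

}  // namespace

// [[Rcpp::export(name = ".fs_energy")]]
List fs_energy_cpp(NumericMatrix xyz, NumericMatrix ions, List par) {
  Model m = build_model(par);
  m.ni = ions.nrow();
  if (xyz.nrow() != m.nb) stop("coordinate/topology bead count mismatch");
  int n = m.nb + m.ni;
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < m.nb; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = xyz(i, k);
  for (int a = 0; a < m.ni; ++a)
    for (int k = 0; k < 3; ++k) x[3*(m.nb+a)+k] = ions(a, k);
  double terms[6];
  double q = 0;
  double tot = eval_forces(m, x, f, terms, &q);
  NumericMatrix force(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) force(i, k) = f[3*i+k];
  return List::create(
      _["total"] = tot, _["bond"] = terms[0], _["angle"] = terms[1],
      _["contact"] = terms[2], _["excluded_volume"] = terms[3],
      _["electrostatic"] = terms[4], _["bias"] = terms[5],
      _["q_smooth"] = q, _["forces"] = force);
}

// [[Rcpp::export(name = ".fs_run_langevin")]]
List fs_run_langevin_cpp(NumericMatrix xyz, NumericMatrix ions, List par,
                         List cfg) {
  Model m = build_model(par);
  m.ni = ions.nrow();
  if (xyz.nrow() != m.nb) stop("coordinate/topology bead count mismatch");
  const int n = m.nb + m.ni;
  const double dt = as<double>(cfg["timestep"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const int save_int = as<int>(cfg["save_interval"]);
  const double T = as<double>(cfg["temperature"]);
  const double gamma = as<double>(cfg["friction"]);
  const double mass = as<double>(cfg["mass"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  Rng rng(seed);

  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < m.nb; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = xyz(i, k);
  for (int a = 0; a < m.ni; ++a)
    for (int k = 0; k < 3; ++k) x[3*(m.nb+a)+k] = ions(a, k);
  if (cfg.containsElementNamed("velocities") &&
      !Rf_isNull(cfg["velocities"])) {
    NumericMatrix v0 = cfg["velocities"];
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i+k] = v0(i, k);
  } else if (T > 0.0) {
    double s = std::sqrt(T / mass);
    for (int i = 0; i < 3 * n; ++i) v[i] = s * rng.norm();
  }

  const double c1 = std::exp(-gamma * dt);
  const double c2 = (T > 0.0) ? std::sqrt((1.0 - c1 * c1) * T / mass) : 0.0;

  const int nf = n_steps / save_int;
  NumericVector rna_out((R_xlen_t)nf * m.nb * 3);
  NumericVector ion_out((R_xlen_t)nf * std::max(m.ni, 0) * 3);
  NumericVector q_out(nf), bias_out(nf), e_out(nf);
  IntegerVector step_out(nf);

  double terms[6]; double qs = 0;
  eval_forces(m, x, f, terms, &qs);
  int fi = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) {
      v[i] += 0.5 * dt * f[i] / mass;
      x[i] += 0.5 * dt * v[i];
    }
    if (c2 > 0.0 || c1 != 1.0)
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * rng.norm();
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // wrap ions into the box; the RNA is never wrapped
    if (m.box > 0.0)
      for (int a = 0; a < m.ni; ++a)
        for (int k = 0; k < 3; ++k) {
          double& xx = x[3*(m.nb+a)+k];
          xx -= m.box * std::floor(xx / m.box + 0.5);
        }
    double tot = eval_forces(m, x, f, terms, &qs);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] / mass;
    if (!std::isfinite(tot))
      stop("non-finite energy/forces at step %d", step);
    if (step % save_int == 0) {
      for (int i = 0; i < m.nb; ++i)
        for (int k = 0; k < 3; ++k)
          rna_out[fi + (R_xlen_t)nf * (i + (R_xlen_t)m.nb * k)] = x[3*i+k];
      for (int a = 0; a < m.ni; ++a)
        for (int k = 0; k < 3; ++k)
          ion_out[fi + (R_xlen_t)nf * (a + (R_xlen_t)m.ni * k)] =
              x[3*(m.nb+a)+k];
      q_out[fi] = qs;
      bias_out[fi] = terms[5];
      e_out[fi] = tot;
      step_out[fi] = step;
      ++fi;
    }
  }
  rna_out.attr("dim") = IntegerVector::create(nf, m.nb, 3);
  if (m.ni > 0) ion_out.attr("dim") = IntegerVector::create(nf, m.ni, 3);
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { xf(i, k) = x[3*i+k]; vf(i, k) = v[3*i+k]; }
  return List::create(
      _["rna"] = rna_out, _["ions"] = ion_out, _["q_smooth"] = q_out,
      _["bias_energy"] = bias_out, _["energy"] = e_out,
      _["steps"] = step_out, _["final_x"] = xf, _["final_v"] = vf);
}
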