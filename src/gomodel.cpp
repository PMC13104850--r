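#include <Rcpp.h>
#include <random>
#include <unordered_set>
using namespace Rcpp;

// Calpha structure-based (Go-type) force field and Langevin dynamics.
// Units: kcal/mol, Angstrom, g/mol; internal time unit
// t0 = sqrt(g/mol * A^2 / (kcal/mol)) = 48.8882 fs (AKMA convention).
// kB = 1.9872041e-3 kcal/mol/K.

static const double KB = 1.9872041e-3;
static const double T0_FS = 48.8882129;

struct GoParams {
  int n;
  // bonds: i, j (0-based), r0, k
  std::vector<int> bi, bj; std::vector<double> br0, bk;
  // angles: i, j, k
  std::vector<int> ai, aj, ak; std::vector<double> ath0, aka;
  // dihedrals: i j k l
  std::vector<int> di, dj, dk, dl; std::vector<double> dphi0, dk1, dk3;
  // native pairs
  std::vector<int> pi_, pj_; std::vector<double> pr0, peps;
  // repulsion
  double rep_eps, rep_sigma;
  int rep_min_sep;
  std::unordered_set<long long> native_set;
  // precomputed non-native pair list for the excluded-volume term
  std::vector<int> ri, rj;
};

static GoParams unpack(const List& model) {
  GoParams P;
  P.n = as<int>(model["n"]);
  NumericMatrix B = model["bonds"], A = model["angles"], D = model["dihedrals"],
                NP = model["pairs"];
  for (int r = 0; r < B.nrow(); ++r) {
    P.bi.push_back((int)B(r, 0) - 1); P.bj.push_back((int)B(r, 1) - 1);
    P.br0.push_back(B(r, 2)); P.bk.push_back(B(r, 3));
  }
  for (int r = 0; r < A.nrow(); ++r) {
    P.ai.push_back((int)A(r, 0) - 1); P.aj.push_back((int)A(r, 1) - 1);
    P.ak.push_back((int)A(r, 2) - 1);
    P.ath0.push_back(A(r, 3)); P.aka.push_back(A(r, 4));
  }
  for (int r = 0; r < D.nrow(); ++r) {
    P.di.push_back((int)D(r, 0) - 1); P.dj.push_back((int)D(r, 1) - 1);
    P.dk.push_back((int)D(r, 2) - 1); P.dl.push_back((int)D(r, 3) - 1);
    P.dphi0.push_back(D(r, 4)); P.dk1.push_back(D(r, 5)); P.dk3.push_back(D(r, 6));
  }
  for (int r = 0; r < NP.nrow(); ++r) {
    int i = (int)NP(r, 0) - 1, j = (int)NP(r, 1) - 1;
    P.pi_.push_back(i); P.pj_.push_back(j);
    P.pr0.push_back(NP(r, 2)); P.peps.push_back(NP(r, 3));
    P.native_set.insert((long long)i * P.n + j);
  }
  P.rep_eps = as<double>(model["rep_eps"]);
  P.rep_sigma = as<double>(model["rep_sigma"]);
  P.rep_min_sep = as<int>(model["rep_min_sep"]);
  for (int i = 0; i < P.n; ++i)
    for (int j = i + P.rep_min_sep + 1; j < P.n; ++j)
      if (!P.native_set.count((long long)i * P.n + j)) {
        P.ri.push_back(i);
        P.rj.push_back(j);
      }
  return P;
}

static inline void sub3(const double* x, int a, int b, double* d) {
  d[0] = x[3 * a] - x[3 * b];
  d[1] = x[3 * a + 1] - x[3 * b + 1];
  d[2] = x[3 * a + 2] - x[3 * b + 2];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// forces accumulated into f (length 3n, zeroed by caller); returns potential
static double go_force(const GoParams& P, const double* x, double* f) {
  double E = 0.0;
  double d[3];
  // bonds
  for (size_t b = 0; b < P.bi.size(); ++b) {
    sub3(x, P.bi[b], P.bj[b], d);
    const double r = std::sqrt(dot3(d, d));
    const double dr = r - P.br0[b];
    E += P.bk[b] * dr * dr;
    const double fac = -2.0 * P.bk[b] * dr / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * P.bi[b] + k] += fac * d[k];
      f[3 * P.bj[b] + k] -= fac * d[k];
    }
  }
  // angles (harmonic in theta)
  for (size_t a = 0; a < P.ai.size(); ++a) {
    double rij[3], rkj[3];
    sub3(x, P.ai[a], P.aj[a], rij);
    sub3(x, P.ak[a], P.aj[a], rkj);
    const double lij = std::sqrt(dot3(rij, rij)), lkj = std::sqrt(dot3(rkj, rkj));
    double c = dot3(rij, rkj) / (lij * lkj);
    c = std::max(-1.0, std::min(1.0, c));
    const double th = std::acos(c);
    const double dth = th - P.ath0[a];
    E += P.aka[a] * dth * dth;
    const double s = std::sqrt(std::max(1e-8, 1.0 - c * c));
    const double dEdth = 2.0 * P.aka[a] * dth;
    // dtheta/dri etc.
    for (int k = 0; k < 3; ++k) {
      const double di_ = (c * rij[k] / lij - rkj[k] / lkj) / (lij * s);
      const double dk_ = (c * rkj[k] / lkj - rij[k] / lij) / (lkj * s);
      f[3 * P.ai[a] + k] += -dEdth * di_;
      f[3 * P.ak[a] + k] += -dEdth * dk_;
      f[3 * P.aj[a] + k] += dEdth * (di_ + dk_);
    }
  }
  // dihedrals: V = k1*(1 - cos(phi - phi0)) + k3*(1 - cos(3(phi - phi0)))
  for (size_t t = 0; t < P.di.size(); ++t) {
    double b1[3], b2[3], b3[3];
    sub3(x, P.dj[t], P.di[t], b1);
    sub3(x, P.dk[t], P.dj[t], b2);
    sub3(x, P.dl[t], P.dk[t], b3);
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    const double l2 = std::sqrt(dot3(b2, b2));
    double m1[3];
    cross3(n1, b2, m1);
    const double xc = dot3(n1, n2);
    const double yc = dot3(m1, n2) / l2;
    const double phi = std::atan2(yc, xc);
    const double dphi = phi - P.dphi0[t];
    E += P.dk1[t] * (1.0 - std::cos(dphi)) + P.dk3[t] * (1.0 - std::cos(3.0 * dphi));
    const double dEdphi = P.dk1[t] * std::sin(dphi) + 3.0 * P.dk3[t] * std::sin(3.0 * dphi);
    const double n1n = dot3(n1, n1), n2n = dot3(n2, n2);
    if (n1n < 1e-10 || n2n < 1e-10) continue;
    // dphi/dr_i = (|b2|/|n1|^2) n1, dphi/dr_l = -(|b2|/|n2|^2) n2,
    // dphi/dr_j = -(1+s12) dphi/dr_i + s32 dphi/dr_l (and symmetrically for k)
    double fi[3], fl[3];
    for (int k = 0; k < 3; ++k) {
      fi[k] = -dEdphi * l2 * n1[k] / n1n;
      fl[k] = dEdphi * l2 * n2[k] / n2n;
    }
    const double s12 = dot3(b1, b2) / (l2 * l2), s32 = dot3(b3, b2) / (l2 * l2);
    for (int k = 0; k < 3; ++k) {
      const double fj = -(1.0 + s12) * fi[k] + s32 * fl[k];
      const double fk = s12 * fi[k] - (1.0 + s32) * fl[k];
      f[3 * P.di[t] + k] += fi[k];
      f[3 * P.dj[t] + k] += fj;
      f[3 * P.dk[t] + k] += fk;
      f[3 * P.dl[t] + k] += fl[k];
    }
  }
  // native 12-10 pairs
  for (size_t p = 0; p < P.pi_.size(); ++p) {
    sub3(x, P.pi_[p], P.pj_[p], d);
    const double r2 = dot3(d, d);
    const double r = std::sqrt(r2);
    const double q = P.pr0[p] / r;
    const double q2 = q * q;
    const double q10 = q2 * q2 * q2 * q2 * q2;
    const double q12 = q10 * q2;
    E += P.peps[p] * (5.0 * q12 - 6.0 * q10);
    const double fac = 60.0 * P.peps[p] * (q12 - q10) / r2;  // -dV/dr / r
    for (int k = 0; k < 3; ++k) {
      f[3 * P.pi_[p] + k] += fac * d[k];
      f[3 * P.pj_[p] + k] -= fac * d[k];
    }
  }
  // non-native excluded volume: eps*(sigma/r)^12, cutoff 2.5 sigma
  const double cut2 = 6.25 * P.rep_sigma * P.rep_sigma;
  for (size_t q = 0; q < P.ri.size(); ++q) {
    const int i = P.ri[q], j = P.rj[q];
    sub3(x, i, j, d);
    const double r2 = dot3(d, d);
    if (r2 > cut2) continue;
    const double s2 = P.rep_sigma * P.rep_sigma / r2;
    const double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    E += P.rep_eps * s12;
    const double fac = 12.0 * P.rep_eps * s12 / r2;
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += fac * d[k];
      f[3 * j + k] -= fac * d[k];
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_go_energy(List model, NumericMatrix coords) {
  GoParams P = unpack(model);
  std::vector<double> x(3 * P.n), f(3 * P.n, 0.0);
  for (int i = 0; i < P.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  const double E = go_force(P, x.data(), f.data());
  NumericMatrix F(P.n, 3);
  for (int i = 0; i < P.n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3 * i + k];
  return List::create(_["energy"] = E, _["forces"] = F);
}

// steepest descent with adaptive step, used for the native-minimum check
// [[Rcpp::export]]
NumericMatrix cpp_go_minimize(List model, NumericMatrix coords, int nsteps,
                              double step0) {
  GoParams P = unpack(model);
  std::vector<double> x(3 * P.n), f(3 * P.n), xt(3 * P.n), ft(3 * P.n);
  for (int i = 0; i < P.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double step = step0;
  std::fill(f.begin(), f.end(), 0.0);
  double E = go_force(P, x.data(), f.data());
  for (int s = 0; s < nsteps; ++s) {
    double fmax = 0.0;
    for (double v : f) fmax = std::max(fmax, std::fabs(v));
    if (fmax < 1e-10) break;
    for (int q = 0; q < 3 * P.n; ++q) xt[q] = x[q] + step * f[q] / fmax;
    std::fill(ft.begin(), ft.end(), 0.0);
    const double Et = go_force(P, xt.data(), ft.data());
    if (Et < E) {
      x = xt; f = ft; E = Et; step *= 1.2;
    } else {
      step *= 0.5;
    }
    if (step < 1e-8) break;
  }
  NumericMatrix out(P.n, 3);
  for (int i = 0; i < P.n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return out;
}

// Langevin (BAOAB) dynamics; gamma_ps = 0 gives NVE velocity Verlet.
// Returns saved frames (nsave x 3n), kinetic temperatures and total energies
// at the save stride, and final coordinates/velocities.
// [[Rcpp::export]]
List cpp_run_langevin(List model, NumericMatrix coords, int nsteps,
                      double dt_fs, double gamma_ps, double temp_K,
                      double mass, int seed, int save_stride,
                      Nullable<NumericMatrix> vel0 = R_NilValue) {
  GoParams P = unpack(model);
  const int n = P.n;
  const double dt = dt_fs / T0_FS;
  const double gamma = gamma_ps * T0_FS / 1000.0;  // per t0
  const double kT = KB * temp_K;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  bool have_spare = false;
  double spare = 0.0;
  auto gauss = [&]() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(rng), u2 = unif(rng);
    while (u1 <= 1e-300) u1 = unif(rng);
    const double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  };

  if (vel0.isNotNull()) {
    NumericMatrix V(vel0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] = V(i, k);
  } else {
    const double sd = std::sqrt(kT / mass);
    for (int q = 0; q < 3 * n; ++q) v[q] = sd * gauss();
  }

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(kT / mass);
  double Epot = go_force(P, x.data(), f.data());

  const int nsave = save_stride > 0 ? nsteps / save_stride : 0;
  NumericMatrix frames(nsave > 0 ? nsave : 0, 3 * n);
  NumericVector temps(nsave > 0 ? nsave : 0), etot(nsave > 0 ? nsave : 0);
  int isave = 0;

  for (int s = 0; s < nsteps; ++s) {
    for (int q = 0; q < 3 * n; ++q) v[q] += 0.5 * dt * f[q] / mass;      // B
    for (int q = 0; q < 3 * n; ++q) x[q] += 0.5 * dt * v[q];             // A
    if (gamma > 0)
      for (int q = 0; q < 3 * n; ++q) v[q] = c1 * v[q] + c2 * gauss();   // O
    // kinetic measurements use the mid-step velocities, where the BAOAB
    // ("middle") scheme's kinetic temperature is unbiased in dt
    double ke = 0.0;
    for (int q = 0; q < 3 * n; ++q) ke += 0.5 * mass * v[q] * v[q];
    for (int q = 0; q < 3 * n; ++q) x[q] += 0.5 * dt * v[q];             // A
    std::fill(f.begin(), f.end(), 0.0);
    Epot = go_force(P, x.data(), f.data());
    for (int q = 0; q < 3 * n; ++q) v[q] += 0.5 * dt * f[q] / mass;      // B
    for (int q = 0; q < 3 * n; ++q)
      if (!std::isfinite(x[q]))
        stop("numerical blow-up (non-finite coordinates) at step %d", s + 1);
    if (save_stride > 0 && (s + 1) % save_stride == 0) {
      // total energy pairs the whole-step velocities with the potential
      double keFull = 0.0;
      for (int q = 0; q < 3 * n; ++q) keFull += 0.5 * mass * v[q] * v[q];
      for (int q = 0; q < 3 * n; ++q) frames(isave, q) = x[q];
      temps[isave] = 2.0 * ke / (3.0 * n * KB);
      etot[isave] = Epot + keFull;
      ++isave;
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      xf(i, k) = x[3 * i + k];
      vf(i, k) = v[3 * i + k];
    }
  return List::create(_["frames"] = frames, _["temps"] = temps,
                      _["etot"] = etot, _["coords"] = xf, _["vel"] = vf);
}
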