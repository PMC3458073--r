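// C-alpha structure-based model: potential energy, analytic forces and a
// BAOAB Langevin integrator in reduced units (epsilon = k_B = mass = 1,
// lengths in Angstrom). Randomness comes from R's RNG so runs are
// reproducible with set.seed().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Topo {
  int n;
  std::vector<double> bond_r0;                 // n-1
  std::vector<double> theta0;                  // n-2
  std::vector<double> phi0;                    // n-3
  std::vector<int> dih_on;                     // n-3
  std::vector<int> ci, cj;                     // native contacts (0-based)
  std::vector<double> cr0;
  std::vector<int> ni, nj;                     // non-native pairs (0-based)
  std::vector<double> nsig;
  double eps, Kr, Kth, Kp1, Kp3;
};

inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x <= -M_PI) x += 2.0 * M_PI;
  return x;
}

Topo unpack(const List& topo) {
  Topo t;
  t.n = as<int>(topo["n_residues"]);
  DataFrame bonds = as<DataFrame>(topo["bonds"]);
  NumericVector br0 = bonds["r0"];
  t.bond_r0.assign(br0.begin(), br0.end());
  DataFrame angles = as<DataFrame>(topo["angles"]);
  NumericVector th0 = angles["theta0"];
  t.theta0.assign(th0.begin(), th0.end());
  DataFrame dih = as<DataFrame>(topo["dihedrals"]);
  NumericVector p0 = dih["phi0"];
  LogicalVector en = dih["enabled"];
  t.phi0.assign(p0.begin(), p0.end());
  t.dih_on.assign(en.begin(), en.end());
  DataFrame con = as<DataFrame>(topo["contacts"]);
  IntegerVector cci = con["i"], ccj = con["j"];
  NumericVector ccr = con["r0"];
  for (int k = 0; k < cci.size(); ++k) {
    t.ci.push_back(cci[k] - 1); t.cj.push_back(ccj[k] - 1);
    t.cr0.push_back(ccr[k]);
  }
  DataFrame nn = as<DataFrame>(topo["nonnative"]);
  IntegerVector nni = nn["i"], nnj = nn["j"];
  NumericVector nns = nn["sigma"];
  for (int k = 0; k < nni.size(); ++k) {
    t.ni.push_back(nni[k] - 1); t.nj.push_back(nnj[k] - 1);
    t.nsig.push_back(nns[k]);
  }
  t.eps = as<double>(topo["epsilon"]);
  t.Kr = as<double>(topo["K_r"]);
  t.Kth = as<double>(topo["K_theta"]);
  t.Kp1 = as<double>(topo["K_phi1"]);
  t.Kp3 = as<double>(topo["K_phi3"]);
  return t;
}

// Energy and (optionally) forces; x is n x 3 row-major [x0 y0 z0 x1 ...].
double eval_model(const Topo& t, const double* x, double* f,
                  bool want_f) {
  const int n = t.n;
  double V = 0.0;
  if (want_f) std::fill(f, f + 3 * n, 0.0);

  // bonds
  for (int i = 0; i < n - 1; ++i) {
    double d[3];
    sub3(x + 3 * (i + 1), x + 3 * i, d);
    double r = std::sqrt(dot3(d, d));
    double dr = r - t.bond_r0[i];
    V += t.Kr * dr * dr;
    if (want_f) {
      double c = 2.0 * t.Kr * dr / r;
      for (int k = 0; k < 3; ++k) {
        f[3 * (i + 1) + k] -= c * d[k];
        f[3 * i + k] += c * d[k];
      }
    }
  }

  // angles over (a, a+1, a+2)
  for (int a = 0; a < n - 2; ++a) {
    double u[3], v[3];
    sub3(x + 3 * a, x + 3 * (a + 1), u);
    sub3(x + 3 * (a + 2), x + 3 * (a + 1), v);
    double ru = std::sqrt(dot3(u, u)), rv = std::sqrt(dot3(v, v));
    double c = dot3(u, v) / (ru * rv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - t.theta0[a];
    V += t.Kth * dth * dth;
    if (want_f) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double dVdth = 2.0 * t.Kth * dth;
      for (int k = 0; k < 3; ++k) {
        double gi = (c * u[k] / ru - v[k] / rv) / (ru * s);
        double gk = (c * v[k] / rv - u[k] / ru) / (rv * s);
        f[3 * a + k] -= dVdth * gi;
        f[3 * (a + 2) + k] -= dVdth * gk;
        f[3 * (a + 1) + k] += dVdth * (gi + gk);
      }
    }
  }

  // dihedrals over (d, d+1, d+2, d+3)
  for (int d = 0; d < n - 3; ++d) {
    if (!t.dih_on[d]) continue;
    double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
    sub3(x + 3 * (d + 1), x + 3 * d, b1);
    sub3(x + 3 * (d + 2), x + 3 * (d + 1), b2);
    sub3(x + 3 * (d + 3), x + 3 * (d + 2), b3);
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double rb2 = std::sqrt(dot3(b2, b2));
    if (n1sq < 1e-14 || n2sq < 1e-14) continue;  // transiently collinear
    cross3(n1, n2, m1);
    double phi = std::atan2(dot3(m1, b2) / rb2, dot3(n1, n2));
    double dphi = wrap_pi(phi - t.phi0[d]);
    V += t.Kp1 * (1.0 - std::cos(dphi)) + t.Kp3 * (1.0 - std::cos(3.0 * dphi));
    if (want_f) {
      double dVdphi = t.Kp1 * std::sin(dphi) + 3.0 * t.Kp3 * std::sin(3.0 * dphi);
      double f1 = dot3(b1, b2) / dot3(b2, b2);
      double f2 = dot3(b3, b2) / dot3(b2, b2);
      for (int k = 0; k < 3; ++k) {
        double da = -rb2 / n1sq * n1[k];
        double dd = rb2 / n2sq * n2[k];
        double db = -(1.0 + f1) * da + f2 * dd;
        double dc = f1 * da - (1.0 + f2) * dd;
        f[3 * d + k] -= dVdphi * da;
        f[3 * (d + 1) + k] -= dVdphi * db;
        f[3 * (d + 2) + k] -= dVdphi * dc;
        f[3 * (d + 3) + k] -= dVdphi * dd;
      }
    }
  }

  // native contacts: 10-12 well, minimum -eps at r0
  for (size_t k = 0; k < t.ci.size(); ++k) {
    double d[3];
    sub3(x + 3 * t.ci[k], x + 3 * t.cj[k], d);
    double r2 = dot3(d, d);
    double r = std::sqrt(r2);
    if (r < 1e-6) stop("overlapping beads (contact pair distance < 1e-6 A)");
    double q2 = t.cr0[k] * t.cr0[k] / r2;
    double q10 = q2 * q2 * q2 * q2 * q2;
    double q12 = q10 * q2;
    V += t.eps * (5.0 * q12 - 6.0 * q10);
    if (want_f) {
      // dV/dr = (60 eps / r) (q10 - q12)
      double c = 60.0 * t.eps * (q10 - q12) / r2;  // dV/dr / r
      for (int m = 0; m < 3; ++m) {
        f[3 * t.ci[k] + m] -= c * d[m];
        f[3 * t.cj[k] + m] += c * d[m];
      }
    }
  }

  // non-native pairs: smooth repulsive wall eps*((sig/r)^6 - 1)^2 for
  // r < sigma_ij, identically zero (value and force) at and beyond sigma_ij
  for (size_t k = 0; k < t.ni.size(); ++k) {
    double d[3];
    sub3(x + 3 * t.ni[k], x + 3 * t.nj[k], d);
    double r2 = dot3(d, d);
    double sig = t.nsig[k];
    if (r2 >= sig * sig) continue;
    double r = std::sqrt(r2);
    if (r < 1e-6) stop("overlapping beads (non-native pair distance < 1e-6 A)");
    double u = sig * sig / r2;
    u = u * u * u;  // (sig/r)^6
    V += t.eps * (u - 1.0) * (u - 1.0);
    if (want_f) {
      double c = -12.0 * t.eps * u * (u - 1.0) / r2;  // dV/dr / r
      for (int m = 0; m < 3; ++m) {
        f[3 * t.ni[k] + m] -= c * d[m];
        f[3 * t.nj[k] + m] += c * d[m];
      }
    }
  }
  return V;
}

double frac_native(const Topo& t, const double* x, double gamma,
                   int* formed) {
  if (t.ci.empty()) return 1.0;
  int nf = 0;
  for (size_t k = 0; k < t.ci.size(); ++k) {
    double d[3];
    sub3(x + 3 * t.ci[k], x + 3 * t.cj[k], d);
    bool on = std::sqrt(dot3(d, d)) < gamma * t.cr0[k];
    if (formed) formed[k] = on;
    nf += on;
  }
  return (double)nf / (double)t.ci.size();
}

}  // namespace

// [[Rcpp::export]]
double go_energy_cpp(List topo, NumericMatrix coords) {
  Topo t = unpack(topo);
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  return eval_model(t, x.data(), nullptr, false);
}

// [[Rcpp::export]]
NumericMatrix go_forces_cpp(List topo, NumericMatrix coords) {
  Topo t = unpack(topo);
  std::vector<double> x(3 * t.n), f(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  eval_model(t, x.data(), f.data(), true);
  NumericMatrix out(t.n, 3);
  for (int i = 0; i < t.n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = f[3 * i + k];
  return out;
}

// [[Rcpp::export]]
List go_q_cpp(List topo, NumericMatrix coords, double gamma) {
  Topo t = unpack(topo);
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  std::vector<int> formed(t.ci.size());
  double q = frac_native(t, x.data(), gamma,
                         t.ci.empty() ? nullptr : formed.data());
  LogicalVector lf(formed.size());
  for (size_t k = 0; k < formed.size(); ++k) lf[k] = formed[k] != 0;
  return List::create(_["q"] = q, _["formed"] = lf);
}

// BAOAB Langevin integration; friction = 0 reduces to velocity Verlet.
// [[Rcpp::export]]
List go_langevin_cpp(List topo, NumericMatrix start, double temperature,
                     double timestep, double friction, double q_gamma,
                     int n_steps, int save_every) {
  Topo t = unpack(topo);
  const int n = t.n;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = start(i, k);

  const double c1 = std::exp(-friction * timestep);
  const double c2 = std::sqrt((1.0 - c1 * c1) * temperature);
  const double sdv = std::sqrt(temperature);
  for (int i = 0; i < 3 * n; ++i) v[i] = sdv * norm_rand();

  double V = eval_model(t, x.data(), f.data(), true);

  const int n_frames = n_steps / save_every;
  NumericVector frames(Dimension(n, 3, n_frames));
  NumericVector epot(n_frames), ekin(n_frames), qv(n_frames);
  IntegerVector steps(n_frames);

  int frame = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * timestep * f[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * timestep * v[i];
    if (friction > 0.0)
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * timestep * v[i];
    V = eval_model(t, x.data(), f.data(), true);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * timestep * f[i];

    if (step % save_every == 0) {
      double K = 0.0, mx = 0.0;
      for (int i = 0; i < 3 * n; ++i) {
        K += 0.5 * v[i] * v[i];
        if (std::fabs(x[i]) > mx) mx = std::fabs(x[i]);
      }
      if (!std::isfinite(V) || !std::isfinite(K) || mx > 1e6)
        stop("numerical blow-up at step %d (non-finite energy or |coordinate|"
             " > 1e6 A); reduce the timestep", step);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[i + n * k + 3 * n * frame] = x[3 * i + k];
      epot[frame] = V;
      ekin[frame] = K;
      qv[frame] = frac_native(t, x.data(), q_gamma, nullptr);
      steps[frame] = step;
      ++frame;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_x(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) final_x(i, k) = x[3 * i + k];
  return List::create(_["frames"] = frames, _["energies"] = epot,
                      _["kinetic"] = ekin, _["q_values"] = qv,
                      _["steps"] = steps, _["final"] = final_x);
}
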