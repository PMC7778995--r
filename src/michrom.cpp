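// Coarse-grained chromatin energy model and Langevin sampler.
//
// Reduced units throughout: bead diameter sigma = 1, thermal energy = 1.
// Terms: FENE connectivity (+ nearest-neighbour WCA core), half-harmonic
// spherical confinement, translationally invariant ideal-chromosome term
// gamma(|i-j|) * f(r), type-to-type couplings alpha(t_i, t_j) * f(r) with a
// non-nearest-neighbour WCA core, and loop-anchor interactions chi * f(r).
// f is the sigmoidal contact kernel f(r) = (1 + tanh(mu (rc - r))) / 2.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

struct ModelPar {
  double fene_k, fene_r0;
  double eps, sigma;
  double R, k_conf;
  double mu, rc;
  double loop_chi;
  int d_min, d_max;
  std::vector<double> gamma;     // gamma[d] for d = 0..d_max (0 below d_min)
  std::vector<double> type_mat;  // 7x7 row-major
  double wca_cut;                // 2^(1/6) sigma
  double kern_cut;               // beyond this f(r) < ~1e-12
};

static ModelPar unpackParams(const List& p) {
  ModelPar q;
  q.fene_k = as<double>(p["feneK"]);
  q.fene_r0 = as<double>(p["feneR0"]);
  q.eps = as<double>(p["stericEpsilon"]);
  q.sigma = as<double>(p["stericSigma"]);
  q.R = as<double>(p["confinementRadius"]);
  q.k_conf = as<double>(p["confinementK"]);
  q.mu = as<double>(p["contactMu"]);
  q.rc = as<double>(p["contactRc"]);
  q.loop_chi = as<double>(p["loopChi"]);
  q.d_min = as<int>(p["dMin"]);
  q.d_max = as<int>(p["dMax"]);
  NumericVector g = p["gammaTable"];  // precomputed in R: gamma[d], d = 0..dMax
  q.gamma.assign(g.begin(), g.end());
  NumericMatrix tm = p["typeMatrix"];
  q.type_mat.assign(tm.begin(), tm.end());  // column-major, symmetric: ok
  q.wca_cut = std::pow(2.0, 1.0 / 6.0) * q.sigma;
  q.kern_cut = q.rc + 14.0 / q.mu;
  return q;
}

static inline double fkern(double r, double mu, double rc) {
  return 0.5 * (1.0 + std::tanh(mu * (rc - r)));
}
// dU/dr of the kernel
static inline double dfkern(double r, double mu, double rc) {
  double t = std::tanh(mu * (rc - r));
  return -0.5 * mu * (1.0 - t * t);
}

// WCA: purely repulsive shifted-truncated Lennard-Jones core.
static inline double wcaE(double r, double eps, double sigma, double cut) {
  if (r >= cut) return 0.0;
  double sr2 = sigma * sigma / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6) + eps;
}
// dU/dr
static inline double wcaDE(double r, double eps, double sigma, double cut) {
  if (r >= cut) return 0.0;
  double sr2 = sigma * sigma / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return -24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;
}

static inline double feneE(double r, double k, double r0) {
  double x = r / r0;
  return -0.5 * k * r0 * r0 * std::log(1.0 - x * x);
}
static inline double feneDE(double r, double k, double r0) {
  double x = r / r0;
  return k * r / (1.0 - x * x);
}

static inline double dist3(const double* a, const double* b, double* d) {
  d[0] = a[0] - b[0];
  d[1] = a[1] - b[1];
  d[2] = a[2] - b[2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

// [[Rcpp::export(name = ".cppEnergyBonded")]]
double cppEnergyBonded(NumericMatrix pos, List params) {
  ModelPar q = unpackParams(params);
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dx = pos(i, 0) - pos(i + 1, 0);
    double dy = pos(i, 1) - pos(i + 1, 1);
    double dz = pos(i, 2) - pos(i + 1, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r >= q.fene_r0)
      stop("bond %d-%d overstretched: r = %f >= r0 = %f", i + 1, i + 2, r,
           q.fene_r0);
    e += feneE(r, q.fene_k, q.fene_r0) + wcaE(r, q.eps, q.sigma, q.wca_cut);
  }
  return e;
}

// [[Rcpp::export(name = ".cppEnergyConfinement")]]
double cppEnergyConfinement(NumericMatrix pos, List params) {
  ModelPar q = unpackParams(params);
  double e = 0.0;
  for (int i = 0; i < pos.nrow(); ++i) {
    double r = std::sqrt(pos(i, 0) * pos(i, 0) + pos(i, 1) * pos(i, 1) +
                         pos(i, 2) * pos(i, 2));
    if (r > q.R) {
      double d = r - q.R;
      e += q.k_conf * d * d;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cppEnergyIdeal")]]
double cppEnergyIdeal(NumericMatrix pos, List params) {
  ModelPar q = unpackParams(params);
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    int jmax = std::min(n - 1, i + q.d_max);
    for (int j = i + q.d_min; j <= jmax; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < q.kern_cut) e += q.gamma[j - i] * fkern(r, q.mu, q.rc);
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cppEnergyType")]]
double cppEnergyType(NumericMatrix pos, IntegerVector types, List params) {
  ModelPar q = unpackParams(params);
  int n = pos.nrow();
  if (types.size() != n) stop("types length must equal bead count");
  for (int i = 0; i < n; ++i)
    if (types[i] < 0 || types[i] > 6) stop("unknown type index %d", types[i]);
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < q.wca_cut) e += wcaE(r, q.eps, q.sigma, q.wca_cut);
      if (r < q.kern_cut)
        e += q.type_mat[types[i] + 7 * types[j]] * fkern(r, q.mu, q.rc);
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cppEnergyLoops")]]
double cppEnergyLoops(NumericMatrix pos, IntegerMatrix loops, List params) {
  ModelPar q = unpackParams(params);
  double e = 0.0;
  for (int l = 0; l < loops.nrow(); ++l) {
    int a = loops(l, 0) - 1, b = loops(l, 1) - 1;
    if (a < 0 || b < 0 || a >= pos.nrow() || b >= pos.nrow())
      stop("loop anchor out of range");
    double dx = pos(a, 0) - pos(b, 0);
    double dy = pos(a, 1) - pos(b, 1);
    double dz = pos(a, 2) - pos(b, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += q.loop_chi * fkern(r, q.mu, q.rc);
  }
  return e;
}

static void addForces(const std::vector<double>& x, int n, const ModelPar& q,
                      const std::vector<int>& types,
                      const std::vector<std::pair<int, int> >& loops,
                      std::vector<double>& f, int step_for_error) {
  std::fill(f.begin(), f.end(), 0.0);
  double d[3];
  // bonded
  for (int i = 0; i + 1 < n; ++i) {
    double r = dist3(&x[3 * i], &x[3 * (i + 1)], d);
    if (r >= q.fene_r0) {
      if (step_for_error >= 0)
        stop("energy divergence at step %d: bond %d-%d overstretched (r = %f)",
             step_for_error, i + 1, i + 2, r);
      else
        stop("bond %d-%d overstretched: r = %f >= r0 = %f", i + 1, i + 2, r,
             q.fene_r0);
    }
    double du = feneDE(r, q.fene_k, q.fene_r0) +
                wcaDE(r, q.eps, q.sigma, q.wca_cut);
    double s = -du / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += s * d[k];
      f[3 * (i + 1) + k] -= s * d[k];
    }
  }
  // confinement
  for (int i = 0; i < n; ++i) {
    double r = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                         x[3 * i + 2] * x[3 * i + 2]);
    if (r > q.R && r > 0) {
      double s = -2.0 * q.k_conf * (r - q.R) / r;
      for (int k = 0; k < 3; ++k) f[3 * i + k] += s * x[3 * i + k];
    }
  }
  // non-bonded pairs: steric core (|i-j| >= 2), type couplings (|i-j| >= 2),
  // ideal chromosome (d_min <= |i-j| <= d_max)
  bool has_types = !types.empty();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double r = dist3(&x[3 * i], &x[3 * j], d);
      if (r >= q.kern_cut && r >= q.wca_cut) continue;
      double du = 0.0;
      if (r < q.wca_cut) {
        if (r < 1e-12) r = 1e-12;
        du += wcaDE(r, q.eps, q.sigma, q.wca_cut);
      }
      if (r < q.kern_cut) {
        double dk = dfkern(r, q.mu, q.rc);
        if (has_types) du += q.type_mat[types[i] + 7 * types[j]] * dk;
        int dg = j - i;
        if (dg >= q.d_min && dg <= q.d_max) du += q.gamma[dg] * dk;
      }
      double s = -du / r;
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += s * d[k];
        f[3 * j + k] -= s * d[k];
      }
    }
  }
  // loops
  for (size_t l = 0; l < loops.size(); ++l) {
    int a = loops[l].first, b = loops[l].second;
    double r = dist3(&x[3 * a], &x[3 * b], d);
    if (r < 1e-12) continue;
    double du = q.loop_chi * dfkern(r, q.mu, q.rc);
    double s = -du / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * a + k] += s * d[k];
      f[3 * b + k] -= s * d[k];
    }
  }
}

static std::vector<std::pair<int, int> > unpackLoops(const IntegerMatrix& lp,
                                                     int n) {
  std::vector<std::pair<int, int> > v;
  for (int l = 0; l < lp.nrow(); ++l) {
    int a = lp(l, 0) - 1, b = lp(l, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n) stop("loop anchor out of range");
    v.push_back(std::make_pair(a, b));
  }
  return v;
}

// [[Rcpp::export(name = ".cppForces")]]
NumericMatrix cppForces(NumericMatrix pos, IntegerVector types,
                        IntegerMatrix loops, List params) {
  ModelPar q = unpackParams(params);
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  std::vector<int> tv(types.begin(), types.end());
  std::vector<std::pair<int, int> > lp = unpackLoops(loops, n);
  addForces(x, n, q, tv, lp, f, -1);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = f[3 * i + k];
  return out;
}

// BAOAB Langevin integrator (unit mass).
// [[Rcpp::export(name = ".cppLangevin")]]
List cppLangevin(NumericMatrix pos0, IntegerVector types, IntegerMatrix loops,
                 List params, int n_steps, int save_every, int equil,
                 double dt, double friction, double temperature,
                 unsigned int seed) {
  ModelPar q = unpackParams(params);
  int n = pos0.nrow();
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos0(i, k);
  std::vector<int> tv(types.begin(), types.end());
  std::vector<std::pair<int, int> > lp = unpackLoops(loops, n);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(temperature * (1.0 - c1 * c1));

  int n_frames = (n_steps - equil) > 0 ? (n_steps - equil) / save_every : 0;
  NumericVector frames(Dimension(n, 3, std::max(n_frames, 1)));
  if (n_frames == 0) stop("no frames would be saved: check nSteps/saveEvery/equilibrationSteps");
  int saved = 0;

  addForces(x, n, q, tv, lp, f, 0);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];          // B
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];          // A
    for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * gauss(rng); // O
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];          // A
    addForces(x, n, q, tv, lp, f, step);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];          // B
    if (step > equil && (step - equil) % save_every == 0 && saved < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[i + n * k + 3 * n * saved] = x[3 * i + k];
      ++saved;
    }
    if (step % 10000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["frames"] = frames, _["n_frames"] = saved);
}

// Contact map over frames: hard cutoff or kernel-averaged.
// frames: n x 3 x F array; returns n x n symmetric matrix.
// [[Rcpp::export(name = ".cppContactMap")]]
NumericMatrix cppContactMap(NumericVector frames, int n, int F, double rc,
                            bool kernel_mode, double mu) {
  NumericMatrix out(n, n);
  for (int fr = 0; fr < F; ++fr) {
    const double* base = &frames[0] + (size_t)3 * n * fr;
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        double dx = base[i] - base[j];
        double dy = base[i + n] - base[j + n];
        double dz = base[i + 2 * n] - base[j + 2 * n];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double c = kernel_mode ? fkern(r, mu, rc) : (r <= rc ? 1.0 : 0.0);
        out(i, j) += c;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      out(i, j) /= F;
      out(j, i) = out(i, j);
    }
  return out;
}
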