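// Compiled kernels for the stochastic side of the package: Euler-Maruyama
// integration of the two-gene Langevin dynamics, streaming histogram and
// occupancy accumulation, first-passage sampling (full 2-D and the 1-D
// reduction at clamped x1), and deterministic RK4 relaxation used for
// watershed-correct basin assignment.  All random numbers come from R's RNG
// so set.seed() governs every stochastic result.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double a1, a2, b1, b2, k1, k2, th, n;
};

static Pars as_pars(const List& p) {
  Pars q;
  q.a1 = as<double>(p["a1"]);
  q.a2 = as<double>(p["a2"]);
  q.b1 = as<double>(p["b1"]);
  q.b2 = as<double>(p["b2"]);
  q.k1 = as<double>(p["k1"]);
  q.k2 = as<double>(p["k2"]);
  q.th = as<double>(p["theta"]);
  q.n  = as<double>(p["n"]);
  return q;
}

// Hill activation x^n/(th^n + x^n); x = 0 handled as the limit 0 (n > 0).
static inline double hillf(double x, double th, double n) {
  if (x <= 0.0) return 0.0;
  return 1.0 / (1.0 + std::exp(n * (std::log(th) - std::log(x))));
}

static inline double f1(double x1, const Pars& p) {
  return p.a1 * hillf(x1, p.th, p.n) + p.b1 - p.k1 * x1;
}
static inline double f2(double x1, double x2, const Pars& p) {
  return p.a2 * hillf(x2, p.th, p.n) + p.b2 * (1.0 - hillf(x1, p.th, p.n)) -
         p.k2 * x2;
}

static inline void em_step(double& x1, double& x2, const Pars& p, double dt,
                           double sig, bool reflect) {
  double d1 = f1(x1, p) * dt;
  double d2 = f2(x1, x2, p) * dt;
  if (sig > 0.0) {
    d1 += sig * norm_rand();
    d2 += sig * norm_rand();
  }
  x1 += d1;
  x2 += d2;
  if (reflect) {
    if (x1 < 0.0) x1 = -x1;
    if (x2 < 0.0) x2 = -x2;
  }
}

static void check_finite(double x1, double x2, double dt) {
  if (!std::isfinite(x1) || !std::isfinite(x2))
    stop("state became non-finite during integration; dt = %g is too large",
         dt);
}

// [[Rcpp::export(name = ".sim_em_cpp")]]
NumericMatrix sim_em_cpp(List params, double D, NumericVector x_init,
                         double dt, int n_steps, int thin, bool reflect) {
  Pars p = as_pars(params);
  double x1 = x_init[0], x2 = x_init[1];
  double sig = std::sqrt(2.0 * D * dt);
  int n_keep = n_steps / thin + 1;
  NumericMatrix out(n_keep, 2);
  out(0, 0) = x1;
  out(0, 1) = x2;
  int k = 1;
  for (int i = 1; i <= n_steps; ++i) {
    em_step(x1, x2, p, dt, sig, reflect);
    if (i % thin == 0 && k < n_keep) {
      check_finite(x1, x2, dt);
      out(k, 0) = x1;
      out(k, 1) = x2;
      ++k;
    }
  }
  return out;
}

// Streaming 2-D histogram of a single long trajectory; counts every post
// burn-in step into an nx-by-ny grid of cells over
// [x1lo, x1hi] x [x2lo, x2hi].  Samples outside the box are tallied in the
// returned attribute "n_outside".
// [[Rcpp::export(name = ".sim_hist_cpp")]]
NumericMatrix sim_hist_cpp(List params, double D, NumericVector x_init,
                           double dt, double n_steps, double burn_steps,
                           double x1lo, double x1hi, int nx, double x2lo,
                           double x2hi, int ny, bool reflect) {
  Pars p = as_pars(params);
  double x1 = x_init[0], x2 = x_init[1];
  double sig = std::sqrt(2.0 * D * dt);
  NumericMatrix counts(nx, ny);
  double hx = (x1hi - x1lo) / nx, hy = (x2hi - x2lo) / ny;
  double outside = 0.0;
  for (double i = 1; i <= n_steps; ++i) {
    em_step(x1, x2, p, dt, sig, reflect);
    if (i <= burn_steps) continue;
    int ix = (int)std::floor((x1 - x1lo) / hx);
    int iy = (int)std::floor((x2 - x2lo) / hy);
    if (ix >= 0 && ix < nx && iy >= 0 && iy < ny)
      counts(ix, iy) += 1.0;
    else
      outside += 1.0;
  }
  check_finite(x1, x2, dt);
  counts.attr("n_outside") = outside;
  return counts;
}

// Time spent in each basin of a precomputed basin map (integer labels on an
// nx-by-ny lookup grid; 0 = unassigned).  Returns counts per label 0..n_lab.
// [[Rcpp::export(name = ".sim_occupancy_cpp")]]
NumericVector sim_occupancy_cpp(List params, double D, NumericVector x_init,
                                double dt, double n_steps, double burn_steps,
                                IntegerMatrix basin_map, double x1lo,
                                double x1hi, double x2lo, double x2hi,
                                int n_lab, bool reflect) {
  Pars p = as_pars(params);
  double x1 = x_init[0], x2 = x_init[1];
  double sig = std::sqrt(2.0 * D * dt);
  int nx = basin_map.nrow(), ny = basin_map.ncol();
  double hx = (x1hi - x1lo) / nx, hy = (x2hi - x2lo) / ny;
  NumericVector tally(n_lab + 1);
  for (double i = 1; i <= n_steps; ++i) {
    em_step(x1, x2, p, dt, sig, reflect);
    if (i <= burn_steps) continue;
    int ix = (int)std::floor((x1 - x1lo) / hx);
    int iy = (int)std::floor((x2 - x2lo) / hy);
    int lab = 0;
    if (ix >= 0 && ix < nx && iy >= 0 && iy < ny) lab = basin_map(ix, iy);
    tally[lab] += 1.0;
  }
  check_finite(x1, x2, dt);
  return tally;
}

// First-passage times of the full 2-D dynamics from `source` into a max-norm
// capture disk of radius `radius` around `target`.  Censored samples are
// returned as NA.
// [[Rcpp::export(name = ".fpt2d_cpp")]]
NumericVector fpt2d_cpp(List params, double D, NumericVector source,
                        NumericVector target, double radius, double dt,
                        double t_max, int n_samples, bool reflect) {
  Pars p = as_pars(params);
  double sig = std::sqrt(2.0 * D * dt);
  double n_max = std::ceil(t_max / dt);
  NumericVector out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    double x1 = source[0], x2 = source[1];
    double hit = NA_REAL;
    for (double i = 1; i <= n_max; ++i) {
      em_step(x1, x2, p, dt, sig, reflect);
      if (std::fabs(x1 - target[0]) <= radius &&
          std::fabs(x2 - target[1]) <= radius) {
        hit = i * dt;
        break;
      }
    }
    check_finite(x1, x2, dt);
    out[s] = hit;
  }
  return out;
}

// First-passage times of the 1-D reduction (x1 clamped at x0): reflecting at
// the origin, absorbing at the first crossing of y_absorb.
// [[Rcpp::export(name = ".fpt1d_cpp")]]
NumericVector fpt1d_cpp(List params, double x0, double D, double y_start,
                        double y_absorb, double dt, double t_max,
                        int n_samples) {
  Pars p = as_pars(params);
  double sig = std::sqrt(2.0 * D * dt);
  double n_max = std::ceil(t_max / dt);
  bool up = y_absorb > y_start;
  NumericVector out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    double y = y_start;
    double hit = NA_REAL;
    for (double i = 1; i <= n_max; ++i) {
      y += f2(x0, y, p) * dt + sig * norm_rand();
      if (y < 0.0) y = -y;
      if (up ? (y >= y_absorb) : (y <= y_absorb)) {
        hit = i * dt;
        break;
      }
    }
    if (!std::isfinite(y))
      stop("state became non-finite during integration; dt = %g is too large",
           dt);
    out[s] = hit;
  }
  return out;
}

// Deterministic relaxation (classic RK4, fixed step) of each starting state
// until it enters the max-norm capture disk of one of the supplied
// attractors; returns the 1-based attractor index, or 0 if still unresolved
// at t_max.
// [[Rcpp::export(name = ".relax_cpp")]]
IntegerVector relax_cpp(List params, NumericMatrix starts,
                        NumericMatrix attractors, double dt, double t_max,
                        double radius) {
  Pars p = as_pars(params);
  int n = starts.nrow(), m = attractors.nrow();
  double n_max = std::ceil(t_max / dt);
  IntegerVector out(n);
  for (int s = 0; s < n; ++s) {
    double x1 = starts(s, 0), x2 = starts(s, 1);
    int lab = 0;
    for (double i = 0; i <= n_max; ++i) {
      for (int j = 0; j < m; ++j) {
        if (std::fabs(x1 - attractors(j, 0)) <= radius &&
            std::fabs(x2 - attractors(j, 1)) <= radius) {
          lab = j + 1;
          break;
        }
      }
      if (lab) break;
      double k1a = f1(x1, p), k1b = f2(x1, x2, p);
      double k2a = f1(x1 + 0.5 * dt * k1a, p),
             k2b = f2(x1 + 0.5 * dt * k1a, x2 + 0.5 * dt * k1b, p);
      double k3a = f1(x1 + 0.5 * dt * k2a, p),
             k3b = f2(x1 + 0.5 * dt * k2a, x2 + 0.5 * dt * k2b, p);
      double k4a = f1(x1 + dt * k3a, p),
             k4b = f2(x1 + dt * k3a, x2 + dt * k3b, p);
      x1 += dt * (k1a + 2 * k2a + 2 * k3a + k4a) / 6.0;
      x2 += dt * (k1b + 2 * k2b + 2 * k3b + k4b) / 6.0;
    }
    out[s] = lab;
  }
  return out;
}
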