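// Langevin dynamics core for the coarse-grained HP heteropolymer.
//
// One bead per residue, unit bead mass. Bonded neighbours interact through a
// harmonic spring 0.5*k*(r-b)^2; all pairs |i-j| >= 2 through an
// Ashbaugh-Hatch lambda-scaled Lennard-Jones potential:
//   r <  2^(1/6)*sigma : U = lj(r) + (1 - lambda)*eps
//   r >= 2^(1/6)*sigma : U = lambda * lj(r)
// with lambda_pair = (lambda_i + lambda_j)/2, truncated at r_cut = 3*sigma
// and shifted to zero there (constant shift; forces untouched).
// Integration: BAOAB splitting (kick / drift / Ornstein-Uhlenbeck / drift /
// kick); "descent" mode replaces it by plain gradient descent for
// energy-minimization sanity checks.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  double bond_k, bond_b, sigma, eps, kT, gamma, dt;
};

// accumulate forces; returns total potential energy
double forces(const std::vector<double>& x, const std::vector<double>& lam,
              int L, const Params& p, std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  double U = 0.0;
  const double rmin2 = std::pow(2.0, 1.0 / 3.0) * p.sigma * p.sigma;
  const double rc = 3.0 * p.sigma, rc2 = rc * rc;
  const double s6c = std::pow(p.sigma / rc, 6);
  const double ljc = 4.0 * p.eps * (s6c * s6c - s6c);  // lj at cutoff (< 0)
  // bonds
  for (int i = 0; i + 1 < L; ++i) {
    double dx = x[3 * (i + 1)] - x[3 * i];
    double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
    double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    double dU = p.bond_k * (r - p.bond_b);
    U += 0.5 * p.bond_k * (r - p.bond_b) * (r - p.bond_b);
    double fr = -dU / r;
    f[3 * i]     -= fr * dx; f[3 * (i + 1)]     += fr * dx;
    f[3 * i + 1] -= fr * dy; f[3 * (i + 1) + 1] += fr * dy;
    f[3 * i + 2] -= fr * dz; f[3 * (i + 1) + 2] += fr * dz;
  }
  // nonbonded
  for (int i = 0; i < L; ++i) {
    for (int j = i + 2; j < L; ++j) {
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double lambda = 0.5 * (lam[i] + lam[j]);
      if (r2 < 1e-12) r2 = 1e-12;
      double s2 = p.sigma * p.sigma / r2;
      double s6 = s2 * s2 * s2;
      double lj = 4.0 * p.eps * (s6 * s6 - s6);
      double flj_over_r = 24.0 * p.eps * (2.0 * s6 * s6 - s6) / r2;  // -dU/dr / r
      double u, fr;
      if (r2 < rmin2) {
        u = lj + (1.0 - lambda) * p.eps - lambda * ljc;
        fr = flj_over_r;
      } else {
        u = lambda * (lj - ljc);
        fr = lambda * flj_over_r;
      }
      U += u;
      f[3 * i]     -= fr * dx; f[3 * j]     += fr * dx;
      f[3 * i + 1] -= fr * dy; f[3 * j + 1] += fr * dy;
      f[3 * i + 2] -= fr * dz; f[3 * j + 2] += fr * dz;
    }
  }
  return U;
}

}  // namespace

// [[Rcpp::export(.hp_simulate_cpp)]]
List hp_simulate_cpp(NumericMatrix init, NumericVector lambdas,
                     double bond_k, double bond_b, double sigma, double eps,
                     double kT, double gamma, double dt,
                     int n_steps, int save_every, int seed,
                     bool descent, int minimize_steps, double max_disp) {
  const int L = init.nrow();
  Params p{bond_k, bond_b, sigma, eps, kT, gamma, dt};
  std::vector<double> x(3 * L), v(3 * L, 0.0), f(3 * L), lam(L);
  for (int i = 0; i < L; ++i) {
    x[3 * i] = init(i, 0); x[3 * i + 1] = init(i, 1); x[3 * i + 2] = init(i, 2);
    lam[i] = lambdas[i];
  }
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(kT);

  const int n_saved = n_steps / save_every;
  NumericMatrix coords(n_saved, 3 * L);
  NumericVector energy(n_saved);

  double U = forces(x, lam, L, p, f);
  // steepest-descent pre-relaxation with a per-coordinate displacement cap:
  // random initial walks can carry severe core overlaps whose forces would
  // destroy the integrator at any reasonable timestep
  for (int step = 0; step < minimize_steps; ++step) {
    for (int a = 0; a < 3 * L; ++a) {
      double d = dt * f[a];
      if (d > max_disp) d = max_disp;
      if (d < -max_disp) d = -max_disp;
      x[a] += d;
    }
    U = forces(x, lam, L, p, f);
  }
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (descent) {
      // backtracking: halve the step until the energy does not increase,
      // so the descent trace is monotone by construction
      std::vector<double> x0 = x, f0 = f;
      double scale = 1.0, U_new;
      for (int bt = 0; bt < 30; ++bt) {
        for (int a = 0; a < 3 * L; ++a) {
          double d = scale * dt * f0[a];
          if (d > max_disp) d = max_disp;
          if (d < -max_disp) d = -max_disp;
          x[a] = x0[a] + d;
        }
        U_new = forces(x, lam, L, p, f);
        if (U_new <= U || !std::isfinite(U)) break;
        scale *= 0.5;
      }
      if (U_new > U) { x = x0; forces(x, lam, L, p, f); } else { U = U_new; }
    } else {
      for (int a = 0; a < 3 * L; ++a) v[a] += 0.5 * dt * f[a];
      for (int a = 0; a < 3 * L; ++a) x[a] += 0.5 * dt * v[a];
      if (kT > 0.0) {
        for (int a = 0; a < 3 * L; ++a) v[a] = c1 * v[a] + c2 * gauss(rng);
      } else {
        for (int a = 0; a < 3 * L; ++a) v[a] = c1 * v[a];
      }
      for (int a = 0; a < 3 * L; ++a) x[a] += 0.5 * dt * v[a];
      U = forces(x, lam, L, p, f);
      for (int a = 0; a < 3 * L; ++a) v[a] += 0.5 * dt * f[a];
    }
    if (step % save_every == 0) {
      bool ok = std::isfinite(U);
      for (int a = 0; ok && a < 3 * L; ++a) ok = std::isfinite(x[a]);
      if (!ok) {
        stop("integrator blow-up at step %d: non-finite coordinates or energy; "
             "reduce the timestep", step);
      }
      for (int a = 0; a < 3 * L; ++a) coords(isave, a) = x[a];
      energy[isave] = U;
      ++isave;
    }
  }
  return List::create(_["coords"] = coords, _["energy"] = energy);
}

// [[Rcpp::export(.hp_energy_cpp)]]
double hp_energy_cpp(NumericMatrix xyz, NumericVector lambdas,
                     double bond_k, double bond_b, double sigma, double eps) {
  const int L = xyz.nrow();
  Params p{bond_k, bond_b, sigma, eps, 1.0, 1.0, 0.01};
  std::vector<double> x(3 * L), f(3 * L), lam(L);
  for (int i = 0; i < L; ++i) {
    x[3 * i] = xyz(i, 0); x[3 * i + 1] = xyz(i, 1); x[3 * i + 2] = xyz(i, 2);
    lam[i] = lambdas[i];
  }
  return forces(x, lam, L, p, f);
}
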