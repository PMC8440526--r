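#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Coarse-grained bead-per-residue chain with fixed bond lengths.
// Energy (kT units):
//   u_lj  : WCA repulsive core (fixed 1 kT) + attractive Lennard-Jones tail
//           with per-pair depth eps0 * mean(hydropathy_i, hydropathy_j)
//   w_el  : Debye-Hueckel  q_i q_j l_B exp(-r / kappa_D) / r  over charged pairs
//   w_solv: -lambda * (# non-bonded contacts with r < 1.5 sigma)
// Non-bonded means |i - j| >= 2.

struct ChainParams {
  double lambda, debye, lB, eps0, sigma, wca_eps;
};

struct EnergyTerms {
  double lj = 0.0, el = 0.0, contacts = 0.0;
  double solv(double lambda) const { return -lambda * contacts; }
  double total(double lambda) const { return lj + el + solv(lambda); }
};

static inline void pair_energy(double dx, double dy, double dz,
                               double qi, double qj, double hi, double hj,
                               const ChainParams &p, EnergyTerms &acc) {
  double r2 = dx * dx + dy * dy + dz * dz;
  double r = std::sqrt(r2);
  double rmin = 1.122462048309373 * p.sigma;   // 2^(1/6) sigma
  double cutoff = 2.5 * p.sigma;
  // repulsive WCA core
  if (r < rmin) {
    double sr6 = std::pow(p.sigma / r, 6);
    acc.lj += 4.0 * p.wca_eps * (sr6 * sr6 - sr6) + p.wca_eps;
  }
  // hydropathy-scaled attractive tail
  double eps_ij = p.eps0 * 0.5 * (hi + hj);
  if (eps_ij > 0.0 && r < cutoff) {
    if (r < rmin) {
      acc.lj += -eps_ij;
    } else {
      double sr6 = std::pow(p.sigma / r, 6);
      acc.lj += 4.0 * eps_ij * (sr6 * sr6 - sr6);
    }
  }
  if (qi != 0.0 && qj != 0.0) {
    acc.el += qi * qj * p.lB * std::exp(-r / p.debye) / r;
  }
  if (r < 1.5 * p.sigma) acc.contacts += 1.0;
}

static EnergyTerms full_energy(const std::vector<double> &x,
                               const std::vector<double> &y,
                               const std::vector<double> &z,
                               const NumericVector &q, const NumericVector &h,
                               const ChainParams &p) {
  int n = x.size();
  EnergyTerms e;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      pair_energy(x[i] - x[j], y[i] - y[j], z[i] - z[j],
                  q[i], q[j], h[i], h[j], p, e);
  return e;
}

// Interaction energy between a moved index range [m0, m1] and the rest.
static EnergyTerms cross_energy(const std::vector<double> &x,
                                const std::vector<double> &y,
                                const std::vector<double> &z,
                                const NumericVector &q, const NumericVector &h,
                                const ChainParams &p, int m0, int m1) {
  int n = x.size();
  EnergyTerms e;
  for (int i = m0; i <= m1; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j >= m0 && j <= m1) continue;
      if (std::abs(i - j) < 2) continue;
      if (j > i && j <= m1) continue;  // unreachable, kept for clarity
      pair_energy(x[i] - x[j], y[i] - y[j], z[i] - z[j],
                  q[i], q[j], h[i], h[j], p, e);
    }
  }
  // each cross pair visited once (i in moved, j outside)
  return e;
}

// [[Rcpp::export]]
List chain_energy_cpp(NumericMatrix coords, NumericVector charges,
                      NumericVector hydropathy, double lambda, double debye,
                      double lB, double eps0, double sigma) {
  int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  ChainParams p{lambda, debye, lB, eps0, sigma, 1.0};
  EnergyTerms e = full_energy(x, y, z, charges, hydropathy, p);
  return List::create(_["total"] = e.total(lambda), _["w_solv"] = e.solv(lambda),
                      _["u_lj"] = e.lj, _["w_el"] = e.el,
                      _["n_contacts"] = e.contacts);
}

// [[Rcpp::export]]
double rg_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += coords(i, 0); cy += coords(i, 1); cz += coords(i, 2); }
  cx /= n; cy /= n; cz /= n;
  double acc = 0;
  for (int i = 0; i < n; ++i) {
    double dx = coords(i, 0) - cx, dy = coords(i, 1) - cy, dz = coords(i, 2) - cz;
    acc += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(acc / n);
}

static inline void rotate_about_axis(double &vx, double &vy, double &vz,
                                     double ux, double uy, double uz,
                                     double c, double s) {
  // Rodrigues rotation of v about unit axis u
  double dot = ux * vx + uy * vy + uz * vz;
  double crx = uy * vz - uz * vy;
  double cry = uz * vx - ux * vz;
  double crz = ux * vy - uy * vx;
  double nx = vx * c + crx * s + ux * dot * (1 - c);
  double ny = vy * c + cry * s + uy * dot * (1 - c);
  double nz = vz * c + crz * s + uz * dot * (1 - c);
  vx = nx; vy = ny; vz = nz;
}

// [[Rcpp::export]]
List mc_run_cpp(NumericVector charges, NumericVector hydropathy,
                double lambda, double debye, double lB, double eps0,
                double sigma, double bond, int steps, int equil,
                int snap_every, int check_every, int seed) {
  int n = charges.size();
  if (n < 3) stop("chain needs at least 3 beads");
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto rand_unit = [&](double &ux, double &uy, double &uz) {
    double zz = 2.0 * unif(rng) - 1.0;
    double phi = 2.0 * M_PI * unif(rng);
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    ux = rr * std::cos(phi); uy = rr * std::sin(phi); uz = zz;
  };

  // initial conformation: random walk grown with overlap avoidance so the
  // starting energy is moderate (bounded retries; the last draw stands)
  std::vector<double> x(n), y(n), z(n);
  x[0] = y[0] = z[0] = 0.0;
  double rmin = 1.122462048309373 * sigma;
  for (int i = 1; i < n; ++i) {
    for (int attempt = 0; attempt < 50; ++attempt) {
      double ux, uy, uz;
      rand_unit(ux, uy, uz);
      x[i] = x[i - 1] + bond * ux;
      y[i] = y[i - 1] + bond * uy;
      z[i] = z[i - 1] + bond * uz;
      bool clash = false;
      for (int j = 0; j <= i - 2; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < rmin * rmin) { clash = true; break; }
      }
      if (!clash) break;
    }
  }

  ChainParams p{lambda, debye, lB, eps0, sigma, 1.0};
  EnergyTerms e_cur = full_energy(x, y, z, charges, hydropathy, p);
  double e_total = e_cur.total(lambda);

  std::vector<double> rg_series;
  rg_series.reserve(steps / std::max(1, snap_every) + 1);
  std::vector<double> xn = x, yn = y, zn = z;
  long accepted = 0;
  double max_drift = 0.0;

  for (int step = 1; step <= steps; ++step) {
    bool do_pivot = unif(rng) < 0.5;
    int m0, m1;
    xn = x; yn = y; zn = z;
    if (do_pivot) {
      int piv = 1 + (int)(unif(rng) * (n - 2));  // pivot bead in 1..n-2
      double ux, uy, uz;
      rand_unit(ux, uy, uz);
      double ang = (2.0 * unif(rng) - 1.0) * M_PI;
      double c = std::cos(ang), s = std::sin(ang);
      bool tail = unif(rng) < 0.5;
      if (tail) { m0 = piv + 1; m1 = n - 1; } else { m0 = 0; m1 = piv - 1; }
      for (int i = m0; i <= m1; ++i) {
        double vx = xn[i] - x[piv], vy = yn[i] - y[piv], vz = zn[i] - z[piv];
        rotate_about_axis(vx, vy, vz, ux, uy, uz, c, s);
        xn[i] = x[piv] + vx; yn[i] = y[piv] + vy; zn[i] = z[piv] + vz;
      }
    } else {
      int i = 1 + (int)(unif(rng) * (n - 2));  // interior bead
      double ax = x[i + 1] - x[i - 1], ay = y[i + 1] - y[i - 1], az = z[i + 1] - z[i - 1];
      double norm = std::sqrt(ax * ax + ay * ay + az * az);
      if (norm < 1e-12) continue;  // degenerate axis; skip proposal
      ax /= norm; ay /= norm; az /= norm;
      double ang = (2.0 * unif(rng) - 1.0) * M_PI;
      double c = std::cos(ang), s = std::sin(ang);
      double vx = x[i] - x[i - 1], vy = y[i] - y[i - 1], vz = z[i] - z[i - 1];
      rotate_about_axis(vx, vy, vz, ax, ay, az, c, s);
      xn[i] = x[i - 1] + vx; yn[i] = y[i - 1] + vy; zn[i] = z[i - 1] + vz;
      m0 = m1 = i;
    }

    EnergyTerms e_old = cross_energy(x, y, z, charges, hydropathy, p, m0, m1);
    EnergyTerms e_new = cross_energy(xn, yn, zn, charges, hydropathy, p, m0, m1);
    double dE = e_new.total(lambda) - e_old.total(lambda);
    if (dE <= 0.0 || unif(rng) < std::exp(-dE)) {
      for (int i = m0; i <= m1; ++i) { x[i] = xn[i]; y[i] = yn[i]; z[i] = zn[i]; }
      e_total += dE;
      e_cur.lj += e_new.lj - e_old.lj;
      e_cur.el += e_new.el - e_old.el;
      e_cur.contacts += e_new.contacts - e_old.contacts;
      ++accepted;
    }

    if (check_every > 0 && step % check_every == 0) {
      EnergyTerms ref = full_energy(x, y, z, charges, hydropathy, p);
      double drift = std::fabs(ref.total(lambda) - e_total);
      if (drift > max_drift) max_drift = drift;
      e_cur = ref;                       // resynchronize the bookkeeping
      e_total = ref.total(lambda);
    }
    if (step > equil && snap_every > 0 && (step - equil) % snap_every == 0) {
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i) { snap(i, 0) = x[i]; snap(i, 1) = y[i]; snap(i, 2) = z[i]; }
      rg_series.push_back(rg_cpp(snap));
    }
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i) {
    final_coords(i, 0) = x[i]; final_coords(i, 1) = y[i]; final_coords(i, 2) = z[i];
  }
  return List::create(
    _["rg"] = NumericVector(rg_series.begin(), rg_series.end()),
    _["final_coords"] = final_coords,
    _["acceptance_rate"] = (double)accepted / steps,
    _["max_energy_drift"] = max_drift,
    _["final_energy"] = e_total);
}
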