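// Coarse-grained structure-based Langevin engine.
//
// Energy terms: harmonic bonds along each chain, Gaussian native-contact
// wells, tapered residue-base wells (cosine switch between rc and rc+w),
// a soft quadratic excluded-volume wall, harmonic pair restraints
// (cross-link tether / sheet-pairing biases), a harmonic umbrella bias on
// the distance between two site-group centroids (with optional linear
// center ramp for steered runs), and an optional harmonic bias on a fixed
// linear collective coordinate. Integration is BAOAB Langevin; with zero
// friction it reduces to velocity Verlet.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Forces {
  double energy;      // force-field potential energy
  double bias_energy; // bias terms only
};

// [[Rcpp::export]]
List cg_engine(NumericMatrix x0, double mass,
               IntegerVector bi, IntegerVector bj, NumericVector br0,
               double bond_k,
               IntegerVector ni, IntegerVector nj, NumericVector nr0,
               NumericVector ndepth, NumericVector nsigma,
               IntegerVector pi_, IntegerVector pj_, NumericVector pdepth,
               double prc, double pw,
               double ev_radius, double ev_k,
               IntegerVector ri, IntegerVector rj, NumericVector rr0,
               NumericVector rk,
               IntegerVector ga, IntegerVector gb, double rbias_k,
               double rbias_c0, double rbias_c1,
               NumericMatrix pc0_w, NumericVector pc0_ref, double pc0_k,
               double pc0_center,
               double dt, double gamma, double kT,
               int n_steps, int stride, int seed) {
  const int n = x0.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = x0(i, d);

  // bonded-pair lookup for excluded-volume exclusion
  std::vector<unsigned char> bonded((size_t)n * n, 0);
  for (int b = 0; b < bi.size(); ++b) {
    bonded[(size_t)bi[b] * n + bj[b]] = 1;
    bonded[(size_t)bj[b] * n + bi[b]] = 1;
  }
  // flat excluded-volume pair list, in the same (i, j) order as the
  // original nested loop so summation order (and thus trajectories)
  // are unchanged
  std::vector<int> evi, evj;
  evi.reserve((size_t)n * (n - 1) / 2);
  evj.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (!bonded[(size_t)i * n + j]) {
        evi.push_back(i);
        evj.push_back(j);
      }

  std::mt19937 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double sdv = std::sqrt(kT / mass);
  for (int i = 0; i < 3 * n; ++i) v[i] = sdv * gauss(rng);

  const bool has_pc0 = pc0_k > 0.0 && pc0_w.nrow() == n;
  const bool has_rbias = rbias_k > 0.0 && ga.size() > 0 && gb.size() > 0;
  const double ev2 = ev_radius * ev_radius;

  auto compute_forces = [&](double frac) -> Forces {
    Forces out{0.0, 0.0};
    std::fill(f.begin(), f.end(), 0.0);
    auto addpair = [&](int i, int j, double coef, double r, double dx,
                       double dy, double dz) {
      // coef = dV/dr / r
      f[3 * i] -= coef * dx; f[3 * i + 1] -= coef * dy;
      f[3 * i + 2] -= coef * dz;
      f[3 * j] += coef * dx; f[3 * j + 1] += coef * dy;
      f[3 * j + 2] += coef * dz;
      (void)r;
    };
    // bonds
    for (int b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - br0[b];
      out.energy += 0.5 * bond_k * dr * dr;
      addpair(i, j, bond_k * dr / r, r, dx, dy, dz);
    }
    // native Gaussian wells
    for (int c = 0; c < ni.size(); ++c) {
      int i = ni[c], j = nj[c];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - nr0[c];
      double sg = nsigma[c];
      if (std::fabs(dr) > 5.0 * sg) continue;
      double g = std::exp(-dr * dr / (2.0 * sg * sg));
      out.energy += -ndepth[c] * g;
      double dVdr = ndepth[c] * g * dr / (sg * sg);
      addpair(i, j, dVdr / r, r, dx, dy, dz);
    }
    // residue-base tapered wells
    for (int c = 0; c < pi_.size(); ++c) {
      int i = pi_[c], j = pj_[c];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= prc + pw) continue;
      if (r <= prc) {
        out.energy += -pdepth[c];
      } else {
        double s = 0.5 * (1.0 + std::cos(M_PI * (r - prc) / pw));
        out.energy += -pdepth[c] * s;
        double dVdr = pdepth[c] * 0.5 * (M_PI / pw) *
          std::sin(M_PI * (r - prc) / pw);
        addpair(i, j, dVdr / r, r, dx, dy, dz);
      }
    }
    // excluded volume (all non-bonded pairs)
    const size_t nev = evi.size();
    for (size_t c = 0; c < nev; ++c) {
      const int i = evi[c], j = evj[c];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ev2) continue;
      double r = std::sqrt(r2);
      double dr = r - ev_radius;
      out.energy += 0.5 * ev_k * dr * dr;
      addpair(i, j, ev_k * dr / r, r, dx, dy, dz);
    }
    // harmonic pair restraints (tether / sheet pairing)
    for (int c = 0; c < ri.size(); ++c) {
      int i = ri[c], j = rj[c];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - rr0[c];
      out.bias_energy += 0.5 * rk[c] * dr * dr;
      addpair(i, j, rk[c] * dr / r, r, dx, dy, dz);
    }
    // umbrella bias on the group-centroid distance
    if (has_rbias) {
      double ca[3] = {0, 0, 0}, cbv[3] = {0, 0, 0};
      for (int k = 0; k < ga.size(); ++k)
        for (int d = 0; d < 3; ++d) ca[d] += x[3 * ga[k] + d];
      for (int k = 0; k < gb.size(); ++k)
        for (int d = 0; d < 3; ++d) cbv[d] += x[3 * gb[k] + d];
      for (int d = 0; d < 3; ++d) {
        ca[d] /= ga.size();
        cbv[d] /= gb.size();
      }
      double dx = ca[0] - cbv[0], dy = ca[1] - cbv[1], dz = ca[2] - cbv[2];
      double s = std::sqrt(dx * dx + dy * dy + dz * dz);
      double c = rbias_c0 + (rbias_c1 - rbias_c0) * frac;
      double ds = s - c;
      out.bias_energy += 0.5 * rbias_k * ds * ds;
      double coef = rbias_k * ds / std::max(s, 1e-8);
      for (int k = 0; k < ga.size(); ++k) {
        f[3 * ga[k]] -= coef * dx / ga.size();
        f[3 * ga[k] + 1] -= coef * dy / ga.size();
        f[3 * ga[k] + 2] -= coef * dz / ga.size();
      }
      for (int k = 0; k < gb.size(); ++k) {
        f[3 * gb[k]] += coef * dx / gb.size();
        f[3 * gb[k] + 1] += coef * dy / gb.size();
        f[3 * gb[k] + 2] += coef * dz / gb.size();
      }
    }
    // harmonic bias on a fixed linear collective coordinate
    if (has_pc0) {
      double s = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          s += pc0_w(i, d) * (x[3 * i + d] - pc0_ref[3 * i + d]);
      double ds = s - pc0_center;
      out.bias_energy += 0.5 * pc0_k * ds * ds;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          f[3 * i + d] -= pc0_k * ds * pc0_w(i, d);
    }
    return out;
  };

  const int nf = n_steps / stride;
  NumericMatrix frames(nf, 3 * n);
  NumericVector energy(nf), bias_energy(nf), kinetic(nf);

  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0) ? std::sqrt((1.0 - c1 * c1) * kT / mass)
                                : 0.0;

  Forces fr = compute_forces(0.0);
  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double frac = (double)step / n_steps;
    // B
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] / mass;
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (gamma > 0)
      for (int i = 0; i < 3 * n; ++i)
        v[i] = c1 * v[i] + c2 * gauss(rng);
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // B
    fr = compute_forces(frac);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] / mass;

    if (step % stride == 0) {
      if (!std::isfinite(fr.energy))
        stop("step-size instability: energy non-finite at step %d", step);
      for (int i = 0; i < 3 * n; ++i) frames(rec, i) = x[i];
      energy[rec] = fr.energy;
      bias_energy[rec] = fr.bias_energy;
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * mass * v[i] * v[i];
      kinetic[rec] = ke;
      ++rec;
    }
  }

  return List::create(_["frames"] = frames, _["energy"] = energy,
                      _["bias_energy"] = bias_energy,
                      _["kinetic"] = kinetic);
}
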