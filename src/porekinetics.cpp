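#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation of a tabulated potential; zero outside the table.
static inline double interp_u(double z, const NumericVector& zs,
                              const NumericVector& us) {
  int n = zs.size();
  if (n == 0 || z <= zs[0] || z >= zs[n - 1]) {
    if (n == 0) return 0.0;
    if (z <= zs[0]) return us[0];
    return us[n - 1];
  }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (zs[mid] <= z) lo = mid; else hi = mid; }
  double w = (z - zs[lo]) / (zs[hi] - zs[lo]);
  return us[lo] * (1 - w) + us[hi] * w;
}

// Piecewise-constant force from a piecewise-linear potential table.
static inline double force_u(double z, const NumericVector& zs,
                             const NumericVector& us) {
  int n = zs.size();
  if (n < 2 || z <= zs[0] || z >= zs[n - 1]) return 0.0;
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (zs[mid] <= z) lo = mid; else hi = mid; }
  return -(us[hi] - us[lo]) / (zs[hi] - zs[lo]);
}

// Overdamped Langevin dynamics of non-interacting ions on a periodic
// z-domain.  The applied-field force acts only inside [span_lo, span_hi]
// (evaluated on the wrapped coordinate); the tabulated potential force is
// also periodic.  Returns unwrapped z, recorded every `record_every`
// steps (including step 0).  Uses the R RNG.
// [[Rcpp::export]]
NumericMatrix langevin_z_cpp(NumericVector z0, int n_steps, double dt,
                             double D, double kT, double f_field,
                             double span_lo, double span_hi,
                             NumericVector u_z, NumericVector u_val,
                             double domain_lo, double domain_len,
                             int record_every) {
  int n_ions = z0.size();
  int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, n_ions);
  std::vector<double> z(z0.begin(), z0.end());
  double sig = std::sqrt(2.0 * D * dt);
  double mob = D / kT;
  for (int i = 0; i < n_ions; ++i) out(0, i) = z[i];
  int rec = 1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n_ions; ++i) {
      double w = z[i] - domain_lo;
      w -= domain_len * std::floor(w / domain_len);
      w += domain_lo;  // wrapped into [domain_lo, domain_lo + L)
      double f = force_u(w, u_z, u_val);
      if (w >= span_lo && w <= span_hi) f += f_field;
      z[i] += mob * f * dt + sig * norm_rand();
    }
    if (s % record_every == 0) {
      for (int i = 0; i < n_ions; ++i) out(rec, i) = z[i];
      ++rec;
    }
  }
  return out;
}

// Random-walk Metropolis sampling of exp(-U(z)/kT) on [z_min, z_max] with
// reflecting boundaries; U given as a piecewise-linear table.
// [[Rcpp::export]]
NumericVector metropolis_z_cpp(int n_samples, int burn_in, int thin,
                               double step_sd, double z_min, double z_max,
                               NumericVector u_z, NumericVector u_val,
                               double kT, double z_start) {
  NumericVector out(n_samples);
  double z = z_start, uz = interp_u(z, u_z, u_val);
  long total = (long)burn_in + (long)n_samples * thin;
  int k = 0;
  for (long s = 0; s < total; ++s) {
    double zp = z + step_sd * norm_rand();
    // reflect at the boundaries
    while (zp < z_min || zp > z_max) {
      if (zp < z_min) zp = 2 * z_min - zp;
      if (zp > z_max) zp = 2 * z_max - zp;
    }
    double up = interp_u(zp, u_z, u_val);
    if (up <= uz || unif_rand() < std::exp(-(up - uz) / kT)) { z = zp; uz = up; }
    if (s >= burn_in && (s - burn_in) % thin == thin - 1 && k < n_samples)
      out[k++] = z;
  }
  return out;
}

// Largest sphere centred in the slice plane touching no atom: maximize
// f(c) = min_i (|c - atom_i| - vdw_i) by simulated annealing.  Atom
// coordinates are given in the pore frame (px, py in-plane, pz axial);
// the slice sits at axial coordinate z.  Returns (cx, cy, radius).
// [[Rcpp::export]]
NumericVector anneal_slice_cpp(NumericVector px, NumericVector py,
                               NumericVector pz, NumericVector vdw,
                               double z, double cx0, double cy0,
                               int n_steps, double start_T, double cool_rate,
                               double max_radius, double max_shift) {
  int n = px.size();
  auto eval = [&](double cx, double cy) {
    double best = max_radius;
    for (int i = 0; i < n; ++i) {
      double dx = cx - px[i], dy = cy - py[i], dz = z - pz[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[i];
      if (d < best) best = d;
    }
    return best;
  };
  double cx = cx0, cy = cy0, f = eval(cx, cy);
  double bx = cx, by = cy, bf = f;
  double T = start_T;
  for (int s = 0; s < n_steps; ++s) {
    double nx = cx + T * norm_rand();
    double ny = cy + T * norm_rand();
    // stay near the seed centre: keeps the probe inside the pore lumen
    // (the objective grows again outside the wall, which would otherwise
    // let the sphere escape to bulk through a thin shell of atoms)
    double sx = nx - cx0, sy = ny - cy0;
    if (sx * sx + sy * sy > max_shift * max_shift) { T *= cool_rate; continue; }
    double nf = eval(nx, ny);
    if (nf > f || unif_rand() < std::exp((nf - f) / std::max(T, 1e-12))) {
      cx = nx; cy = ny; f = nf;
      if (f > bf) { bf = f; bx = cx; by = cy; }
    }
    T *= cool_rate;
  }
  return NumericVector::create(bx, by, bf);
}

// Three-compartment permeation state machine for one ion trace.
// States: 1 above, -1 below, 2 in pore from above, -2 in pore from below,
// 0 initial inside-pore (no entry side, cannot produce an event).
// Events need a complete traversal; direction -1 = inward (+z to -z).
// Returns a matrix with columns (t_enter, t_exit, direction).
// [[Rcpp::export]]
NumericMatrix detect_events_cpp(NumericVector z, NumericVector t,
                                double upper, double lower, double hys) {
  int n = z.size();
  std::vector<double> te, tx, dir;
  int state;
  if (z[0] >= upper) state = 1;
  else if (z[0] <= lower) state = -1;
  else state = 0;
  double t_enter = NA_REAL;
  for (int i = 1; i < n; ++i) {
    double zi = z[i];
    switch (state) {
    case 1:
      if (zi <= lower) {  // jumped clean through in one step
        te.push_back(t[i]); tx.push_back(t[i]); dir.push_back(-1);
        state = -1;
      } else if (zi < upper - hys) { state = 2; t_enter = t[i]; }
      break;
    case -1:
      if (zi >= upper) {
        te.push_back(t[i]); tx.push_back(t[i]); dir.push_back(1);
        state = 1;
      } else if (zi > lower + hys) { state = -2; t_enter = t[i]; }
      break;
    case 2:
      if (zi <= lower) {
        te.push_back(t_enter); tx.push_back(t[i]); dir.push_back(-1);
        state = -1;
      } else if (zi >= upper) state = 1;  // re-entry, no event
      break;
    case -2:
      if (zi >= upper) {
        te.push_back(t_enter); tx.push_back(t[i]); dir.push_back(1);
        state = 1;
      } else if (zi <= lower) state = -1;
      break;
    default:  // 0: started inside the pore
      if (zi >= upper) state = 1;
      else if (zi <= lower) state = -1;
    }
  }
  NumericMatrix out(te.size(), 3);
  for (size_t k = 0; k < te.size(); ++k) {
    out(k, 0) = te[k]; out(k, 1) = tx[k]; out(k, 2) = dir[k];
  }
  return out;
}
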