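// Metropolis Monte Carlo core for a driven bead-rod chain.
//
// Joints are stored as an (N+1) x 3 matrix in units of the bond length.
// Joint 0 is anchored at the origin and never moves. All randomness draws
// from R's RNG so set.seed() on the R side gives full determinism.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Overlap slack: non-consecutive joints overlap iff d < l_b * (1 - SLACK),
// so exactly-touching spheres (d == l_b) never trigger.
static const double OVERLAP_SLACK = 1e-12;

// --- geometry helpers -------------------------------------------------------

// Rodrigues rotation of point p about unit axis u anchored at o, by angle.
static inline void rotate_point(double* p, const double* o, const double* u,
                                double c, double s) {
  double v0 = p[0] - o[0], v1 = p[1] - o[1], v2 = p[2] - o[2];
  double dot = u[0] * v0 + u[1] * v1 + u[2] * v2;
  double cx0 = u[1] * v2 - u[2] * v1;
  double cx1 = u[2] * v0 - u[0] * v2;
  double cx2 = u[0] * v1 - u[1] * v0;
  double omc = 1.0 - c;
  p[0] = o[0] + v0 * c + cx0 * s + u[0] * dot * omc;
  p[1] = o[1] + v1 * c + cx1 * s + u[1] * dot * omc;
  p[2] = o[2] + v2 * c + cx2 * s + u[2] * dot * omc;
}

// Rotate rows [from, to] (0-based, inclusive) of joints in place.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_segment(NumericMatrix joints, int from, int to,
                                 NumericVector origin, NumericVector axis,
                                 double angle) {
  NumericMatrix out = clone(joints);
  double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                         axis[2] * axis[2]);
  if (nrm <= 0) stop("degenerate rotation axis");
  double u[3] = {axis[0] / nrm, axis[1] / nrm, axis[2] / nrm};
  double o[3] = {origin[0], origin[1], origin[2]};
  double c = std::cos(angle), s = std::sin(angle);
  for (int i = from; i <= to; ++i) {
    double p[3] = {out(i, 0), out(i, 1), out(i, 2)};
    rotate_point(p, o, u, c, s);
    out(i, 0) = p[0];
    out(i, 1) = p[1];
    out(i, 2) = p[2];
  }
  return out;
}

// --- overlap ----------------------------------------------------------------

// Full O(M^2) hard-sphere check: TRUE iff some non-consecutive pair of
// joints sits closer than l_b (sphere radius l_b / 2 on every joint).
// [[Rcpp::export]]
bool cpp_has_overlap(NumericMatrix joints, double lb) {
  int m = joints.nrow();
  double thr = lb * (1.0 - OVERLAP_SLACK);
  double thr2 = thr * thr;
  for (int i = 0; i < m - 2; ++i) {
    for (int j = i + 2; j < m; ++j) {
      double dx = joints(i, 0) - joints(j, 0);
      double dy = joints(i, 1) - joints(j, 1);
      double dz = joints(i, 2) - joints(j, 2);
      if (dx * dx + dy * dy + dz * dz < thr2) return true;
    }
  }
  return false;
}

// Overlap test restricted to moved rows [from, to] against the rest.
// A rigid rotation preserves distances inside the moved block, so only
// moved-vs-unmoved pairs can create a new overlap.
static bool overlap_partial(const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& z, int m, int from,
                            int to, double thr2) {
  // moved rows [from, to] against unmoved [0, from-1] and [to+1, m-1];
  // the consecutive pairs (from-1, from) and (to, to+1) are skipped
  for (int i = from; i <= to; ++i) {
    double xi = x[i], yi = y[i], zi = z[i];
    int jend = (i == from) ? from - 1 : from;
    for (int j = 0; j < jend; ++j) {
      double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      if (dx * dx + dy * dy + dz * dz < thr2) return true;
    }
    int jstart = (i == to) ? to + 2 : to + 1;
    for (int j = jstart; j < m; ++j) {
      double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      if (dx * dx + dy * dy + dz * dz < thr2) return true;
    }
  }
  return false;
}

// --- energy -----------------------------------------------------------------

// E = sum_{i=1}^{N-1} kappa (1 - t_{i-1}.t_i)
//     - f  l_b sum_{i=0}^{N-1} (t_i . x)
//     - gamma l_b sum_{i=0}^{N-1} z_i (t_i . x),   z_i = z of joint i
// with t_i = (r_{i+1} - r_i) / l_b. Returns c(bending, stretch, shear).
// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericMatrix joints, double kappa, double f,
                               double gamma, double lb) {
  int m = joints.nrow();
  int n = m - 1;  // bonds
  double bend = 0.0, stretch = 0.0, shear = 0.0;
  double px = 0, py = 0, pz = 0;  // previous tangent
  for (int i = 0; i < n; ++i) {
    double tx = (joints(i + 1, 0) - joints(i, 0)) / lb;
    double ty = (joints(i + 1, 1) - joints(i, 1)) / lb;
    double tz = (joints(i + 1, 2) - joints(i, 2)) / lb;
    if (i > 0) bend += kappa * (1.0 - (px * tx + py * ty + pz * tz));
    stretch -= f * lb * tx;
    shear -= gamma * lb * joints(i, 2) * tx;
    px = tx;
    py = ty;
    pz = tz;
  }
  return NumericVector::create(_["bending"] = bend, _["stretch"] = stretch,
                               _["shear"] = shear);
}

static inline double energy_total(const std::vector<double>& x,
                                  const std::vector<double>& y,
                                  const std::vector<double>& z, int m,
                                  double kappa, double f, double gamma,
                                  double lb) {
  int n = m - 1;
  double e = 0.0;
  double px = 0, py = 0, pz = 0;
  for (int i = 0; i < n; ++i) {
    double tx = (x[i + 1] - x[i]) / lb;
    double ty = (y[i + 1] - y[i]) / lb;
    double tz = (z[i + 1] - z[i]) / lb;
    if (i > 0) e += kappa * (1.0 - (px * tx + py * ty + pz * tz));
    e -= f * lb * tx;
    e -= gamma * lb * z[i] * tx;
    px = tx;
    py = ty;
    pz = tz;
  }
  return e;
}

// --- MC driver --------------------------------------------------------------

// Runs (n_equil + n_sample) sweeps of N attempted moves each, retaining one
// configuration every `interval` sweeps of the sampling phase. Move mix is
// 50/50 crankshaft/pivot (pivot only for N = 2). Proposals that violate
// hard-sphere self-avoidance are rejected outright; otherwise standard
// Metropolis acceptance min(1, exp(-dE)).
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix joints0, double kappa, double f, double gamma,
                double lb, int n_equil, int n_sample, int interval,
                double max_angle, bool self_avoid, bool tune) {
  int m = joints0.nrow();
  int n = m - 1;
  std::vector<double> x(m), y(m), z(m);
  for (int i = 0; i < m; ++i) {
    x[i] = joints0(i, 0);
    y[i] = joints0(i, 1);
    z[i] = joints0(i, 2);
  }
  double thr = lb * (1.0 - OVERLAP_SLACK);
  double thr2 = thr * thr;
  double e_cur = energy_total(x, y, z, m, kappa, f, gamma, lb);
  double amp = max_angle;

  int n_keep = n_sample / interval;
  NumericVector samples(static_cast<R_xlen_t>(n_keep) * m * 3);
  samples.attr("dim") = IntegerVector::create(m, 3, n_keep);
  NumericVector energy_trace(n_equil + n_sample);
  double acc_crank = 0, try_crank = 0, acc_pivot = 0, try_pivot = 0;
  double acc_equil = 0, try_equil = 0;

  std::vector<double> bx(m), by(m), bz(m);  // backup of moved rows
  RNGScope scope;

  int total_sweeps = n_equil + n_sample;
  int kept = 0;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      bool crank = (n >= 3) && (unif_rand() < 0.5);
      int from, to;
      double o[3], u[3];
      if (crank) {
        // a in 0..N-2, b in a+2..N; rotate joints strictly between a and b
        int a = static_cast<int>(unif_rand() * (n - 1));
        if (a > n - 2) a = n - 2;
        int nb = n - a - 1;  // count of candidates a+2..N
        int b = a + 2 + static_cast<int>(unif_rand() * nb);
        if (b > n) b = n;
        from = a + 1;
        to = b - 1;
        o[0] = x[a];
        o[1] = y[a];
        o[2] = z[a];
        double ux = x[b] - x[a], uy = y[b] - y[a], uz = z[b] - z[a];
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        u[0] = ux / nrm;
        u[1] = uy / nrm;
        u[2] = uz / nrm;
      } else {
        // pivot joint p in 0..N-1, rotate tail p+1..N about a random axis
        int p = static_cast<int>(unif_rand() * n);
        if (p > n - 1) p = n - 1;
        from = p + 1;
        to = n;
        o[0] = x[p];
        o[1] = y[p];
        o[2] = z[p];
        // uniform random unit vector (Marsaglia via normals)
        double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (nrm < 1e-300) { ux = 1; uy = 0; uz = 0; nrm = 1; }
        u[0] = ux / nrm;
        u[1] = uy / nrm;
        u[2] = uz / nrm;
      }
      double angle = (2.0 * unif_rand() - 1.0) * amp;
      double c = std::cos(angle), s = std::sin(angle);
      for (int i = from; i <= to; ++i) {
        bx[i] = x[i];
        by[i] = y[i];
        bz[i] = z[i];
        double p3[3] = {x[i], y[i], z[i]};
        rotate_point(p3, o, u, c, s);
        x[i] = p3[0];
        y[i] = p3[1];
        z[i] = p3[2];
      }
      // acceptance = (Metropolis on dE) AND (no hard-sphere overlap);
      // the O(N) energy test runs first, the costlier overlap scan only
      // for energetically accepted proposals
      bool reject = false;
      double e_new = energy_total(x, y, z, m, kappa, f, gamma, lb);
      double de = e_new - e_cur;
      if (de > 0 && unif_rand() >= std::exp(-de)) reject = true;
      if (!reject && self_avoid &&
          overlap_partial(x, y, z, m, from, to, thr2))
        reject = true;
      if (reject) {
        for (int i = from; i <= to; ++i) {
          x[i] = bx[i];
          y[i] = by[i];
          z[i] = bz[i];
        }
      } else {
        e_cur = e_new;
      }
      if (sweep >= n_equil) {
        if (crank) {
          try_crank += 1;
          if (!reject) acc_crank += 1;
        } else {
          try_pivot += 1;
          if (!reject) acc_pivot += 1;
        }
      } else {
        try_equil += 1;
        if (!reject) acc_equil += 1;
      }
    }
    energy_trace[sweep] = e_cur;
    // optional amplitude tuning toward ~50% acceptance, frozen at the
    // midpoint of equilibration so sampling uses a fixed move amplitude
    if (tune && sweep < n_equil / 2 && (sweep + 1) % 100 == 0 &&
        try_equil > 0) {
      double rate = acc_equil / try_equil;
      amp *= (rate > 0.5) ? 1.15 : 0.87;
      if (amp > M_PI) amp = M_PI;
      if (amp < 1e-3) amp = 1e-3;
      acc_equil = 0;
      try_equil = 0;
    }
    if (sweep >= n_equil && (sweep - n_equil + 1) % interval == 0 &&
        kept < n_keep) {
      R_xlen_t off = static_cast<R_xlen_t>(kept) * m * 3;
      for (int i = 0; i < m; ++i) {
        samples[off + i] = x[i];
        samples[off + m + i] = y[i];
        samples[off + 2 * m + i] = z[i];
      }
      ++kept;
    }
  }

  double rate_c = try_crank > 0 ? acc_crank / try_crank : NA_REAL;
  double rate_p = try_pivot > 0 ? acc_pivot / try_pivot : NA_REAL;
  double rate_e = try_equil > 0 ? acc_equil / try_equil : NA_REAL;
  return List::create(
      _["samples"] = samples, _["energy_trace"] = energy_trace,
      _["acceptance"] = NumericVector::create(_["crankshaft"] = rate_c,
                                              _["pivot"] = rate_p),
      _["acceptance_equil"] = rate_e, _["max_angle_final"] = amp,
      _["n_kept"] = kept);
}
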