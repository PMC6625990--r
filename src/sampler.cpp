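// Monte-Carlo pivot sampler for a flexible Ca tail on a rigid core.
//
// Moves are pivot rotations about a tail Ca: all residues downstream of the
// pivot rotate rigidly about it, so virtual bond lengths are preserved
// exactly by construction. Stage 1 anneals large pivots under a geometric
// temperature schedule; stage 2 applies small pivots at the final
// temperature followed by greedy per-pivot line-search minimization.
//
// Energy: w_clash * sum_{d_ij < dmin, |i-j|>1} (dmin - d_ij)^2
//       + w_elec  * sum_{charged pairs, |i-j|>1} q_i q_j exp(-d_ij/lambda)/d_ij
//       + w_xl    * sum_links flat_harmonic(d)

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Params {
  double w_clash, w_elec, w_xl, dmin, lambda;
};

inline double flat_harm(double d, double edge, double sigma) {
  if (d <= edge) return 0.0;
  double t = (d - edge) / sigma;
  return t * t;
}

// pair energy (clash + electrostatics) between sites i and j
inline double pair_e(const NumericMatrix& X, int i, int j,
                     const NumericVector& q, const Params& P) {
  double dx = X(i, 0) - X(j, 0);
  double dy = X(i, 1) - X(j, 1);
  double dz = X(i, 2) - X(j, 2);
  double d2 = dx * dx + dy * dy + dz * dz;
  double e = 0.0;
  double qq = q[i] * q[j];
  bool need_elec = (P.w_elec != 0.0) && (qq != 0.0);
  if (d2 < P.dmin * P.dmin || need_elec) {
    double d = std::sqrt(d2);
    if (d < P.dmin) {
      double t = P.dmin - d;
      e += P.w_clash * t * t;
    }
    if (need_elec && d > 1e-9)
      e += P.w_elec * qq * std::exp(-d / P.lambda) / d;
  }
  return e;
}

inline double link_dist(const NumericMatrix& X, int i, int j) {
  double dx = X(i, 0) - X(j, 0);
  double dy = X(i, 1) - X(j, 1);
  double dz = X(i, 2) - X(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// total energy over all nonadjacent pairs plus all restraints
double full_energy(const NumericMatrix& X, const NumericVector& q,
                   const IntegerMatrix& links, const NumericVector& edge,
                   const NumericVector& sigma, const Params& P) {
  int n = X.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      e += pair_e(X, i, j, q, P);
  for (int l = 0; l < links.nrow(); ++l)
    e += P.w_xl * flat_harm(link_dist(X, links(l, 0), links(l, 1)),
                            edge[l], sigma[l]);
  return e;
}

// energy of interactions crossing the boundary between static [0, m0) and
// moved [m0, n); the bonded pair (m0-1, m0) is adjacent and excluded
double cross_energy(const NumericMatrix& X, int m0, const NumericVector& q,
                    const IntegerMatrix& links, const NumericVector& edge,
                    const NumericVector& sigma, const Params& P) {
  int n = X.nrow();
  double e = 0.0;
  for (int i = 0; i < m0; ++i)
    for (int j = m0; j < n; ++j) {
      if (i == m0 - 1 && j == m0) continue;
      e += pair_e(X, i, j, q, P);
    }
  for (int l = 0; l < links.nrow(); ++l) {
    bool a = links(l, 0) >= m0, b = links(l, 1) >= m0;
    if (a != b)
      e += P.w_xl * flat_harm(link_dist(X, links(l, 0), links(l, 1)),
                              edge[l], sigma[l]);
  }
  return e;
}

// rotate rows [m0, n) about point X[pivot] by angle about unit axis u
void rotate_block(NumericMatrix& X, int pivot, int m0, const double* u,
                  double angle) {
  double c = std::cos(angle), s = std::sin(angle);
  double px = X(pivot, 0), py = X(pivot, 1), pz = X(pivot, 2);
  int n = X.nrow();
  for (int i = m0; i < n; ++i) {
    double vx = X(i, 0) - px, vy = X(i, 1) - py, vz = X(i, 2) - pz;
    double dot = u[0] * vx + u[1] * vy + u[2] * vz;
    double cx = u[1] * vz - u[2] * vy;
    double cy = u[2] * vx - u[0] * vz;
    double cz = u[0] * vy - u[1] * vx;
    X(i, 0) = px + vx * c + cx * s + u[0] * dot * (1 - c);
    X(i, 1) = py + vy * c + cy * s + u[1] * dot * (1 - c);
    X(i, 2) = pz + vz * c + cz * s + u[2] * dot * (1 - c);
  }
}

void rand_axis(double* u) {
  double nrm = 0.0;
  do {
    u[0] = R::norm_rand(); u[1] = R::norm_rand(); u[2] = R::norm_rand();
    nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  } while (nrm < 1e-12);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

}  // namespace

// [[Rcpp::export(name = ".sample_tail_cpp")]]
List sample_tail_cpp(NumericMatrix coords, IntegerVector pivot_ok,
                     NumericVector charges, IntegerMatrix links,
                     NumericVector link_edge, NumericVector link_sigma,
                     double w_clash, double w_elec, double w_xl,
                     double dmin, double lambda,
                     int stage1_steps, int stage2_steps,
                     double T_start, double T_end,
                     double max_ang1, double max_ang2,
                     int n_scramble, int minimize_sweeps) {
  NumericMatrix X = clone(coords);
  Params P = {w_clash, w_elec, w_xl, dmin, lambda};
  int npiv = pivot_ok.size();
  if (npiv == 0) stop("no pivot sites available");
  double u[3];
  // scramble: forced random large pivots to erase the start conformation
  for (int k = 0; k < n_scramble; ++k) {
    int p = pivot_ok[(int)(R::unif_rand() * npiv) % npiv];
    rand_axis(u);
    rotate_block(X, p, p + 1, u, R::unif_rand() * 2.0 * M_PI - M_PI);
  }
  int accepted = 0, rejected_stage = 0;
  int total_steps = stage1_steps + stage2_steps;
  for (int k = 0; k < total_steps; ++k) {
    bool stage1 = k < stage1_steps;
    double T;
    if (stage1) {
      double frac = stage1_steps > 1 ? (double)k / (stage1_steps - 1) : 1.0;
      T = T_start * std::pow(T_end / T_start, frac);
    } else {
      T = T_end;
    }
    double maxang = stage1 ? max_ang1 : max_ang2;
    int p = pivot_ok[(int)(R::unif_rand() * npiv) % npiv];
    rand_axis(u);
    double ang = (R::unif_rand() * 2.0 - 1.0) * maxang;
    double e_old = cross_energy(X, p + 1, charges, links, link_edge,
                                link_sigma, P);
    rotate_block(X, p, p + 1, u, ang);
    double e_new = cross_energy(X, p + 1, charges, links, link_edge,
                                link_sigma, P);
    double dE = e_new - e_old;
    if (dE <= 0.0 || R::unif_rand() < std::exp(-dE / T)) {
      ++accepted;
    } else {
      rotate_block(X, p, p + 1, u, -ang);  // reject: undo
      ++rejected_stage;
    }
  }
  // greedy minimization: per-pivot golden-section line search
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  for (int sweep = 0; sweep < minimize_sweeps; ++sweep) {
    for (int pi = 0; pi < npiv; ++pi) {
      int p = pivot_ok[pi];
      rand_axis(u);
      double e0 = cross_energy(X, p + 1, charges, links, link_edge,
                               link_sigma, P);
      double lo = -max_ang2, hi = max_ang2;
      double a = hi - gr * (hi - lo), b = lo + gr * (hi - lo);
      double fa, fb;
      rotate_block(X, p, p + 1, u, a);
      fa = cross_energy(X, p + 1, charges, links, link_edge, link_sigma, P);
      rotate_block(X, p, p + 1, u, b - a);
      fb = cross_energy(X, p + 1, charges, links, link_edge, link_sigma, P);
      rotate_block(X, p, p + 1, u, -b);  // back to 0
      for (int it = 0; it < 16; ++it) {
        if (fa < fb) {
          hi = b; b = a; fb = fa;
          a = hi - gr * (hi - lo);
          rotate_block(X, p, p + 1, u, a);
          fa = cross_energy(X, p + 1, charges, links, link_edge,
                            link_sigma, P);
          rotate_block(X, p, p + 1, u, -a);
        } else {
          lo = a; a = b; fa = fb;
          b = lo + gr * (hi - lo);
          rotate_block(X, p, p + 1, u, b);
          fb = cross_energy(X, p + 1, charges, links, link_edge,
                            link_sigma, P);
          rotate_block(X, p, p + 1, u, -b);
        }
      }
      double best = 0.5 * (lo + hi);
      rotate_block(X, p, p + 1, u, best);
      double fbest = cross_energy(X, p + 1, charges, links, link_edge,
                                  link_sigma, P);
      if (fbest >= e0 - 1e-12)
        rotate_block(X, p, p + 1, u, -best);  // no improvement: undo
    }
  }
  double energy = full_energy(X, charges, links, link_edge, link_sigma, P);
  return List::create(_["coords"] = X, _["energy"] = energy,
                      _["accepted"] = accepted);
}

// [[Rcpp::export(name = ".tail_energy_cpp")]]
List tail_energy_cpp(NumericMatrix coords, NumericVector charges,
                     IntegerMatrix links, NumericVector link_edge,
                     NumericVector link_sigma, double w_clash,
                     double w_elec, double w_xl, double dmin,
                     double lambda) {
  int n = coords.nrow();
  double e_clash = 0.0, e_elec = 0.0, e_xl = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < dmin) {
        double t = dmin - d;
        e_clash += t * t;
      }
      double qq = charges[i] * charges[j];
      if (qq != 0.0 && d > 1e-9)
        e_elec += qq * std::exp(-d / lambda) / d;
    }
  for (int l = 0; l < links.nrow(); ++l)
    e_xl += flat_harm(link_dist(coords, links(l, 0), links(l, 1)),
                      link_edge[l], link_sigma[l]);
  return List::create(_["clash"] = w_clash * e_clash,
                      _["elec"] = w_elec * e_elec,
                      _["xl"] = w_xl * e_xl,
                      _["total"] = w_clash * e_clash + w_elec * e_elec +
                                   w_xl * e_xl);
}

// [[Rcpp::export(name = ".debye_cpp")]]
NumericVector debye_cpp(NumericMatrix coords, NumericVector q,
                        NumericVector f) {
  int n = coords.nrow(), nq = q.size();
  NumericVector I(nq);
  double diag = 0.0;
  for (int i = 0; i < n; ++i) diag += f[i] * f[i];
  for (int k = 0; k < nq; ++k) I[k] = diag;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ff = 2.0 * f[i] * f[j];
      for (int k = 0; k < nq; ++k) {
        double qd = q[k] * d;
        I[k] += ff * (qd == 0.0 ? 1.0 : std::sin(qd) / qd);
      }
    }
  return I;
}
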