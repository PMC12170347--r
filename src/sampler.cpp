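// Core numerical kernels for the blocked Gibbs reconstruction sampler.
//
// All random numbers come from R's generator (RNGScope), so set.seed()
// at the R level makes every routine reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log P(o | y) under the perturbation mechanism:
//   eps ~ pmf on {-d..d};  o' = max(0, y + eps);  publish 0 if o' <= tau,
//   else o'.  True zeros publish as zero when zero_fixed.
static double pert_ll(int o, int y, const NumericVector& pmf, int d, int tau,
                      bool zero_fixed) {
  if (zero_fixed && y == 0) return (o == 0) ? 0.0 : R_NegInf;
  if (o == 0) {
    // every eps with max(0, y + eps) <= tau collapses to a published 0;
    // since tau >= 0 this is exactly eps <= tau - y
    double s = 0.0;
    for (int e = -d; e <= d; ++e)
      if (y + e <= tau) s += pmf[e + d];
    return (s > 0.0) ? std::log(s) : R_NegInf;
  }
  if (o <= tau) return R_NegInf;  // counts in 1..tau are never published
  int e = o - y;
  if (e < -d || e > d || pmf[e + d] <= 0.0) return R_NegInf;
  return std::log(pmf[e + d]);
}

// Soft-support version used inside the count sweeps: infeasible (o, y)
// pairs get a steep linear penalty in their integer distance from the
// feasible set instead of -Inf, so a chain initialised outside the joint
// support hill-climbs into it (and once inside, essentially never leaves:
// one unit of infeasibility costs e^-100 in posterior mass).
static double pert_ll_soft(int o, int y, const NumericVector& pmf, int d,
                           int tau, bool zero_fixed) {
  double ll = pert_ll(o, y, pmf, d, tau, zero_fixed);
  if (std::isfinite(ll)) return ll;
  int dist;
  if (zero_fixed && y == 0) dist = o;
  else if (o == 0) dist = y - (tau + d);
  else if (o <= tau) dist = 1;
  else dist = std::abs(o - y) - d;
  if (dist < 1) dist = 1;  // e.g. zero-probability pmf entries
  return -100.0 * dist;
}

// [[Rcpp::export]]
NumericVector cpp_pert_loglik(IntegerVector o, IntegerVector y,
                              NumericVector pmf, int d, int tau,
                              bool zero_fixed) {
  R_xlen_t n = o.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = pert_ll(o[i], y[i], pmf, d, tau, zero_fixed);
  return out;
}

// Binomial log-likelihood of the latent counts under the three-age logit
// model.  Columns of y/nst: [0] youngest, [1] middle (mixture), [2] oldest.
// eta_young = b0y + off + u,  eta_old = b0o + off + u,
// eta_mid   = w * eta_young + (1 - w) * eta_old.
static double binom_ll(const IntegerMatrix& y, const IntegerMatrix& nst,
                       const NumericVector& off, const NumericVector& u,
                       double b0y, double b0o, double w) {
  int n = y.nrow();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double base = off[i] + u[i];
    double ey = b0y + base;
    double eo = b0o + base;
    double em = w * ey + (1.0 - w) * eo;
    if (nst(i, 0) > 0)
      ll += R::dbinom(y(i, 0), nst(i, 0), 1.0 / (1.0 + std::exp(-ey)), 1);
    if (nst(i, 1) > 0)
      ll += R::dbinom(y(i, 1), nst(i, 1), 1.0 / (1.0 + std::exp(-em)), 1);
    if (nst(i, 2) > 0)
      ll += R::dbinom(y(i, 2), nst(i, 2), 1.0 / (1.0 + std::exp(-eo)), 1);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_binom_loglik(IntegerMatrix y, IntegerMatrix nst, NumericVector off,
                        NumericVector u, double b0y, double b0o, double w) {
  return binom_ll(y, nst, off, u, b0y, b0o, w);
}

// One or more Metropolis sweeps over the latent fine-unit counts.
//
// y, nst, prob: n_fine x 3 (ages).  prob holds the current model
// probabilities expit(eta).  gid: per observed partition, a 1-based group
// index of length n_fine.  agg/obs: per partition, (n_groups x 3) integer
// matrices of current latent aggregates and published positive counts.
// Proposals are y +/- k with k ~ 1 + Geometric(geom_p); moves outside
// [0, nst] are rejected.  The perturbation term uses the soft-support
// likelihood (see pert_ll_soft) so chains initialised outside the joint
// support of all published cells repair themselves during burn-in.
//
// Modifies y and the agg matrices IN PLACE (callers pass fresh copies via
// the R wrapper).  If trace = true, records y after every sweep, columns in
// cell order (unit fastest, then age).
// [[Rcpp::export]]
List cpp_sweep_counts(IntegerMatrix y, IntegerMatrix nst, NumericMatrix prob,
                      List gid, List agg, List obs, NumericVector pmf, int d,
                      int tau, bool zero_fixed, double geom_p, int n_sweeps,
                      bool trace) {
  int n = y.nrow();
  int P = gid.size();
  std::vector<IntegerVector> G(P);
  std::vector<IntegerMatrix> A(P), O(P);
  for (int p = 0; p < P; ++p) {
    G[p] = as<IntegerVector>(gid[p]);
    A[p] = as<IntegerMatrix>(agg[p]);
    O[p] = as<IntegerMatrix>(obs[p]);
  }
  long accept = 0, total = 0;
  IntegerMatrix tr;
  if (trace) tr = IntegerMatrix(n_sweeps, n * 3);

  for (int s = 0; s < n_sweeps; ++s) {
    for (int a = 0; a < 3; ++a) {
      for (int i = 0; i < n; ++i) {
        int ni = nst(i, a);
        if (ni <= 0) continue;
        ++total;
        int yi = y(i, a);
        int k = 1 + (int)R::rgeom(geom_p);
        int delta = (unif_rand() < 0.5) ? -k : k;
        int yp = yi + delta;
        if (yp < 0 || yp > ni) continue;

        double lr = 0.0;
        for (int p = 0; p < P; ++p) {
          int g = G[p][i] - 1;
          int o = O[p](g, a);
          int ag = A[p](g, a);
          lr += pert_ll_soft(o, ag + delta, pmf, d, tau, zero_fixed) -
                pert_ll_soft(o, ag, pmf, d, tau, zero_fixed);
        }
        double pr = prob(i, a);
        lr += R::dbinom(yp, ni, pr, 1) - R::dbinom(yi, ni, pr, 1);
        bool acc = std::isfinite(lr) && (std::log(unif_rand()) < lr);
        if (acc) {
          y(i, a) = yp;
          for (int p = 0; p < P; ++p) A[p](G[p][i] - 1, a) += delta;
          ++accept;
        }
      }
    }
    if (trace)
      for (int a = 0; a < 3; ++a)
        for (int i = 0; i < n; ++i) tr(s, a * n + i) = y(i, a);
  }
  List out = List::create(_["accept"] = (double)accept,
                          _["total"] = (double)total);
  if (trace) out["trace"] = tr;
  return out;
}

// Elliptical slice sampling update of the spatial field u under its
// Gaussian prior (nu is a fresh prior draw) and the binomial likelihood.
// Returns the new field and the accepted angle theta (0 keeps the current
// state), so callers tracking a whitened representation can rotate it by
// the same angle.  Always terminates because theta -> 0 recovers u.
// [[Rcpp::export]]
List cpp_ess_field(NumericVector u, NumericVector nu, NumericVector off,
                   double b0y, double b0o, double w, IntegerMatrix y,
                   IntegerMatrix nst) {
  int n = u.size();
  double ly = binom_ll(y, nst, off, u, b0y, b0o, w);
  double logy = ly + std::log(unif_rand());
  double theta = unif_rand() * 2.0 * M_PI;
  double lo = theta - 2.0 * M_PI, hi = theta;
  NumericVector up(n);
  for (int iter = 0; iter < 1000; ++iter) {
    double ct = std::cos(theta), st = std::sin(theta);
    for (int i = 0; i < n; ++i) up[i] = u[i] * ct + nu[i] * st;
    double ll = binom_ll(y, nst, off, up, b0y, b0o, w);
    if (ll > logy)
      return List::create(_["u"] = up, _["theta"] = theta, _["ll"] = ll);
    if (theta < 0) lo = theta; else hi = theta;
    theta = lo + unif_rand() * (hi - lo);
  }
  return List::create(_["u"] = u, _["theta"] = 0.0, _["ll"] = ly);
}
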