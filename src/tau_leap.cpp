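#include <Rcpp.h>
using namespace Rcpp;

// Poisson draw that stays safe for very large means: above 2^30 the Poisson
// is indistinguishable from its Gaussian limit and would overflow rpois.
static double safe_rpois(double lambda) {
  if (lambda > 1073741824.0) {
    double v = lambda + std::sqrt(lambda) * norm_rand();
    return v > 0 ? std::floor(v + 0.5) : 0.0;
  }
  return R::rpois(lambda);
}

// One tau-leap of the reaction network in integer counts. All propensities
// are evaluated at the leap start; births are thinned (multivariate
// hypergeometric across sources) when the drawn total exceeds the food
// available, so the conserved total N_X + N_W + sum(N_U) never changes.
// Sources are visited in `src_order`, and target placement consumes the RNG
// in per-source storage order; both are what make mirrored-kernel runs
// reproduce mirrored trajectories exactly.
// [[Rcpp::export]]
List pc_tau_leap_cpp(NumericVector N_U, double N_X, double N_W,
                     NumericVector ka, NumericVector gam,
                     IntegerVector src_order,
                     List targets, List masses,
                     double k0, double rho0, double n_exp,
                     double gamma0, double s, double dt) {
  const int n = N_U.size();
  NumericVector NU = clone(N_U);
  std::vector<int> occ;
  occ.reserve(1024);
  for (int i = 0; i < n; ++i) {
    int k = src_order[i] - 1;
    if (N_U[k] > 0) occ.push_back(k);
  }
  const int m = (int) occ.size();
  double totB = 0.0, totD = 0.0;

  std::vector<double> births(m, 0.0);
  if (m > 0 && N_X > 0) {
    const double coef = k0 / std::pow(rho0, n_exp) * std::pow(N_X, n_exp) * dt;
    for (int i = 0; i < m; ++i) {
      births[i] = safe_rpois(coef * ka[occ[i]] * N_U[occ[i]]);
      totB += births[i];
    }
    if (totB > N_X) { // consume all the food, but no more than is available
      double rem_keep = N_X, rem_tot = totB;
      for (int i = 0; i < m; ++i) {
        if (births[i] > 0) {
          double ki = R::rhyper(births[i], rem_tot - births[i], rem_keep);
          rem_keep -= ki;
          rem_tot -= births[i];
          births[i] = ki;
        }
      }
      totB = N_X;
    }
    std::vector<int> buf;
    for (int i = 0; i < m; ++i) {
      if (births[i] > 0) {
        if (births[i] >= 2147483647.0)
          stop("birth count exceeds integer range in one leap");
        IntegerVector tg = targets[occ[i]];
        NumericVector ms = masses[occ[i]];
        const int K = tg.size();
        const double b = births[i];
        if (b < K) {
          // few events: place each birth by inverse-CDF scan (same law,
          // far cheaper than a full multinomial over K categories)
          const double *p = REAL(ms);
          for (int e = 0; e < (int) b; ++e) {
            double u = unif_rand(), acc = 0.0;
            int j = 0;
            for (; j < K - 1; ++j) {
              acc += p[j];
              if (u <= acc) break;
            }
            NU[tg[j] - 1] += 1.0;
          }
        } else {
          if ((int) buf.size() < K) buf.resize(K);
          rmultinom((int) b, REAL(ms), K, buf.data());
          for (int j = 0; j < K; ++j)
            if (buf[j] > 0) NU[tg[j] - 1] += buf[j];
        }
      }
    }
  }

  for (int i = 0; i < m; ++i) {
    double d = safe_rpois(gamma0 * gam[occ[i]] * N_U[occ[i]] * dt);
    if (d > N_U[occ[i]]) d = N_U[occ[i]]; // clamp: cannot kill more than exist
    NU[occ[i]] -= d;
    totD += d;
  }

  double rec = safe_rpois(s * N_W * dt);
  if (rec > N_W) rec = N_W;

  return List::create(_["N_U"] = NU,
                      _["N_X"] = N_X - totB + rec,
                      _["N_W"] = N_W + totD - rec);
}
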