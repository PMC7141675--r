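#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the two three-parameter
// binomial dose-response models:
//   model 0 (NEC):  p = l * exp(-m * (x - c)_+)          params (l, m, c)
//   model 1 (LL3):  p = d / (1 + exp(b (log x - log e))) params (d, b, e)
// Priors: param 1 ~ U(0, 1), param 2 ~ U(0, slope_upper),
//         param 3 ~ Gamma(shape, rate) (vague: 0.001, 0.001).
// Per-parameter Gaussian random-walk proposals with Robbins-Monro step
// adaptation during warm-up only, so the sampling phase is a valid
// fixed-kernel Markov chain. Uses R's RNG: seeding via set.seed() on the
// R side makes chains reproducible.

static const double P_EPS = 1e-12;

static double loglik_model(const NumericVector& x, const IntegerVector& y,
                           const IntegerVector& n, int model,
                           double p1, double p2, double p3) {
  double ll = 0.0;
  for (int i = 0; i < x.size(); ++i) {
    double p;
    if (model == 0) {
      double excess = x[i] - p3;
      p = p1 * (excess > 0 ? std::exp(-p2 * excess) : 1.0);
    } else {
      if (x[i] == 0.0) {
        p = p1;
      } else {
        p = p1 / (1.0 + std::exp(p2 * (std::log(x[i]) - std::log(p3))));
      }
    }
    if (p < P_EPS) p = P_EPS;
    if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
    ll += y[i] * std::log(p) + (n[i] - y[i]) * std::log(1.0 - p);
  }
  return ll;
}

// [[Rcpp::export(name = ".mwg_chain_cpp")]]
List mwg_chain_cpp(NumericVector x, IntegerVector y, IntegerVector n,
                   int model, NumericVector init, int warmup, int iter,
                   int thin, double slope_upper, double gamma_shape,
                   double gamma_rate, bool use_lik, LogicalVector fixed) {
  RNGScope scope;
  const int npar = 3;
  NumericVector theta = clone(init);

  auto logprior = [&](const NumericVector& th) -> double {
    if (th[0] <= 0.0 || th[0] >= 1.0) return R_NegInf;
    if (th[1] <= 0.0 || th[1] >= slope_upper) return R_NegInf;
    if (th[2] <= 0.0) return R_NegInf;
    return (gamma_shape - 1.0) * std::log(th[2]) - gamma_rate * th[2];
  };
  auto logpost = [&](const NumericVector& th, double& ll_out) -> double {
    double lp = logprior(th);
    if (!R_finite(lp)) { ll_out = NA_REAL; return R_NegInf; }
    ll_out = use_lik ? loglik_model(x, y, n, model, th[0], th[1], th[2])
                     : 0.0;
    return lp + ll_out;
  };

  double ll_cur;
  double lp_cur = logpost(theta, ll_cur);
  if (!R_finite(lp_cur)) stop("initial values outside the prior support");

  NumericVector log_step(npar);
  log_step[0] = std::log(0.05);
  log_step[1] = std::log(0.5);
  log_step[2] = std::log(0.05);

  int nkeep = iter / thin;
  NumericMatrix draws(nkeep, npar);
  NumericVector loglik_keep(nkeep);
  NumericVector acc(npar), tries(npar);

  int keep_i = 0;
  int total = warmup + iter;
  for (int t = 1; t <= total; ++t) {
    for (int j = 0; j < npar; ++j) {
      if (fixed[j]) continue;
      NumericVector prop = clone(theta);
      prop[j] = theta[j] + R::rnorm(0.0, std::exp(log_step[j]));
      double ll_prop;
      double lp_prop = logpost(prop, ll_prop);
      double alpha = R_finite(lp_prop)
                       ? std::min(1.0, std::exp(lp_prop - lp_cur)) : 0.0;
      if (R::runif(0.0, 1.0) < alpha) {
        theta = prop; lp_cur = lp_prop; ll_cur = ll_prop;
      }
      if (t <= warmup) {
        log_step[j] += (alpha - 0.44) * std::pow((double)t, -0.6);
      } else {
        tries[j] += 1.0;
        if (alpha > 0 && lp_cur == lp_prop) acc[j] += 1.0;
      }
    }
    if (t > warmup && (t - warmup) % thin == 0 && keep_i < nkeep) {
      for (int j = 0; j < npar; ++j) draws(keep_i, j) = theta[j];
      loglik_keep[keep_i] = use_lik ? ll_cur
        : loglik_model(x, y, n, model, theta[0], theta[1], theta[2]);
      ++keep_i;
    }
  }

  NumericVector acc_rate(npar);
  for (int j = 0; j < npar; ++j)
    acc_rate[j] = tries[j] > 0 ? acc[j] / tries[j] : NA_REAL;

  return List::create(_["draws"] = draws,
                      _["loglik"] = loglik_keep,
                      _["accept_rate"] = acc_rate,
                      _["step"] = exp(log_step));
}
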