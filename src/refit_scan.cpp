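#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grid scan of the post-hoc refit: for each (beta, delta, epsilon) candidate
// the full log-posterior over the threshold grid is accumulated from the
// sign-restricted trial history, and the normalized posterior peak and its
// location are returned. The psychometric form must match weibull_p() in R:
//   p = delta*gamma + (1-delta) * (1 - (1-gamma) * exp(-10^(beta*(x-T+eps))))
// Far from the tested level the curve saturates exactly in double precision
// (ceiling below, gamma above), so those grid ranges receive constant
// log-likelihood contributions via a difference array and only a narrow
// window is evaluated transcendentally. The grid must be uniform ascending.
// [[Rcpp::export(name = ".refit_scan_cpp")]]
List refit_scan_cpp(NumericVector grid, NumericVector log_prior,
                    NumericVector x, LogicalVector correct,
                    NumericVector betas, NumericVector deltas,
                    NumericVector epsilons, double gamma) {
  const int ng = grid.size();
  const int nt = x.size();
  const int np = betas.size();
  const double LN10 = std::log(10.0);
  const double g0 = grid[0];
  const double step = ng > 1 ? grid[1] - grid[0] : 1.0;

  NumericVector peak(np);
  IntegerVector argmax(np);
  std::vector<double> lp(ng), diff(ng + 1);

  for (int j = 0; j < np; ++j) {
    const double beta = betas[j];
    const double delta = deltas[j];
    const double eps = epsilons[j];
    const double floor_term = delta * gamma;
    const double scale = 1.0 - delta;
    const double gg = 1.0 - gamma;
    const double ceiling = floor_term + scale;
    const double win_lo = 3.0 / beta;    // u > 3: exp(-10^u) underflows to 0
    const double win_hi = 18.0 / beta;   // u < -18: p rounds to gamma exactly

    for (int g = 0; g < ng; ++g) lp[g] = log_prior[g];
    std::fill(diff.begin(), diff.end(), 0.0);

    for (int t = 0; t < nt; ++t) {
      const double xt = x[t] + eps;
      const bool corr = correct[t];
      int ia = (int)std::floor((xt - win_lo - g0) / step);
      int ib = (int)std::ceil((xt + win_hi - g0) / step) + 1;
      if (ia < 0) ia = 0; if (ia > ng) ia = ng;
      if (ib < ia) ib = ia; if (ib > ng) ib = ng;
      const double cl = corr ? std::log(ceiling) : std::log1p(-ceiling);
      const double ch = corr ? std::log(gamma) : std::log1p(-gamma);
      if (ia > 0) { diff[0] += cl; diff[ia] -= cl; }
      if (ib < ng) diff[ib] += ch;
      for (int g = ia; g < ib; ++g) {
        const double u = beta * (xt - grid[g]);
        const double p = floor_term +
          scale * (1.0 - gg * std::exp(-std::exp(LN10 * u)));
        lp[g] += corr ? std::log(p) : std::log1p(-p);
      }
    }
    double acc = 0.0;
    for (int g = 0; g < ng; ++g) { acc += diff[g]; lp[g] += acc; }

    // normalized posterior peak via log-sum-exp
    double m = lp[0];
    int im = 0;
    for (int g = 1; g < ng; ++g) {
      if (lp[g] > m) { m = lp[g]; im = g; }
    }
    double z = 0.0;
    for (int g = 0; g < ng; ++g) z += std::exp(lp[g] - m);
    peak[j] = 1.0 / z;
    argmax[j] = im + 1;  // 1-based for R
  }
  return List::create(_["peak"] = peak, _["argmax"] = argmax);
}
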