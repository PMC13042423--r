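#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-inflated negative binomial loss and gradients for a batch.
//
// X:   B x G counts
// eta: B x G decoder output; the NB mean is mu = lib[b] * exp(eta), with eta
//      clamped to [-30, 30]
// log_theta, pi_logit: per-gene dispersion and dropout parameters
//
// Returns the mean NLL per entry and, when grad is true, d(loss)/d(eta)
// (B x G) plus per-gene gradients for log_theta and pi_logit, all already
// scaled by 1 / (B * G).
// [[Rcpp::export(name = ".zinb_stats_cpp")]]
List zinb_stats_cpp(NumericMatrix X, NumericMatrix eta, NumericVector lib,
                    NumericVector log_theta, NumericVector pi_logit,
                    bool grad) {
  const int B = X.nrow(), G = X.ncol();
  const double scale = 1.0 / (double(B) * double(G));
  double loss = 0.0;
  NumericMatrix deta;
  NumericVector g_lt, g_pl;
  if (grad) {
    deta = NumericMatrix(B, G);
    g_lt = NumericVector(G);
    g_pl = NumericVector(G);
  }
  for (int j = 0; j < G; ++j) {
    const double th = std::exp(log_theta[j]);
    const double pl = pi_logit[j];
    const double pi = 1.0 / (1.0 + std::exp(-pl));
    const double log1m_pi = -std::log1p(std::exp(pl));  // log(1 - pi)
    const double log_pi = pl + log1m_pi;                // log(pi)
    const double lg_th = std::lgamma(th);
    const double dg_th = R::digamma(th);
    const double log_th = std::log(th);
    double acc_lt = 0.0, acc_pl = 0.0;
    for (int i = 0; i < B; ++i) {
      double e = eta(i, j);
      if (e > 30.0) e = 30.0; else if (e < -30.0) e = -30.0;
      const double mu = lib[i] * std::exp(e);
      const double x = X(i, j);
      const double log_thmu = std::log(th + mu);
      if (x > 0.0) {
        // -log(1-pi) - log NB(x; mu, th)
        const double lnb = std::lgamma(x + th) - lg_th - std::lgamma(x + 1.0) +
          th * (log_th - log_thmu) + x * (std::log(mu) - log_thmu);
        loss += -(log1m_pi + lnb);
        if (grad) {
          const double dmu = (th + x) / (th + mu) - x / mu;
          deta(i, j) = dmu * mu * scale;
          acc_lt += -(R::digamma(x + th) - dg_th + (log_th - log_thmu) +
                      1.0 - (th + x) / (th + mu));
          acc_pl += 1.0 / (1.0 - pi);
        }
      } else {
        const double lp0 = th * (log_th - log_thmu);
        // -log(pi + (1-pi) p0), stable
        const double b = log1m_pi + lp0;
        double lmix;
        if (pi > 0.0) {
          const double mx = std::max(log_pi, b);
          lmix = mx + std::log(std::exp(log_pi - mx) + std::exp(b - mx));
        } else {
          lmix = b;
        }
        loss += -lmix;
        if (grad) {
          const double p0 = std::exp(lp0);
          const double mix = std::exp(lmix);
          const double w0 = (1.0 - pi) * p0 / mix;
          deta(i, j) = w0 * th / (th + mu) * mu * scale;
          acc_lt += -w0 * ((log_th - log_thmu) + mu / (th + mu));
          acc_pl += -(1.0 - p0) / mix;
        }
      }
    }
    if (grad) {
      g_lt[j] = acc_lt * th * scale;
      g_pl[j] = acc_pl * pi * (1.0 - pi) * scale;
    }
  }
  if (!grad) return List::create(_["loss"] = loss * scale);
  return List::create(_["loss"] = loss * scale, _["deta"] = deta,
                      _["g_log_theta"] = g_lt, _["g_pi_logit"] = g_pl);
}
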