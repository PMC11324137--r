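// Hot per-peak kernels: ZINB likelihood on collapsed count histograms,
// the EM loop, bounded coordinate refinement, and the posterior-mode
// search for the shrunken dispersion. Peaks collapse to the histogram of
// their non-zero values, so every likelihood evaluation is O(#unique).

#include <Rcpp.h>
#include <cmath>
#include <functional>
using namespace Rcpp;

static const double PHI_MIN = 1e-6;
static const double PHI_MAX = 1e3;

struct PStats {
  std::vector<double> vals, cnts;
  double n, n1, n2, sum_y, lgy1;
};

static PStats make_stats(const NumericVector& vals, const NumericVector& cnts,
                         double n) {
  PStats s;
  s.vals.assign(vals.begin(), vals.end());
  s.cnts.assign(cnts.begin(), cnts.end());
  s.n = n;
  s.n2 = 0.0; s.sum_y = 0.0; s.lgy1 = 0.0;
  for (size_t i = 0; i < s.vals.size(); ++i) {
    s.n2 += s.cnts[i];
    s.sum_y += s.cnts[i] * s.vals[i];
    s.lgy1 += s.cnts[i] * std::lgamma(s.vals[i] + 1.0);
  }
  s.n1 = n - s.n2;
  return s;
}

// ZINB log-likelihood, factorized over zero and non-zero cells.
static double zinb_ll(const PStats& s, double mu, double phi, double p) {
  double a = 1.0 / phi;
  double lmp = std::log1p(mu * phi);
  double ll = 0.0;
  if (s.n1 > 0) ll += s.n1 * std::log(p + (1.0 - p) * std::exp(-a * lmp));
  if (s.n2 > 0) {
    double acc = 0.0;
    for (size_t i = 0; i < s.vals.size(); ++i)
      acc += s.cnts[i] * std::lgamma(s.vals[i] + a);
    ll += s.n2 * std::log1p(-p) + acc - s.n2 * std::lgamma(a) - s.lgy1 +
      s.sum_y * (std::log(mu) + std::log(phi) - lmp) - s.n2 * a * lmp;
  }
  return ll;
}

// Responsibility-weighted NB log-likelihood (terms free of mu, phi
// dropped); all zero cells share weight w0.
static double nb_wll(const PStats& s, double w0, double mu, double phi) {
  double a = 1.0 / phi;
  double lmp = std::log1p(mu * phi);
  double ll = -w0 * s.n1 * a * lmp;
  if (s.n2 > 0) {
    double acc = 0.0;
    for (size_t i = 0; i < s.vals.size(); ++i)
      acc += s.cnts[i] * std::lgamma(s.vals[i] + a);
    ll += acc - s.n2 * std::lgamma(a) +
      s.sum_y * (std::log(mu) + std::log(phi) - lmp) - s.n2 * a * lmp;
  }
  return ll;
}

// Golden-section maximization on [lo, hi]; deterministic and
// derivative-free.
static double golden_max(const std::function<double(double)>& f,
                         double lo, double hi, double tol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = f(x1);
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export(name = ".cpp_zinb_ll")]]
double cpp_zinb_ll(NumericVector vals, NumericVector cnts, double n,
                   double mu, double phi, double p) {
  PStats s = make_stats(vals, cnts, n);
  return zinb_ll(s, mu, phi, p);
}

// [[Rcpp::export(name = ".cpp_em")]]
List cpp_em(NumericVector vals, NumericVector cnts, double n,
            double tol, int max_iter, int min_nonzero) {
  PStats s = make_stats(vals, cnts, n);
  if (s.n2 < min_nonzero)
    return List::create(_["degenerate"] = true);

  double sum_y2 = 0.0;
  for (size_t i = 0; i < s.vals.size(); ++i)
    sum_y2 += s.cnts[i] * s.vals[i] * s.vals[i];
  double ybar = s.sum_y / s.n;
  double s2 = (sum_y2 - s.n * ybar * ybar) / (s.n - 1.0);

  // moment starts
  double phi = (s2 - ybar) / (ybar * ybar);
  phi = std::min(std::max(phi, 0.01), PHI_MAX);
  double pi0 = std::exp(-std::log1p(ybar * phi) / phi);
  double p = std::min(std::max(s.n1 / s.n - pi0, 0.01), 0.95);
  double mu = ybar / (1.0 - p);

  double ll = zinb_ll(s, mu, phi, p);
  std::vector<double> trace;
  trace.push_back(ll);
  bool converged = false;
  int iter = 0;
  const double eta_lo = std::log(PHI_MIN), eta_hi = std::log(PHI_MAX);
  while (iter < max_iter) {
    ++iter;
    // E-step: responsibility of the zero point mass for zero cells
    pi0 = std::exp(-std::log1p(mu * phi) / phi);
    double r = (s.n1 > 0) ? p / (p + (1.0 - p) * pi0) : 0.0;
    // M-step
    p = s.n1 * r / s.n;
    double w0 = 1.0 - r;
    mu = std::max(s.sum_y / (w0 * s.n1 + s.n2), 1e-8);
    auto f = [&](double eta) { return nb_wll(s, w0, mu, std::exp(eta)); };
    double eta_new = golden_max(f, eta_lo, eta_hi, 1e-9);
    // guard: never decrease the M-step objective
    if (f(eta_new) >= f(std::log(phi))) phi = std::exp(eta_new);
    double ll_new = zinb_ll(s, mu, phi, p);
    trace.push_back(ll_new);
    if (std::fabs(ll_new - ll) / (std::fabs(ll) + 1e-8) < tol) {
      converged = true;
      ll = ll_new;
      break;
    }
    ll = ll_new;
  }

  // delta-method variance of log(phi) from observed information
  double h = 1e-4, eta = std::log(phi);
  double info = -(zinb_ll(s, mu, std::exp(eta + h), p) -
                  2.0 * zinb_ll(s, mu, phi, p) +
                  zinb_ll(s, mu, std::exp(eta - h), p)) / (h * h);
  double se2 = (std::isfinite(info) && info > 1e-6) ? 1.0 / info : NA_REAL;

  return List::create(
    _["degenerate"] = false,
    _["p"] = p, _["mu"] = mu, _["phi"] = phi,
    _["loglik"] = ll, _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
    _["n_iter"] = iter, _["converged"] = converged,
    _["se2_logphi"] = se2,
    _["phi_interior"] = (phi > PHI_MIN * 1.01 && phi < PHI_MAX * 0.99)
  );
}

// [[Rcpp::export(name = ".cpp_refine")]]
List cpp_refine(NumericVector vals, NumericVector cnts, double n,
                double mu0, double p0, double phi,
                double mu_max, double p_max, double tol, int max_iter) {
  PStats s = make_stats(vals, cnts, n);
  p_max = std::min(p_max, 0.99);
  mu_max = std::max(mu_max, 0.01 + 1e-8);
  p_max = std::max(p_max, 0.01 + 1e-8);
  double mu_prev = std::min(std::max(mu0, 0.01), mu_max);
  double p_prev = std::min(std::max(p0, 0.01), p_max);
  double best_mu = mu_prev, best_p = p_prev;
  double best_ll = zinb_ll(s, mu_prev, phi, p_prev);
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    // both 1-D searches condition on the previous iterate
    auto fmu = [&](double m) { return zinb_ll(s, m, phi, p_prev); };
    double mu_new = golden_max(fmu, 0.01, mu_max, 1e-8);
    auto fp = [&](double q) { return zinb_ll(s, mu_prev, phi, q); };
    double p_new = golden_max(fp, 0.01, p_max, 1e-8);
    double ll = zinb_ll(s, mu_new, phi, p_new);
    if (std::isfinite(ll) && ll > best_ll) {
      best_ll = ll; best_mu = mu_new; best_p = p_new;
    }
    if (std::fabs(mu_prev - mu_new) / std::max(mu_prev, 0.01) <= tol &&
        std::fabs(p_prev - p_new) / std::max(p_prev, 0.01) <= tol) {
      converged = true;
      break;
    }
    mu_prev = mu_new;
    p_prev = p_new;
  }
  return List::create(_["mu"] = best_mu, _["p"] = best_p,
                      _["loglik"] = best_ll,
                      _["n_iter"] = iter, _["converged"] = converged);
}

// [[Rcpp::export(name = ".cpp_post_mode")]]
List cpp_post_mode(NumericVector vals, NumericVector cnts, double n,
                   double mu, double p, double theta, double sigma,
                   double phi_init) {
  PStats s = make_stats(vals, cnts, n);
  auto f = [&](double eta) {
    double phi = std::exp(eta);
    return zinb_ll(s, mu, phi, p) -
      (eta - theta) * (eta - theta) / (2.0 * sigma * sigma) - eta;
  };
  double lo = std::max(theta - 6.0 * sigma, std::log(PHI_MIN));
  double hi = std::min(theta + 6.0 * sigma, std::log(PHI_MAX));
  double eta = (std::isfinite(phi_init) && phi_init > 0)
    ? std::min(std::max(std::log(phi_init), lo), hi) : theta;
  const double h = 1e-5;
  bool ok = false;
  for (int i = 0; i < 50; ++i) {
    double f0 = f(eta), fp = f(eta + h), fm = f(eta - h);
    double g = (fp - fm) / (2.0 * h);
    double H = (fp - 2.0 * f0 + fm) / (h * h);
    if (!std::isfinite(g) || !std::isfinite(H) || H >= -1e-12) break;
    if (std::fabs(g) < 1e-8) { ok = true; break; }
    double step = -g / H;
    bool ascended = false;
    for (int j = 0; j < 30; ++j) {
      double cand = eta + step;
      double fc = f(cand);
      if (std::isfinite(fc) && fc >= f0) { eta = cand; ascended = true; break; }
      step *= 0.5;
    }
    if (!ascended) break;
  }
  if (ok && (eta < lo - 2.0 || eta > hi + 2.0)) ok = false;
  if (!ok) {
    eta = golden_max(f, lo, hi, 1e-10);
    return List::create(_["phi_tilde"] = std::exp(eta),
                        _["status"] = "fallback");
  }
  return List::create(_["phi_tilde"] = std::exp(eta),
                      _["status"] = "newton");
}
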