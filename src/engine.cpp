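// Markov-recursion engine for group-sequential operating characteristics.
//
// The sequence of stagewise z-statistics (Z_1, ..., Z_K) is Markov; on the
// score scale S_k = Z_k * sqrt(I_k) the increments S_k - S_{k-1} are
// independent N(theta * dI, dI), with I_k = k * n1 / (2 sigma^2) the per-arm
// information at analysis k and theta the (centred) treatment effect.  Exit
// probabilities are obtained by propagating the continuation sub-density
// through Gauss-Legendre quadrature on each continuation interval, truncated
// at +/- 8 conditional standard deviations.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Gauss-Legendre nodes/weights on [-1, 1], cached per node count.
struct GLRule {
  std::vector<double> x, w;
};

const GLRule &gl_rule(int n) {
  static std::map<int, GLRule> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  GLRule r;
  r.x.resize(n);
  r.w.resize(n);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double z1, pp;
    do {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z;
      z = z1 - p1 / pp;
    } while (std::fabs(z - z1) > 1e-15);
    r.x[i] = -z;
    r.x[n - 1 - i] = z;
    r.w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    r.w[n - 1 - i] = r.w[i];
  }
  auto res = cache.emplace(n, std::move(r));
  return res.first->second;
}

inline double phi(double z) { return M_1_SQRT_2PI * std::exp(-0.5 * z * z); }

inline double upper_tail(double z) {
  if (z == R_PosInf) return 0.0;
  if (z == R_NegInf) return 1.0;
  return R::pnorm(z, 0.0, 1.0, 0, 0);
}

inline double lower_tail(double z) {
  if (z == R_PosInf) return 1.0;
  if (z == R_NegInf) return 0.0;
  return R::pnorm(z, 0.0, 1.0, 1, 0);
}

// Stagewise first-exit probabilities; fut/eff must have length K.
void exit_probs_core(double n1, int K, const double *f, const double *e,
                     double theta, double sigma, int m,
                     double *fut, double *eff) {
  const double dI = n1 / (2.0 * sigma * sigma);
  const double sd = std::sqrt(dI);
  const double mu_inc = theta * dI;

  for (int k = 0; k < K; ++k) { fut[k] = 0.0; eff[k] = 0.0; }

  // Stage 1: marginal N(theta * I_1, I_1) on the score scale.
  double m1 = mu_inc, s1 = sd;
  double e_sc = (e[0] == R_PosInf) ? R_PosInf : e[0] * s1;
  double f_sc = (f[0] == R_NegInf) ? R_NegInf : f[0] * s1;
  eff[0] = upper_tail((e_sc - m1) / s1);
  fut[0] = lower_tail((f_sc - m1) / s1);
  if (K == 1) return;

  const GLRule &rule = gl_rule(m);
  std::vector<double> x(m), h(m), xn(m), hn(m);

  double L = std::max(f_sc, m1 - 8.0 * s1);
  double U = std::min(e_sc, m1 + 8.0 * s1);
  int ncur = 0;
  if (U > L) {
    double c0 = 0.5 * (L + U), c1 = 0.5 * (U - L);
    for (int j = 0; j < m; ++j) {
      x[j] = c0 + c1 * rule.x[j];
      h[j] = c1 * rule.w[j] * phi((x[j] - m1) / s1) / s1;
    }
    ncur = m;
  }

  for (int k = 1; k < K; ++k) {
    double sIk = std::sqrt((k + 1.0) * dI);
    double ek_sc = (e[k] == R_PosInf) ? R_PosInf : e[k] * sIk;
    double fk_sc = (f[k] == R_NegInf) ? R_NegInf : f[k] * sIk;
    if (ncur == 0) break;
    double se = 0.0, sf = 0.0;
    for (int j = 0; j < ncur; ++j) {
      se += h[j] * upper_tail((ek_sc - x[j] - mu_inc) / sd);
      sf += h[j] * lower_tail((fk_sc - x[j] - mu_inc) / sd);
    }
    eff[k] = se;
    fut[k] = sf;
    if (k == K - 1) break;
    double Ln = std::max(fk_sc, L + mu_inc - 8.0 * sd);
    double Un = std::min(ek_sc, U + mu_inc + 8.0 * sd);
    if (Un <= Ln) { ncur = 0; break; }
    double c0 = 0.5 * (Ln + Un), c1 = 0.5 * (Un - Ln);
    for (int i = 0; i < m; ++i) {
      double y = c0 + c1 * rule.x[i];
      double acc = 0.0;
      for (int j = 0; j < ncur; ++j)
        acc += h[j] * phi((y - x[j] - mu_inc) / sd);
      xn[i] = y;
      hn[i] = c1 * rule.w[i] * acc / sd;
    }
    x.swap(xn);
    h.swap(hn);
    L = Ln;
    U = Un;
    ncur = m;
  }
}

double expected_n_core(double n1, int K, const double *f, const double *e,
                       double theta, double sigma, int m,
                       std::vector<double> &fut, std::vector<double> &eff) {
  exit_probs_core(n1, K, f, e, theta, sigma, m, fut.data(), eff.data());
  double en = 0.0, stopped = 0.0;
  for (int k = 0; k < K - 1; ++k) {
    double p = fut[k] + eff[k];
    en += (k + 1.0) * n1 * p;
    stopped += p;
  }
  en += K * n1 * (1.0 - stopped);
  return en;
}

double power_core(double n1, int K, const double *f, const double *e,
                  double theta, double sigma, int m) {
  std::vector<double> fut(K), eff(K);
  exit_probs_core(n1, K, f, e, theta, sigma, m, fut.data(), eff.data());
  double p = 0.0;
  for (int k = 0; k < K; ++k) p += eff[k];
  return p;
}

// Golden-section maximisation of E[N](theta) over [lo, hi].
void emax_core(double n1, int K, const double *f, const double *e,
               double sigma, int m, double lo, double hi, double tol,
               double &theta_star, double &emax, bool &widened) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  std::vector<double> fut(K), eff(K);
  widened = false;
  for (int attempt = 0; attempt < 6; ++attempt) {
    double a = lo, b = hi;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double fc = expected_n_core(n1, K, f, e, c, sigma, m, fut, eff);
    double fd = expected_n_core(n1, K, f, e, d, sigma, m, fut, eff);
    while (b - a > tol) {
      if (fc > fd) {
        b = d; d = c; fd = fc;
        c = b - gr * (b - a);
        fc = expected_n_core(n1, K, f, e, c, sigma, m, fut, eff);
      } else {
        a = c; c = d; fc = fd;
        d = a + gr * (b - a);
        fd = expected_n_core(n1, K, f, e, d, sigma, m, fut, eff);
      }
    }
    theta_star = 0.5 * (a + b);
    emax = expected_n_core(n1, K, f, e, theta_star, sigma, m, fut, eff);
    double span = hi - lo;
    if (theta_star > hi - 0.02 * span) {        // maximiser at upper edge: widen
      hi = hi + 2.0 * span;
      widened = true;
    } else if (theta_star < lo + 0.02 * span) { // at lower edge: widen downward
      lo = lo - 2.0 * span;
      widened = true;
    } else {
      return;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_exit_probs")]]
List cpp_exit_probs(double n1, NumericVector f, NumericVector e,
                    double theta, double sigma, int grid_points) {
  int K = f.size();
  NumericVector fut(K), eff(K);
  exit_probs_core(n1, K, f.begin(), e.begin(), theta, sigma, grid_points,
                  fut.begin(), eff.begin());
  return List::create(_["futility"] = fut, _["efficacy"] = eff);
}

// [[Rcpp::export(name = ".cpp_power")]]
double cpp_power(double n1, NumericVector f, NumericVector e,
                 double theta, double sigma, int grid_points) {
  return power_core(n1, f.size(), f.begin(), e.begin(), theta, sigma,
                    grid_points);
}

// [[Rcpp::export(name = ".cpp_expected_n")]]
double cpp_expected_n(double n1, NumericVector f, NumericVector e,
                      double theta, double sigma, int grid_points) {
  int K = f.size();
  std::vector<double> fut(K), eff(K);
  return expected_n_core(n1, K, f.begin(), e.begin(), theta, sigma,
                         grid_points, fut, eff);
}

// [[Rcpp::export(name = ".cpp_emax")]]
List cpp_emax(double n1, NumericVector f, NumericVector e, double sigma,
              int grid_points, double lo, double hi, double tol) {
  double theta_star, emax;
  bool widened;
  emax_core(n1, f.size(), f.begin(), e.begin(), sigma, grid_points, lo, hi,
            tol, theta_star, emax, widened);
  return List::create(_["delta_star"] = theta_star, _["e_max"] = emax,
                      _["widened"] = widened);
}

// Penalty-augmented SA objective.  theta1 is the centred CRD (delta1-delta0);
// target: 0 = E[N] at the null, 1 = E[N] at the CRD, 2 = maximum E[N].
// [[Rcpp::export(name = ".cpp_objective")]]
NumericVector cpp_objective(double n1, NumericVector f, NumericVector e,
                            double sigma, double theta1, double alpha,
                            double beta, double mu, int target,
                            int grid_points, double search_hi, double tol) {
  int K = f.size();
  double alpha_att = power_core(n1, K, f.begin(), e.begin(), 0.0, sigma,
                                grid_points);
  double pow_att = power_core(n1, K, f.begin(), e.begin(), theta1, sigma,
                              grid_points);
  double beta_att = 1.0 - pow_att;
  double pen = 0.0;
  if (alpha_att > alpha) pen += mu * (alpha_att - alpha) / alpha;
  if (beta_att > beta) pen += mu * (beta_att - beta) / beta;
  double base;
  if (target == 2) {
    double theta_star, emax;
    bool widened;
    emax_core(n1, K, f.begin(), e.begin(), sigma, grid_points, 0.0, search_hi,
              tol, theta_star, emax, widened);
    base = emax;
  } else {
    std::vector<double> fut(K), eff(K);
    base = expected_n_core(n1, K, f.begin(), e.begin(),
                           target == 1 ? theta1 : 0.0, sigma, grid_points,
                           fut, eff);
  }
  return NumericVector::create(_["objective"] = base + pen,
                               _["base"] = base,
                               _["alpha_attained"] = alpha_att,
                               _["power_attained"] = pow_att,
                               _["penalty"] = pen);
}
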