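// Auxiliary-variable slice-Gibbs sampler for dichotomous testlet response
// models.  Model codes: 0 = 2PL, 1 = T2PLTM (random-effects testlet model),
// 2 = N2PLTM (testlet effect loaded by the testlet discrimination
// alpha_d = mean of item slopes in testlet d).
//
// The auxiliary threshold t_ij is stored on the logit scale:
//   y_ij = 1:  lambda ~ U(0, p)  =>  t = logit(lambda),  constraint  z >= t
//   y_ij = 0:  phi    ~ U(0, q)  =>  t = log((1-phi)/phi), constraint z <= t
// where z is the linear predictor.  All full conditionals are the priors
// truncated to the interval in which every indicator of Eq.-(3) type holds.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double LIK_GUARD = 1e-12;   // floor for likelihood evaluations
static const double LOG_GUARD = std::log(1e-12);

// log(1/(1+exp(-z))) computed stably
static inline double log_plogis(double z) {
  if (z < 0) return z - log1p(std::exp(z));
  return -log1p(std::exp(-z));
}

// std-normal sample truncated to [a, b] with 6 <= a < b (Robert 1995)
static double rtail_std(double a, double b) {
  for (int it = 0; it < 1000; ++it) {
    double e = R::exp_rand() / a;
    double x = a + e;
    if (x <= b && R::unif_rand() <= std::exp(-0.5 * e * e)) return x;
  }
  // interval mass is vanishing; the density is ~flat over [a, b]
  return a + (b - a) * R::unif_rand();
}

// N(mu, sd^2) truncated to [lo, hi]; bounds may be infinite
static double rtnorm(double mu, double sd, double lo, double hi) {
  double a = (lo - mu) / sd, b = (hi - mu) / sd;
  if (a > b) {
    if (a - b < 1e-6) return mu + sd * 0.5 * (a + b);
    stop("truncated-normal interval inverted (lo > hi)");
  }
  if (a >= 6.0)  return mu + sd * rtail_std(a, b);
  if (b <= -6.0) return mu - sd * rtail_std(-b, -a);
  double pa = (a == -INF) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = (b == INF) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa < 1e-14) {
    double l = (a == -INF) ? b - 1.0 : a;
    double h = (b == INF) ? a + 1.0 : b;
    return mu + sd * (l + (h - l) * R::unif_rand());
  }
  double u = pa + (pb - pa) * R::unif_rand();
  double x = R::qnorm(u, 0.0, 1.0, 1, 0);
  if (x < a) x = a;
  if (x > b) x = b;
  return mu + sd * x;
}

// Inverse-Gamma(shape, scale) draw (density ~ x^-(shape+1) exp(-scale/x))
static inline double rinvgamma1(double shape, double scale) {
  return scale / R::rgamma(shape, 1.0);
}

struct TestletMap {
  int J, K;
  std::vector<int> d;                    // item -> testlet (0-based)
  std::vector<std::vector<int> > S;      // testlet -> items
  std::vector<int> nd;
  TestletMap(const IntegerVector &item_testlet) {
    J = item_testlet.size();
    K = 0;
    d.resize(J);
    for (int j = 0; j < J; ++j) {
      d[j] = item_testlet[j];
      if (d[j] + 1 > K) K = d[j] + 1;
    }
    S.resize(K);
    nd.resize(K);
    for (int j = 0; j < J; ++j) S[d[j]].push_back(j);
    for (int k = 0; k < K; ++k) nd[k] = (int) S[k].size();
  }
};

// Linear predictor of cell (i, j) for a given model
static inline double linpred(int model, double a, double theta, double b,
                             double eta, double alpha) {
  double z = a * (theta - b);
  if (model == 1) z += a * eta;
  else if (model == 2) z += alpha * eta;
  return z;
}

struct Sampler {
  const IntegerMatrix &Y;
  const TestletMap &map;
  int model, n, J, K;
  std::vector<double> a, b, theta, s2eta;
  NumericMatrix eta;                       // n x K
  double s2a, s2b;
  std::vector<double> sumA;                // per-testlet sum of slopes
  NumericMatrix tmat;                      // auxiliary thresholds (logit)
  // prior
  int family;                              // 0 normal, 1 uniform
  double mu_a, mu_b, mu_eta, v1, tau1, v2, tau2, v3, tau3;
  double ua_lo, ua_hi, ub_lo, ub_hi;
  bool upd_s2a, upd_s2b, upd_s2eta;
  // debug
  int debug;
  long checks_run = 0, violations = 0;
  int iter_now = 0;

  Sampler(const IntegerMatrix &Y_, const TestletMap &map_, int model_)
    : Y(Y_), map(map_), model(model_), n(Y_.nrow()), J(map_.J), K(map_.K),
      eta(Y_.nrow(), map_.K), tmat(Y_.nrow(), map_.J) {
    a.assign(J, 1.0); b.assign(J, 0.0); theta.assign(n, 0.0);
    s2eta.assign(K, 1.0); s2a = 1.0; s2b = 1.0;
    sumA.assign(K, 0.0);
  }

  void refresh_sumA() {
    std::fill(sumA.begin(), sumA.end(), 0.0);
    for (int j = 0; j < J; ++j) sumA[map.d[j]] += a[j];
  }
  inline double alpha_of(int k) const { return sumA[k] / map.nd[k]; }

  inline double zcell(int i, int j) const {
    int k = map.d[j];
    return linpred(model, a[j], theta[i], b[j], eta(i, k), alpha_of(k));
  }

  // Step 1: refresh all auxiliary thresholds
  void sample_aux() {
    for (int j = 0; j < J; ++j) {
      int k = map.d[j];
      double alph = alpha_of(k);
      for (int i = 0; i < n; ++i) {
        double z = linpred(model, a[j], theta[i], b[j], eta(i, k), alph);
        // p = e / (1 + e) with e = exp(-|z|) folded for stability
        double e = std::exp(-std::fabs(z));
        double den = 1.0 + e;
        double small = e / den;              // min(p, q)
        double big = 1.0 / den;              // max(p, q)
        double p = (z >= 0) ? big : small;
        double q = (z >= 0) ? small : big;
        double u = R::unif_rand();
        if (Y(i, j) == 1) {
          // t = logit(u p) = log(u p) - log(q + p (1 - u))
          tmat(i, j) = std::log(u * p) - std::log(q + p * (1.0 - u));
        } else {
          tmat(i, j) = std::log(p + q * (1.0 - u)) - std::log(u * q);
        }
      }
    }
  }

  // slice-indicator audit: every cell must satisfy its inequality
  void check_slice(const char *where) {
    ++checks_run;
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < n; ++i) {
        double z = zcell(i, j);
        bool ok = (Y(i, j) == 1) ? (z >= tmat(i, j) - 1e-8)
                                 : (z <= tmat(i, j) + 1e-8);
        if (!ok) {
          ++violations;
          stop("slice indicator violated after %s (iteration %d, cell %d,%d)",
               where, iter_now, i + 1, j + 1);
        }
      }
  }

  // ---- truncation bounds ---------------------------------------------------
  // item slope a_j; constraints from item j's own cells and (for the n2pl
  // model) from sibling cells of the same testlet, in which a_j appears
  // through alpha_d.
  void bounds_a(int j, bool include_siblings, double &lo, double &hi) const {
    lo = 0.0; hi = INF;
    int k = map.d[j];
    int ndk = map.nd[k];
    double B = sumA[k] - a[j];            // others' slope sum
    for (int i = 0; i < n; ++i) {
      double e = eta(i, k);
      double w = 0.0, c, rhs;
      if (model == 2) {
        w = e / ndk;
        c = theta[i] - b[j] + w;
        rhs = tmat(i, j) - B * w;
      } else if (model == 1) {
        c = theta[i] - b[j] + e;
        rhs = tmat(i, j);
      } else {
        c = theta[i] - b[j];
        rhs = tmat(i, j);
      }
      if (Y(i, j) == 1) {
        if (c > 0) { double v = rhs / c; if (v > lo) lo = v; }
        else if (c < 0) { double v = rhs / c; if (v < hi) hi = v; }
      } else {
        if (c > 0) { double v = rhs / c; if (v < hi) hi = v; }
        else if (c < 0) { double v = rhs / c; if (v > lo) lo = v; }
      }
      if (model == 2 && include_siblings && ndk > 1 && w != 0.0) {
        const std::vector<int> &items = map.S[k];
        double invw = 1.0 / w, Bw = B * w;
        for (size_t m = 0; m < items.size(); ++m) {
          int jj = items[m];
          if (jj == j) continue;
          double v = (tmat(i, jj) - a[jj] * (theta[i] - b[jj]) - Bw) * invw;
          bool lower = (Y(i, jj) == 1) == (w > 0);
          if (lower) { if (v > lo) lo = v; }
          else { if (v < hi) hi = v; }
        }
      }
    }
  }

  void bounds_b(int j, double &lo, double &hi) const {
    lo = -INF; hi = INF;
    int k = map.d[j];
    double alph = alpha_of(k);
    double inva = 1.0 / a[j];
    for (int i = 0; i < n; ++i) {
      double h;
      if (model == 2) h = alph * eta(i, k);
      else if (model == 1) h = a[j] * eta(i, k);
      else h = 0.0;
      double cand = theta[i] + (h - tmat(i, j)) * inva;
      if (Y(i, j) == 1) { if (cand < hi) hi = cand; }
      else { if (cand > lo) lo = cand; }
    }
  }

  void bounds_theta(int i, double &lo, double &hi) const {
    lo = -INF; hi = INF;
    for (int j = 0; j < J; ++j) {
      int k = map.d[j];
      double h;
      if (model == 2) h = alpha_of(k) * eta(i, k);
      else if (model == 1) h = a[j] * eta(i, k);
      else h = 0.0;
      double cand = b[j] + (tmat(i, j) - h) / a[j];
      if (Y(i, j) == 1) { if (cand > lo) lo = cand; }
      else { if (cand < hi) hi = cand; }
    }
  }

  void bounds_eta(int i, int k, double &lo, double &hi) const {
    lo = -INF; hi = INF;
    double inv_alph = 1.0 / alpha_of(k);
    const std::vector<int> &items = map.S[k];
    for (size_t m = 0; m < items.size(); ++m) {
      int j = items[m];
      double invc = (model == 2) ? inv_alph : 1.0 / a[j];
      double cand = (tmat(i, j) - a[j] * (theta[i] - b[j])) * invc;
      if (Y(i, j) == 1) { if (cand > lo) lo = cand; }
      else { if (cand < hi) hi = cand; }
    }
  }

  // ---- parameter updates ---------------------------------------------------
  void draw_a(int j) {
    double lo, hi;
    bounds_a(j, true, lo, hi);
    double old = a[j];
    if (family == 1) {
      double l = std::max(lo, ua_lo), h = std::min(hi, ua_hi);
      if (l > h) stop("empty truncation interval for a[%d]", j + 1);
      a[j] = l + (h - l) * R::unif_rand();
    } else {
      a[j] = rtnorm(mu_a, std::sqrt(s2a), std::max(lo, 0.0), hi);
    }
    sumA[map.d[j]] += a[j] - old;
  }

  void draw_b(int j) {
    double lo, hi;
    bounds_b(j, lo, hi);
    if (family == 1) {
      double l = std::max(lo, ub_lo), h = std::min(hi, ub_hi);
      if (l > h) stop("empty truncation interval for b[%d]", j + 1);
      b[j] = l + (h - l) * R::unif_rand();
    } else {
      b[j] = rtnorm(mu_b, std::sqrt(s2b), lo, hi);
    }
  }

  void draw_theta(int i) {
    double lo, hi;
    bounds_theta(i, lo, hi);
    theta[i] = rtnorm(0.0, 1.0, lo, hi);   // identification: theta ~ N(0,1)
  }

  void draw_eta(int i, int k) {
    double lo, hi;
    bounds_eta(i, k, lo, hi);
    eta(i, k) = rtnorm(mu_eta, std::sqrt(s2eta[k]), lo, hi);
  }

  void draw_variances(const LogicalVector &upd_a_mask,
                      const LogicalVector &upd_b_mask) {
    if (family == 0 && upd_s2a) {
      double ss = 0.0;
      for (int j = 0; j < J; ++j) ss += (a[j] - mu_a) * (a[j] - mu_a);
      s2a = rinvgamma1(0.5 * J + v1, 0.5 * ss + tau1);
    }
    if (family == 0 && upd_s2b) {
      double ss = 0.0;
      for (int j = 0; j < J; ++j) ss += (b[j] - mu_b) * (b[j] - mu_b);
      s2b = rinvgamma1(0.5 * J + v2, 0.5 * ss + tau2);
    }
    if (model != 0 && upd_s2eta) {
      for (int k = 0; k < K; ++k) {
        double ss = 0.0;
        for (int i = 0; i < n; ++i)
          ss += (eta(i, k) - mu_eta) * (eta(i, k) - mu_eta);
        s2eta[k] = rinvgamma1(0.5 * n + v3, 0.5 * ss + tau3);
      }
    }
    (void) upd_a_mask; (void) upd_b_mask;
  }
};

// [[Rcpp::export]]
List cpp_run_chain(IntegerMatrix Y, IntegerVector item_testlet, int model,
                   int n_iter, int burnin, int thin, List prior, List init,
                   List ctrl) {
  TestletMap map(item_testlet);
  int n = Y.nrow(), J = Y.ncol(), K = map.K;
  if ((int) map.d.size() != J) stop("design/item dimension mismatch");

  Sampler s(Y, map, model);
  {
    NumericVector a0 = init["a"], b0 = init["b"], th0 = init["theta"],
                  s2e0 = init["s2eta"];
    NumericMatrix e0 = init["eta"];
    for (int j = 0; j < J; ++j) { s.a[j] = a0[j]; s.b[j] = b0[j]; }
    for (int i = 0; i < n; ++i) s.theta[i] = th0[i];
    for (int k = 0; k < K; ++k) s.s2eta[k] = s2e0[k];
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) s.eta(i, k) = e0(i, k);
    s.s2a = as<double>(init["s2a"]);
    s.s2b = as<double>(init["s2b"]);
  }
  s.refresh_sumA();
  s.family = as<int>(prior["family"]);
  s.mu_a = as<double>(prior["mu_a"]);
  s.mu_b = as<double>(prior["mu_b"]);
  s.mu_eta = as<double>(prior["mu_eta"]);
  s.v1 = as<double>(prior["v1"]);   s.tau1 = as<double>(prior["tau1"]);
  s.v2 = as<double>(prior["v2"]);   s.tau2 = as<double>(prior["tau2"]);
  s.v3 = as<double>(prior["v3"]);   s.tau3 = as<double>(prior["tau3"]);
  s.ua_lo = as<double>(prior["unif_a_lo"]);
  s.ua_hi = as<double>(prior["unif_a_hi"]);
  s.ub_lo = as<double>(prior["unif_b_lo"]);
  s.ub_hi = as<double>(prior["unif_b_hi"]);
  s.upd_s2a = as<bool>(prior["update_s2a"]);
  s.upd_s2b = as<bool>(prior["update_s2b"]);
  s.upd_s2eta = as<bool>(prior["update_s2eta"]);

  LogicalVector upd_a = ctrl["upd_a"], upd_b = ctrl["upd_b"];
  bool upd_theta = as<bool>(ctrl["upd_theta"]);
  bool upd_eta = as<bool>(ctrl["upd_eta"]) && model != 0;
  bool store_latent = as<bool>(ctrl["store_latent"]);
  s.debug = as<int>(ctrl["debug"]);

  int n_stored = 0;
  for (int m = burnin + 1; m <= n_iter; ++m)
    if ((m - burnin) % thin == 0) ++n_stored;

  int P = 2 * J + 2;                       // a, b, s2a, s2b
  if (model != 0) P += K;                  // s2eta
  if (store_latent) {
    P += n;                                // theta
    if (model != 0) P += n * K;            // eta
  }
  NumericMatrix draws(n_stored, P);
  NumericVector devs(n_stored);
  NumericMatrix invlik_sum(n, J);
  std::vector<double> ma(J, 0.0), mb(J, 0.0), mth(n, 0.0), ms2e(K, 0.0);
  std::vector<double> meta(n * (size_t) K, 0.0);
  double ms2a = 0.0, ms2b = 0.0;

  int row = 0;
  for (int m = 1; m <= n_iter; ++m) {
    s.iter_now = m;
    s.sample_aux();
    if (s.debug >= 1) s.check_slice("step 1 (auxiliary)");

    for (int j = 0; j < J; ++j) if (upd_a[j]) {
      s.draw_a(j);
      if (s.debug >= 2) s.check_slice("step 2 (slope)");
    }
    if (s.debug == 1) s.check_slice("step 2 (slope)");

    for (int j = 0; j < J; ++j) if (upd_b[j]) {
      s.draw_b(j);
      if (s.debug >= 2) s.check_slice("step 3 (difficulty)");
    }
    if (s.debug == 1) s.check_slice("step 3 (difficulty)");

    if (upd_theta) {
      for (int i = 0; i < n; ++i) {
        s.draw_theta(i);
        if (s.debug >= 2 && n <= 64) s.check_slice("step 4 (ability)");
      }
      if (s.debug >= 1) s.check_slice("step 4 (ability)");
    }

    if (upd_eta) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) {
          s.draw_eta(i, k);
          if (s.debug >= 2 && n <= 64) s.check_slice("step 5 (testlet effect)");
        }
      if (s.debug >= 1) s.check_slice("step 5 (testlet effect)");
    }

    s.draw_variances(upd_a, upd_b);
    if (s.debug >= 1) s.check_slice("steps 6-8 (variances)");

    if (m > burnin && (m - burnin) % thin == 0) {
      int c = 0;
      for (int j = 0; j < J; ++j) draws(row, c++) = s.a[j];
      for (int j = 0; j < J; ++j) draws(row, c++) = s.b[j];
      draws(row, c++) = s.s2a;
      draws(row, c++) = s.s2b;
      if (model != 0) for (int k = 0; k < K; ++k) draws(row, c++) = s.s2eta[k];
      if (store_latent) {
        for (int i = 0; i < n; ++i) draws(row, c++) = s.theta[i];
        if (model != 0)
          for (int k = 0; k < K; ++k)
            for (int i = 0; i < n; ++i) draws(row, c++) = s.eta(i, k);
      }
      // deviance of the stored state + CVPD accumulation
      double dev = 0.0;
      for (int j = 0; j < J; ++j) {
        int k = map.d[j];
        double alph = s.alpha_of(k);
        for (int i = 0; i < n; ++i) {
          double z = linpred(model, s.a[j], s.theta[i], s.b[j], s.eta(i, k),
                             alph);
          double ll = (Y(i, j) == 1) ? log_plogis(z) : log_plogis(-z);
          if (ll < LOG_GUARD) ll = LOG_GUARD;   // cell likelihood floor
          dev += -2.0 * ll;
          invlik_sum(i, j) += std::exp(-ll);
        }
      }
      devs[row] = dev;
      for (int j = 0; j < J; ++j) { ma[j] += s.a[j]; mb[j] += s.b[j]; }
      for (int i = 0; i < n; ++i) mth[i] += s.theta[i];
      for (int k = 0; k < K; ++k) {
        ms2e[k] += s.s2eta[k];
        for (int i = 0; i < n; ++i) meta[(size_t) k * n + i] += s.eta(i, k);
      }
      ms2a += s.s2a; ms2b += s.s2b;
      ++row;
    }
    if (m % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  double denom = (n_stored > 0) ? (double) n_stored : 1.0;
  NumericVector pa(J), pb(J), pth(n), ps2e(K);
  NumericMatrix peta(n, K), invlik_mean(n, J);
  for (int j = 0; j < J; ++j) { pa[j] = ma[j] / denom; pb[j] = mb[j] / denom; }
  for (int i = 0; i < n; ++i) pth[i] = mth[i] / denom;
  for (int k = 0; k < K; ++k) {
    ps2e[k] = ms2e[k] / denom;
    for (int i = 0; i < n; ++i) peta(i, k) = meta[(size_t) k * n + i] / denom;
  }
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i) invlik_mean(i, j) = invlik_sum(i, j) / denom;

  return List::create(
    _["draws"] = draws, _["deviance"] = devs, _["invlik_mean"] = invlik_mean,
    _["post_mean"] = List::create(
      _["a"] = pa, _["b"] = pb, _["theta"] = pth, _["eta"] = peta,
      _["s2a"] = ms2a / denom, _["s2b"] = ms2b / denom, _["s2eta"] = ps2e),
    _["n_stored"] = n_stored, _["checks_run"] = (double) s.checks_run,
    _["violations"] = (double) s.violations);
}

// Standalone access to the truncation-bound computations (same code paths as
// the sweep), for unit testing and for the exported R helpers.
static Sampler make_state(const IntegerMatrix &Y, const TestletMap &map,
                          int model, NumericVector a, NumericVector b,
                          NumericVector theta, NumericMatrix eta,
                          NumericMatrix tmat) {
  Sampler s(Y, map, model);
  int n = Y.nrow(), J = Y.ncol(), K = map.K;
  for (int j = 0; j < J; ++j) { s.a[j] = a[j]; s.b[j] = b[j]; }
  for (int i = 0; i < n; ++i) s.theta[i] = theta[i];
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) s.eta(i, k) = eta(i, k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < J; ++j) s.tmat(i, j) = tmat(i, j);
  s.refresh_sumA();
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_bounds(std::string what, int idx1, int idx2,
                         IntegerMatrix Y, IntegerVector item_testlet,
                         int model, NumericVector a, NumericVector b,
                         NumericVector theta, NumericMatrix eta,
                         NumericMatrix tmat, bool include_siblings) {
  TestletMap map(item_testlet);
  Sampler s = make_state(Y, map, model, a, b, theta, eta, tmat);
  double lo = 0, hi = 0;
  if (what == "a") s.bounds_a(idx1 - 1, include_siblings, lo, hi);
  else if (what == "b") s.bounds_b(idx1 - 1, lo, hi);
  else if (what == "theta") s.bounds_theta(idx1 - 1, lo, hi);
  else if (what == "eta") s.bounds_eta(idx1 - 1, idx2 - 1, lo, hi);
  else stop("unknown bound type '%s'", what.c_str());
  return NumericVector::create(lo, hi);
}

// [[Rcpp::export]]
NumericMatrix cpp_prob_matrix(IntegerVector item_testlet, int model,
                              NumericVector a, NumericVector b,
                              NumericVector theta, NumericMatrix eta) {
  TestletMap map(item_testlet);
  int n = theta.size(), J = map.J;
  NumericMatrix P(n, J);
  std::vector<double> sumA(map.K, 0.0);
  for (int j = 0; j < J; ++j) sumA[map.d[j]] += a[j];
  for (int j = 0; j < J; ++j) {
    int k = map.d[j];
    double alph = sumA[k] / map.nd[k];
    for (int i = 0; i < n; ++i) {
      double z = linpred(model, a[j], theta[i], b[j], eta(i, k), alph);
      P(i, j) = std::exp(log_plogis(z));
    }
  }
  return P;
}

// [[Rcpp::export]]
double cpp_loglik(IntegerMatrix Y, IntegerVector item_testlet, int model,
                  NumericVector a, NumericVector b, NumericVector theta,
                  NumericMatrix eta) {
  TestletMap map(item_testlet);
  int n = Y.nrow(), J = Y.ncol();
  std::vector<double> sumA(map.K, 0.0);
  for (int j = 0; j < J; ++j) sumA[map.d[j]] += a[j];
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    int k = map.d[j];
    double alph = sumA[k] / map.nd[k];
    for (int i = 0; i < n; ++i) {
      double z = linpred(model, a[j], theta[i], b[j], eta(i, k), alph);
      double l = (Y(i, j) == 1) ? log_plogis(z) : log_plogis(-z);
      double lik = std::exp(l);
      if (lik < LIK_GUARD) lik = LIK_GUARD;
      ll += std::log(lik);
    }
  }
  return ll;
}
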