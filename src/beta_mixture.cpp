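#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted beta MLE by damped Newton on (alpha, beta) using the
// sufficient statistics E_w[log x], E_w[log(1-x)]. Warm-startable:
// pass a,b <= 0 to initialise by weighted method of moments.
static void beta_mle(const std::vector<double>& x, const std::vector<double>& w,
                     double& a, double& b, int max_newton,
                     double lo = 1e-3) {
  // CMAX caps the concentration a + b (mean-preserving): unit levels are
  // coarse, so near-degenerate components are represented by a tight but
  // finite beta rather than a divergent one. lo = 1 constrains the fit
  // to unimodal shapes.
  const double LO = lo, CMAX = 1e3;
  double W = 0, T1 = 0, T2 = 0, m = 0;
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    W += w[i];
    T1 += w[i] * std::log(x[i]);
    T2 += w[i] * std::log1p(-x[i]);
    m += w[i] * x[i];
  }
  if (W <= 1e-10) return;
  T1 /= W; T2 /= W; m /= W;
  if (a <= 0 || b <= 0 || !R_finite(a) || !R_finite(b)) {
    double v = 0;
    for (int i = 0; i < n; ++i) v += w[i] * (x[i] - m) * (x[i] - m);
    v /= W;
    if (v < 1e-10) v = 1e-10;
    double c = m * (1 - m) / v - 1;
    if (c < 1e-2) c = 1e-2;
    a = m * c; b = (1 - m) * c;
  }
  if (a + b > CMAX) { double s = CMAX / (a + b); a *= s; b *= s; }
  a = std::max(a, LO);
  b = std::max(b, LO);
  // weighted log-likelihood up to a constant (entropy terms dropped)
  auto wll = [&](double aa, double bb) {
    return W * ((aa - 1) * T1 + (bb - 1) * T2 - R::lbeta(aa, bb));
  };
  double cur = wll(a, b);
  for (int it = 0; it < max_newton; ++it) {
    double dab = R::digamma(a + b);
    double f1 = R::digamma(a) - dab - T1;
    double f2 = R::digamma(b) - dab - T2;
    if (std::fabs(f1) + std::fabs(f2) < 1e-10) break;
    double tab = R::trigamma(a + b);
    double j11 = R::trigamma(a) - tab, j12 = -tab, j22 = R::trigamma(b) - tab;
    double det = j11 * j22 - j12 * j12;
    if (!R_finite(det) || std::fabs(det) < 1e-300) break;
    double da = ( j22 * f1 - j12 * f2) / det;
    double db = (-j12 * f1 + j11 * f2) / det;
    double step = 1.0;
    while ((a - step * da <= 0 || b - step * db <= 0) && step > 1e-4) step *= 0.5;
    // backtrack: the Newton direction can point uphill through a saddle
    bool accepted = false;
    for (int bt = 0; bt < 8; ++bt) {
      double an = a - step * da, bn = b - step * db;
      if (an + bn > CMAX) { double s = CMAX / (an + bn); an *= s; bn *= s; }
      an = std::max(an, LO);
      bn = std::max(bn, LO);
      double nl = wll(an, bn);
      if (R_finite(nl) && nl >= cur - 1e-12) {
        a = an; b = bn; cur = nl; accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;
  }
}

static double loglik1(const std::vector<double>& x, double a, double b) {
  double ll = 0;
  for (size_t i = 0; i < x.size(); ++i) ll += R::dbeta(x[i], a, b, 1);
  return ll;
}

struct Fit2 {
  double w1, a1, b1, a2, b2, ll;
  bool conv;
  std::vector<double> r1;
};

// EM for a 2-component beta mixture; M-step is a truncated Newton
// update (ECM), warm-started between iterations.
static Fit2 em2(const std::vector<double>& x, std::vector<double> r1,
                double a1, double b1, double a2, double b2,
                int max_iter, double tol) {
  const int n = (int)x.size();
  std::vector<double> r2(n);
  double w1 = 0.5, ll = -1e300, ll_old = -1e300;
  bool conv = false;
  // the truncated-Newton M-step is not exactly monotone, so the best
  // iterate along the path is kept, not the last
  Fit2 best;
  best.ll = -1e300;
  for (int it = 0; it < max_iter; ++it) {
    // M-step
    w1 = 0;
    for (int i = 0; i < n; ++i) w1 += r1[i];
    w1 /= n;
    if (w1 < 1e-6) w1 = 1e-6;
    if (w1 > 1 - 1e-6) w1 = 1 - 1e-6;
    for (int i = 0; i < n; ++i) r2[i] = 1 - r1[i];
    beta_mle(x, r1, a1, b1, 3);
    beta_mle(x, r2, a2, b2, 3);
    // E-step with observed-data log-likelihood at current parameters
    ll = 0;
    double lw1 = std::log(w1), lw2 = std::log1p(-w1);
    for (int i = 0; i < n; ++i) {
      double l1 = lw1 + R::dbeta(x[i], a1, b1, 1);
      double l2 = lw2 + R::dbeta(x[i], a2, b2, 1);
      double mx = std::max(l1, l2);
      double s = std::exp(l1 - mx) + std::exp(l2 - mx);
      ll += mx + std::log(s);
      r1[i] = std::exp(l1 - mx) / s;
    }
    if (R_finite(ll) && ll > best.ll) {
      best.w1 = w1; best.a1 = a1; best.b1 = b1;
      best.a2 = a2; best.b2 = b2;
      best.ll = ll; best.r1 = r1;
    }
    if (it > 0 && std::fabs(ll - ll_old) < tol * (std::fabs(ll) + 1)) {
      conv = true;
      break;
    }
    ll_old = ll;
  }
  best.conv = conv;
  if (best.ll <= -1e299) {  // never finite: report the last state
    best.w1 = w1; best.a1 = a1; best.b1 = b1;
    best.a2 = a2; best.b2 = b2;
    best.ll = ll; best.r1 = r1;
  }
  return best;
}

// 1-D two-means partition from random data-point centers (Lloyd),
// returned as softened responsibilities to start EM.
static std::vector<double> kmeans_part(const std::vector<double>& x) {
  const int n = (int)x.size();
  double c1 = x[(int)(unif_rand() * n)], c2 = x[(int)(unif_rand() * n)];
  for (int t = 0; t < 30 && c1 == c2; ++t) c2 = x[(int)(unif_rand() * n)];
  for (int it = 0; it < 25; ++it) {
    double s1 = 0, s2 = 0;
    int n1 = 0, n2 = 0;
    for (int i = 0; i < n; ++i) {
      if (std::fabs(x[i] - c1) <= std::fabs(x[i] - c2)) { s1 += x[i]; ++n1; }
      else { s2 += x[i]; ++n2; }
    }
    double nc1 = n1 ? s1 / n1 : c1, nc2 = n2 ? s2 / n2 : c2;
    if (nc1 == c1 && nc2 == c2) break;
    c1 = nc1; c2 = nc2;
  }
  std::vector<double> r1(n);
  for (int i = 0; i < n; ++i)
    r1[i] = (std::fabs(x[i] - c1) <= std::fabs(x[i] - c2)) ? 0.9 : 0.1;
  return r1;
}

struct FullFit {
  double a0, b0, ll1, ll2;
  Fit2 best;
  bool degenerate;
};

static FullFit fit_both(const std::vector<double>& x, int max_iter, double tol,
                        int n_restarts) {
  const int n = (int)x.size();
  FullFit out;
  out.degenerate = false;
  std::vector<double> ones(n, 1.0);
  // the null is a homogeneous cell population: a unimodal beta (both
  // shapes >= 1). A U-shaped level distribution is itself bipolarity,
  // so it belongs to the alternative, not the null.
  out.a0 = -1; out.b0 = -1;
  beta_mle(x, ones, out.a0, out.b0, 50, 1.0);
  out.ll1 = loglik1(x, out.a0, out.b0);
  Fit2 best;
  best.ll = -1e300;
  for (int r = 0; r < n_restarts; ++r) {
    Fit2 f = em2(x, kmeans_part(x), -1, -1, -1, -1, max_iter, tol);
    if (f.ll > best.ll) best = f;
  }
  // start at the 1-component solution: guarantees ll2 >= ll1 up to
  // M-step truncation, enforced below
  {
    std::vector<double> r1(n, 0.5);
    Fit2 f = em2(x, r1, out.a0, out.b0, out.a0 * 1.05, out.b0 * 0.95,
                 max_iter, tol);
    if (f.ll > best.ll) best = f;
  }
  if (best.ll < out.ll1) {
    best.ll = out.ll1;
    best.w1 = 0.5;
    best.a1 = out.a0; best.b1 = out.b0;
    best.a2 = out.a0; best.b2 = out.b0;
    std::fill(best.r1.begin(), best.r1.end(), 0.5);
    if (best.r1.empty()) best.r1.assign(n, 0.5);
    out.degenerate = true;
  }
  out.ll2 = best.ll;
  out.best = best;
  return out;
}

// ---------------------------------------------------------------------
// Beta-binomial variant for read-derived unit levels: a unit level is
// k/n_sites with k methylated calls out of n_sites, so the component
// likelihood integrates the beta over the binomial sampling instead of
// evaluating a continuous density at discrete atoms. All computations
// are tabulated over the n_sites + 1 count categories.

// For integer counts k out of ns, the beta-binomial likelihood and its
// shape derivatives are finite products:
//   log BB(k | ns, a, b) = lchoose(ns, k)
//     + sum_{j<k} log(a+j) + sum_{j<ns-k} log(b+j) - sum_{j<ns} log(a+b+j)
// so everything below works on prefix sums of log(a+j), 1/(a+j) and
// 1/(a+j)^2 -- no lgamma/digamma calls in the hot path.
#define BB_MAX_NS 15

// prefix arrays: p[k] = sum_{j<k} f(x+j), k = 0..ns
static inline void bb_prefix(double x, int ns, double* plog, double* pinv,
                             double* pinv2) {
  plog[0] = 0; pinv[0] = 0; pinv2[0] = 0;
  for (int j = 0; j < ns; ++j) {
    double v = x + j;
    plog[j + 1] = plog[j] + std::log(v);
    pinv[j + 1] = pinv[j] + 1 / v;
    pinv2[j + 1] = pinv2[j] + 1 / (v * v);
  }
}

// weighted beta-binomial log-likelihood up to the binomial-coefficient
// constant (enough for line searches and LRT differences)
static double bb_loglik_raw(const std::vector<double>& wk, int ns,
                            double a, double b) {
  double la[BB_MAX_NS + 1], lb[BB_MAX_NS + 1], lab[BB_MAX_NS + 1], dum[BB_MAX_NS + 1];
  bb_prefix(a, ns, la, dum, dum);
  bb_prefix(b, ns, lb, dum, dum);
  bb_prefix(a + b, ns, lab, dum, dum);
  double ll = 0;
  for (int k = 0; k <= ns; ++k) {
    if (wk[k] <= 0) continue;
    ll += wk[k] * (la[k] + lb[ns - k] - lab[ns]);
  }
  return ll;
}

// weighted beta-binomial MLE by damped Newton; wk has length ns + 1
// (weight mass per count category)
static void bb_mle(const std::vector<double>& wk, int ns,
                   double& a, double& b, int max_newton, double lo) {
  const double CMAX = 1e3;
  double W = 0, m = 0;
  for (int k = 0; k <= ns; ++k) { W += wk[k]; m += wk[k] * k; }
  if (W <= 1e-10) return;
  m /= (W * ns);
  if (a <= 0 || b <= 0 || !R_finite(a) || !R_finite(b)) {
    double v = 0;
    for (int k = 0; k <= ns; ++k) {
      double d = (double)k / ns - m;
      v += wk[k] * d * d;
    }
    v /= W;
    double mm = std::min(std::max(m, 0.02), 0.98);
    double rho = (ns * v / (mm * (1 - mm)) - 1) / (ns - 1);
    rho = std::min(std::max(rho, 1e-4), 0.99);
    double c = 1 / rho - 1;
    a = mm * c; b = (1 - mm) * c;
  }
  if (a + b > CMAX) { double s = CMAX / (a + b); a *= s; b *= s; }
  a = std::max(a, lo);
  b = std::max(b, lo);
  double cur = bb_loglik_raw(wk, ns, a, b);
  double la[BB_MAX_NS + 1], ia[BB_MAX_NS + 1], i2a[BB_MAX_NS + 1];
  double lb_[BB_MAX_NS + 1], ib[BB_MAX_NS + 1], i2b[BB_MAX_NS + 1];
  double lab[BB_MAX_NS + 1], iab[BB_MAX_NS + 1], i2ab[BB_MAX_NS + 1];
  for (int it = 0; it < max_newton; ++it) {
    bb_prefix(a, ns, la, ia, i2a);
    bb_prefix(b, ns, lb_, ib, i2b);
    bb_prefix(a + b, ns, lab, iab, i2ab);
    double ga = 0, gb = 0, haa = 0, hab = 0, hbb = 0;
    for (int k = 0; k <= ns; ++k) {
      if (wk[k] <= 0) continue;
      ga += wk[k] * ia[k];
      gb += wk[k] * ib[ns - k];
      haa -= wk[k] * i2a[k];
      hbb -= wk[k] * i2b[ns - k];
    }
    ga -= W * iab[ns];
    gb -= W * iab[ns];
    haa += W * i2ab[ns];
    hbb += W * i2ab[ns];
    hab = W * i2ab[ns];
    if (std::fabs(ga) + std::fabs(gb) < 1e-10 * W) break;
    double det = haa * hbb - hab * hab;
    if (!R_finite(det) || std::fabs(det) < 1e-300) break;
    // Newton ascent step on the log-likelihood
    double da = (hbb * ga - hab * gb) / det;
    double db = (-hab * ga + haa * gb) / det;
    double step = 1.0;
    while ((a - step * da <= 0 || b - step * db <= 0) && step > 1e-4) step *= 0.5;
    // backtrack: the Newton direction can point uphill through a saddle
    bool accepted = false;
    for (int bt = 0; bt < 8; ++bt) {
      double an = a - step * da, bn = b - step * db;
      if (an + bn > CMAX) { double s = CMAX / (an + bn); an *= s; bn *= s; }
      an = std::max(an, lo);
      bn = std::max(bn, lo);
      double nl = bb_loglik_raw(wk, ns, an, bn);
      if (R_finite(nl) && nl >= cur - 1e-12) {
        a = an; b = bn; cur = nl; accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;
  }
}

struct FitBB {
  double w1, a1, b1, a2, b2, ll;
  bool conv;
  std::vector<double> r1;  // responsibility of component 1 per category
};

static FitBB em2_bb(const std::vector<double>& cnt, int ns,
                    std::vector<double> r1, double a1, double b1,
                    double a2, double b2, int max_iter, double tol) {
  const int K = ns + 1;
  double N = 0;
  for (int k = 0; k < K; ++k) N += cnt[k];
  std::vector<double> w1k(K), w2k(K);
  double w1 = 0.5, ll = -1e300, ll_old = -1e300;
  bool conv = false;
  FitBB best;
  best.ll = -1e300;
  for (int it = 0; it < max_iter; ++it) {
    double s1 = 0;
    for (int k = 0; k < K; ++k) {
      w1k[k] = cnt[k] * r1[k];
      w2k[k] = cnt[k] - w1k[k];
      s1 += w1k[k];
    }
    w1 = std::min(std::max(s1 / N, 1e-6), 1 - 1e-6);
    bb_mle(w1k, ns, a1, b1, 3, 1e-3);
    bb_mle(w2k, ns, a2, b2, 3, 1e-3);
    // E-step; ll omits the binomial-coefficient constant (added back by
    // the caller), which cancels from responsibilities and the LRT
    ll = 0;
    double lw1 = std::log(w1), lw2 = std::log1p(-w1);
    double la1[BB_MAX_NS + 1], lb1[BB_MAX_NS + 1], lab1[BB_MAX_NS + 1];
    double la2[BB_MAX_NS + 1], lb2[BB_MAX_NS + 1], lab2[BB_MAX_NS + 1];
    double dum[BB_MAX_NS + 1];
    bb_prefix(a1, ns, la1, dum, dum);
    bb_prefix(b1, ns, lb1, dum, dum);
    bb_prefix(a1 + b1, ns, lab1, dum, dum);
    bb_prefix(a2, ns, la2, dum, dum);
    bb_prefix(b2, ns, lb2, dum, dum);
    bb_prefix(a2 + b2, ns, lab2, dum, dum);
    for (int k = 0; k < K; ++k) {
      double l1 = lw1 + la1[k] + lb1[ns - k] - lab1[ns];
      double l2 = lw2 + la2[k] + lb2[ns - k] - lab2[ns];
      double mx = std::max(l1, l2);
      double s = std::exp(l1 - mx) + std::exp(l2 - mx);
      r1[k] = std::exp(l1 - mx) / s;
      if (cnt[k] > 0) ll += cnt[k] * (mx + std::log(s));
    }
    if (R_finite(ll) && ll > best.ll) {
      best.w1 = w1; best.a1 = a1; best.b1 = b1;
      best.a2 = a2; best.b2 = b2;
      best.ll = ll; best.r1 = r1;
    }
    if (it > 0 && std::fabs(ll - ll_old) < tol * (std::fabs(ll) + 1)) {
      conv = true;
      break;
    }
    ll_old = ll;
  }
  best.conv = conv;
  if (best.ll <= -1e299) {
    best.w1 = w1; best.a1 = a1; best.b1 = b1;
    best.a2 = a2; best.b2 = b2;
    best.ll = ll; best.r1 = r1;
  }
  return best;
}

struct FullFitBB {
  double a0, b0, ll1, ll2;
  FitBB best;
  bool degenerate;
};

// counts tabulated; starts enumerate split thresholds (nearest the mean
// first, n_starts of them) plus the 1-component solution, so the fit is
// deterministic
static FullFitBB fit_both_bb(const std::vector<double>& cnt, int ns,
                             int max_iter, double tol, int n_starts) {
  const int K = ns + 1;
  FullFitBB out;
  out.degenerate = false;
  out.a0 = -1; out.b0 = -1;
  bb_mle(cnt, ns, out.a0, out.b0, 50, 1.0);  // unimodal-constrained null
  // binomial-coefficient constant, shared by every model
  double cc = 0;
  for (int k = 0; k < K; ++k) {
    if (cnt[k] > 0) cc += cnt[k] * R::lchoose(ns, k);
  }
  out.ll1 = bb_loglik_raw(cnt, ns, out.a0, out.b0) + cc;
  double N = 0, mk = 0;
  for (int k = 0; k < K; ++k) { N += cnt[k]; mk += cnt[k] * k; }
  mk /= N;
  std::vector<int> ts(ns);
  for (int t = 0; t < ns; ++t) ts[t] = t;
  std::sort(ts.begin(), ts.end(), [&](int u, int v) {
    return std::fabs(u + 0.5 - mk) < std::fabs(v + 0.5 - mk);
  });
  if (n_starts < 1) n_starts = 1;
  if (n_starts > ns) n_starts = ns;
  FitBB best;
  best.ll = -1e300;
  for (int s = 0; s < n_starts; ++s) {
    int t = ts[s];
    std::vector<double> r1(K);
    for (int k = 0; k < K; ++k) r1[k] = (k <= t) ? 0.9 : 0.1;
    FitBB f = em2_bb(cnt, ns, r1, -1, -1, -1, -1, max_iter, tol);
    if (f.ll > best.ll) best = f;
  }
  {
    std::vector<double> r1(K, 0.5);
    FitBB f = em2_bb(cnt, ns, r1, out.a0, out.b0, out.a0 * 1.05,
                     out.b0 * 0.95, max_iter, tol);
    if (f.ll > best.ll) best = f;
  }
  best.ll += cc;
  if (best.ll < out.ll1) {
    best.ll = out.ll1;
    best.w1 = 0.5;
    best.a1 = out.a0; best.b1 = out.b0;
    best.a2 = out.a0; best.b2 = out.b0;
    best.r1.assign(K, 0.5);
    out.degenerate = true;
  }
  out.ll2 = best.ll;
  out.best = best;
  return out;
}

static std::vector<double> tab_counts(const IntegerVector& k, int ns) {
  std::vector<double> cnt(ns + 1, 0.0);
  for (int i = 0; i < k.size(); ++i) cnt[k[i]] += 1.0;
  return cnt;
}

// [[Rcpp::export]]
List cpp_fit_bb_mixture(IntegerVector counts, int n_sites, int max_iter,
                        double tol) {
  std::vector<double> cnt = tab_counts(counts, n_sites);
  FullFitBB f = fit_both_bb(cnt, n_sites, max_iter, tol, n_sites);
  const int n = counts.size();
  double m1 = f.best.a1 / (f.best.a1 + f.best.b1);
  double m2 = f.best.a2 / (f.best.a2 + f.best.b2);
  bool swap = m1 > m2;
  NumericMatrix resp(n, 2);
  for (int i = 0; i < n; ++i) {
    double r = f.best.r1[counts[i]];
    resp(i, 0) = swap ? 1 - r : r;
    resp(i, 1) = swap ? r : 1 - r;
  }
  NumericVector alpha = swap
    ? NumericVector::create(f.best.a2, f.best.a1)
    : NumericVector::create(f.best.a1, f.best.a2);
  NumericVector beta = swap
    ? NumericVector::create(f.best.b2, f.best.b1)
    : NumericVector::create(f.best.b1, f.best.b2);
  NumericVector wts = swap
    ? NumericVector::create(1 - f.best.w1, f.best.w1)
    : NumericVector::create(f.best.w1, 1 - f.best.w1);
  return List::create(
    _["weights"] = wts,
    _["alpha"] = alpha,
    _["beta"] = beta,
    _["resp"] = resp,
    _["ll1"] = f.ll1,
    _["ll2"] = f.ll2,
    _["fit1"] = NumericVector::create(f.a0, f.b0),
    _["converged"] = f.best.conv || f.degenerate,
    _["degenerate"] = f.degenerate);
}

// [[Rcpp::export]]
double cpp_lrt_stat_bb(IntegerVector counts, int n_sites, int max_iter,
                       double tol, int n_starts) {
  std::vector<double> cnt = tab_counts(counts, n_sites);
  FullFitBB f = fit_both_bb(cnt, n_sites, max_iter, tol, n_starts);
  double lam = 2.0 * (f.ll2 - f.ll1);
  return lam > 0 ? lam : 0;
}

// [[Rcpp::export]]
NumericVector cpp_lrt_bootstrap_bb(int n, int n_sites, double a0, double b0,
                                   int B, int max_iter, double tol,
                                   int n_starts) {
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    std::vector<double> cnt(n_sites + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      double u = R::rbeta(a0, b0);
      cnt[(int)R::rbinom((double)n_sites, u)] += 1.0;
    }
    FullFitBB f = fit_both_bb(cnt, n_sites, max_iter, tol, n_starts);
    double lam = 2.0 * (f.ll2 - f.ll1);
    out[b] = lam > 0 ? lam : 0;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_fit_beta_mixture(NumericVector levels, int max_iter, double tol,
                          int n_restarts) {
  std::vector<double> x(levels.begin(), levels.end());
  FullFit f = fit_both(x, max_iter, tol, n_restarts);
  const int n = (int)x.size();
  NumericMatrix resp(n, 2);
  double m1 = f.best.a1 / (f.best.a1 + f.best.b1);
  double m2 = f.best.a2 / (f.best.a2 + f.best.b2);
  bool swap = m1 > m2;  // component 1 reported as the hypomethylated one
  for (int i = 0; i < n; ++i) {
    double r = f.best.r1[i];
    resp(i, 0) = swap ? 1 - r : r;
    resp(i, 1) = swap ? r : 1 - r;
  }
  NumericVector alpha = swap
    ? NumericVector::create(f.best.a2, f.best.a1)
    : NumericVector::create(f.best.a1, f.best.a2);
  NumericVector beta = swap
    ? NumericVector::create(f.best.b2, f.best.b1)
    : NumericVector::create(f.best.b1, f.best.b2);
  NumericVector wts = swap
    ? NumericVector::create(1 - f.best.w1, f.best.w1)
    : NumericVector::create(f.best.w1, 1 - f.best.w1);
  return List::create(
    _["weights"] = wts,
    _["alpha"] = alpha,
    _["beta"] = beta,
    _["resp"] = resp,
    _["ll1"] = f.ll1,
    _["ll2"] = f.ll2,
    _["fit1"] = NumericVector::create(f.a0, f.b0),
    _["converged"] = f.best.conv || f.degenerate,
    _["degenerate"] = f.degenerate);
}

// [[Rcpp::export]]
double cpp_lrt_stat(NumericVector levels, int max_iter, double tol,
                    int n_restarts) {
  std::vector<double> x(levels.begin(), levels.end());
  FullFit f = fit_both(x, max_iter, tol, n_restarts);
  double lam = 2.0 * (f.ll2 - f.ll1);
  return lam > 0 ? lam : 0;
}

// Parametric-bootstrap null draws of the likelihood-ratio statistic.
// n_sites > 0 mimics the discreteness of read-derived unit levels:
// each draw is Binomial(n_sites, u)/n_sites with u ~ Beta(a0, b0).
// [[Rcpp::export]]
NumericVector cpp_lrt_bootstrap(int n, double a0, double b0, int B, double eps,
                                int n_sites, int max_iter, double tol,
                                int n_restarts) {
  NumericVector out(B);
  std::vector<double> x(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      double u = R::rbeta(a0, b0);
      double v = (n_sites > 0) ? R::rbinom((double)n_sites, u) / n_sites : u;
      if (v < eps) v = eps;
      if (v > 1 - eps) v = 1 - eps;
      x[i] = v;
    }
    FullFit f = fit_both(x, max_iter, tol, n_restarts);
    double lam = 2.0 * (f.ll2 - f.ll1);
    out[b] = lam > 0 ? lam : 0;
  }
  return out;
}
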