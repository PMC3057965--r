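#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double LN10 = 2.302585092994045684;
static const double LOG2PI = 1.8378770664093454836;

// Variance floor on the scale of the data: 1e-12 times the larger of the
// overall variance and the squared magnitude, so that constant phenotypes
// collapse both hypotheses onto the same floored fit.
static double var_floor(const double* y, int N) {
  double my = 0.0, vy = 0.0, mag = 0.0;
  for (int i = 0; i < N; ++i) my += y[i];
  my /= N;
  for (int i = 0; i < N; ++i) {
    vy += (y[i] - my) * (y[i] - my);
    if (std::fabs(y[i]) > mag) mag = std::fabs(y[i]);
  }
  double scale = std::max(vy / N, mag * mag);
  return std::max(1e-12 * scale, 1e-300);
}

// Per-family ML null fit (mean, variance with divisor n_f) and its
// log-likelihood. varFloor guards degenerate (constant) families.
static void null_fit_core(const double* y, const int* fam, int N, int F,
                          std::vector<double>& mean, std::vector<double>& var,
                          std::vector<int>& nf, double& logL0,
                          double varFloor) {
  std::fill(mean.begin(), mean.end(), 0.0);
  std::fill(var.begin(), var.end(), 0.0);
  std::fill(nf.begin(), nf.end(), 0);
  for (int i = 0; i < N; ++i) { mean[fam[i]] += y[i]; nf[fam[i]]++; }
  for (int f = 0; f < F; ++f) if (nf[f] > 0) mean[f] /= nf[f];
  std::vector<double> ss(F, 0.0);
  for (int i = 0; i < N; ++i) {
    double d = y[i] - mean[fam[i]];
    ss[fam[i]] += d * d;
  }
  logL0 = 0.0;
  for (int f = 0; f < F; ++f) {
    if (nf[f] == 0) continue;
    var[f] = std::max(ss[f] / nf[f], varFloor);
    // quadratic term written out so the floor keeps the likelihood exact
    logL0 += -0.5 * nf[f] * (LOG2PI + std::log(var[f]))
             - ss[f] / (2.0 * var[f]);
  }
}

// EM for the JICIM mixture at one testing position: line i in family f
// contributes p_i * N(mu_f, s2_f) + (1 - p_i) * N(mu0, s2_f), with mu0
// shared across families. Responsibilities are initialised from the
// marker-class priors p (the null configuration perturbed by class means),
// variances from the null fit.
static void em_core(const double* y, const int* fam, const double* p,
                    int N, int F,
                    const std::vector<double>& nullMean,
                    const std::vector<double>& nullVar,
                    const std::vector<int>& nf,
                    double tol, int maxit, double varFloor,
                    double& mu0, std::vector<double>& mu,
                    std::vector<double>& s2,
                    double& logL, int& iter, bool& converged,
                    std::vector<double>* trace) {
  std::vector<double> w(N), sw(F), swy(F), cw(F), cwy(F), ss(F);
  std::vector<double> lp(N), lq(N), inv2s(F), logs2(F);
  for (int i = 0; i < N; ++i) {
    w[i] = p[i];
    lp[i] = (p[i] > 0.0) ? std::log(p[i])
                         : -std::numeric_limits<double>::infinity();
    lq[i] = (p[i] < 1.0) ? std::log1p(-p[i])
                         : -std::numeric_limits<double>::infinity();
  }
  for (int f = 0; f < F; ++f) s2[f] = nullVar[f];
  // global precision-weighted mean as a safe fallback for mu0
  double gm = 0.0, gw = 0.0;
  for (int f = 0; f < F; ++f) {
    if (nf[f] == 0) continue;
    gm += nf[f] * nullMean[f] / s2[f];
    gw += nf[f] / s2[f];
  }
  gm = (gw > 0.0) ? gm / gw : 0.0;
  mu0 = gm;
  logL = -std::numeric_limits<double>::infinity();
  converged = false;
  for (iter = 1; iter <= maxit; ++iter) {
    // --- M-step (mu0 pooled with precision weights from current s2) ---
    std::fill(sw.begin(), sw.end(), 0.0);
    std::fill(swy.begin(), swy.end(), 0.0);
    std::fill(cw.begin(), cw.end(), 0.0);
    std::fill(cwy.begin(), cwy.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int f = fam[i];
      sw[f] += w[i];          swy[f] += w[i] * y[i];
      cw[f] += 1.0 - w[i];    cwy[f] += (1.0 - w[i]) * y[i];
    }
    double num0 = 0.0, den0 = 0.0;
    for (int f = 0; f < F; ++f) {
      if (nf[f] == 0) continue;
      num0 += cwy[f] / s2[f];
      den0 += cw[f] / s2[f];
    }
    mu0 = (den0 > 1e-300) ? num0 / den0 : gm;
    for (int f = 0; f < F; ++f)
      mu[f] = (sw[f] > 1e-12) ? swy[f] / sw[f] : mu0;
    std::fill(ss.begin(), ss.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int f = fam[i];
      double d1 = y[i] - mu[f], d0 = y[i] - mu0;
      ss[f] += w[i] * d1 * d1 + (1.0 - w[i]) * d0 * d0;
    }
    for (int f = 0; f < F; ++f)
      if (nf[f] > 0) s2[f] = std::max(ss[f] / nf[f], varFloor);
    // --- E-step + log-likelihood (log domain for stability) ---
    for (int f = 0; f < F; ++f) {
      inv2s[f] = 0.5 / s2[f];
      logs2[f] = std::log(s2[f]);
    }
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      int f = fam[i];
      double d1 = y[i] - mu[f], d0 = y[i] - mu0;
      double la = lp[i] - d1 * d1 * inv2s[f];
      double lb = lq[i] - d0 * d0 * inv2s[f];
      double base = -0.5 * (LOG2PI + logs2[f]);
      if (la >= lb) {
        double e = std::exp(lb - la);
        ll += la + std::log1p(e) + base;
        w[i] = 1.0 / (1.0 + e);
      } else {
        double e = std::exp(la - lb);
        ll += lb + std::log1p(e) + base;
        w[i] = e / (1.0 + e);
      }
    }
    if (trace) trace->push_back(ll);
    if (iter > 1 && std::fabs(ll - logL) < tol * (1.0 + std::fabs(ll))) {
      logL = ll;
      converged = true;
      break;
    }
    logL = ll;
  }
  if (iter > maxit) iter = maxit;
}

//' @noRd
// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector y, IntegerVector fam, int F, NumericVector p,
                double tol = 1e-8, int maxit = 200, bool trace = false) {
  int N = y.size();
  std::vector<double> nullMean(F), nullVar(F), mu(F), s2(F);
  std::vector<int> nf(F);
  double logL0, mu0, logL;
  int iter; bool converged;
  double varFloor = var_floor(REAL(y), N);
  null_fit_core(REAL(y), INTEGER(fam), N, F, nullMean, nullVar, nf, logL0,
                varFloor);
  std::vector<double> tr;
  em_core(REAL(y), INTEGER(fam), REAL(p), N, F, nullMean, nullVar, nf,
          tol, maxit, varFloor, mu0, mu, s2, logL, iter, converged,
          trace ? &tr : (std::vector<double>*)0);
  List out = List::create(
    _["mu0"] = mu0, _["mu"] = wrap(mu), _["sigma2"] = wrap(s2),
    _["logLA"] = logL, _["logL0"] = logL0,
    _["nullMean"] = wrap(nullMean), _["nullVar"] = wrap(nullVar),
    _["iterations"] = iter, _["converged"] = converged);
  if (trace) out["trace"] = wrap(tr);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".null_fit_cpp")]]
List null_fit_cpp(NumericVector y, IntegerVector fam, int F) {
  int N = y.size();
  std::vector<double> mean(F), var(F);
  std::vector<int> nf(F);
  double logL0;
  double varFloor = var_floor(REAL(y), N);
  null_fit_core(REAL(y), INTEGER(fam), N, F, mean, var, nf, logL0, varFloor);
  return List::create(_["mean"] = wrap(mean), _["variance"] = wrap(var),
                      _["n"] = wrap(nf), _["logL0"] = logL0);
}

// Whole-chromosome scan: for grid position t in interval k = posInterval[t],
// line i uses prior pf[cls(i,k), fam[i], t] and adjusted phenotype dY(, k).
// Null fits are cached per interval since consecutive positions share them.
//' @noRd
// [[Rcpp::export(name = ".scan_core_cpp")]]
List scan_core_cpp(NumericMatrix dY, IntegerMatrix cls, IntegerVector fam,
                   int F, NumericVector pf, IntegerVector posInterval,
                   double tol = 1e-8, int maxit = 200) {
  int N = dY.nrow();
  int npos = posInterval.size();
  NumericVector lod(npos), mu0v(npos), logLA(npos), logL0v(npos);
  NumericMatrix muMat(npos, F);
  LogicalVector conv(npos);
  IntegerVector iters(npos);
  std::vector<double> nullMean(F), nullVar(F), mu(F), s2(F), p(N);
  std::vector<int> nf(F);
  double logL0 = 0.0, varFloor = 1e-300;
  int curK = -1;
  const int* famp = INTEGER(fam);
  const int* clsp = INTEGER(cls);
  const double* pfp = REAL(pf);
  for (int t = 0; t < npos; ++t) {
    int k = posInterval[t];
    const double* y = &dY(0, k);
    if (k != curK) {
      varFloor = var_floor(y, N);
      null_fit_core(y, famp, N, F, nullMean, nullVar, nf, logL0, varFloor);
      curK = k;
    }
    for (int i = 0; i < N; ++i)
      p[i] = pfp[clsp[i + (size_t)N * k] + 4 * famp[i] + 4 * F * (size_t)t];
    double mu0, ll;
    int iter; bool cvg;
    em_core(y, famp, p.data(), N, F, nullMean, nullVar, nf, tol, maxit,
            varFloor, mu0, mu, s2, ll, iter, cvg,
            (std::vector<double>*)0);
    double L = (ll - logL0) / LN10;
    lod[t] = (L > 0.0) ? L : 0.0;
    mu0v[t] = mu0;
    logLA[t] = ll;
    logL0v[t] = logL0;
    for (int f = 0; f < F; ++f) muMat(t, f) = mu[f];
    conv[t] = cvg;
    iters[t] = iter;
  }
  return List::create(_["lod"] = lod, _["mu0"] = mu0v, _["mu"] = muMat,
                      _["logLA"] = logLA, _["logL0"] = logL0v,
                      _["iterations"] = iters, _["converged"] = conv);
}
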