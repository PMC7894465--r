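#include <Rcpp.h>
#include <algorithm>
#include <cfloat>
#include <vector>
using namespace Rcpp;

// Median with the mean-of-central-pair convention for even lengths.
static double med(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + h);
  return (lo + hi) / 2.0;
}

// Tukey median polish of one probe-set block (probes x samples), sweeping
// rows then columns; stops when the largest absolute change of any residual
// in a full sweep is < eps, or after maxiter sweeps. Writes t + col effects
// (the per-sample summaries) into out.
static void medpolish_block(const double* x, int nr, int nc, int ld,
                            double eps, int maxiter, double* out) {
  std::vector<double> z(x ? (size_t)nr * nc : 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      z[(size_t)j * nr + i] = x[(size_t)j * ld + i];
  std::vector<double> r(nr, 0.0), c(nc, 0.0), buf;
  double t = 0.0;
  for (int iter = 0; iter < maxiter; ++iter) {
    double maxchange = 0.0;
    // row sweep
    for (int i = 0; i < nr; ++i) {
      buf.assign(nc, 0.0);
      for (int j = 0; j < nc; ++j) buf[j] = z[(size_t)j * nr + i];
      double m = med(buf);
      for (int j = 0; j < nc; ++j) z[(size_t)j * nr + i] -= m;
      r[i] += m;
      if (std::abs(m) > maxchange) maxchange = std::abs(m);
    }
    buf = c;
    double dc = med(buf);
    for (int j = 0; j < nc; ++j) c[j] -= dc;
    t += dc;
    // column sweep
    for (int j = 0; j < nc; ++j) {
      buf.assign(z.begin() + (size_t)j * nr, z.begin() + (size_t)(j + 1) * nr);
      double m = med(buf);
      for (int i = 0; i < nr; ++i) z[(size_t)j * nr + i] -= m;
      c[j] += m;
      if (std::abs(m) > maxchange) maxchange = std::abs(m);
    }
    buf = r;
    double dr = med(buf);
    for (int i = 0; i < nr; ++i) r[i] -= dr;
    t += dr;
    if (maxchange < eps) break;
  }
  for (int j = 0; j < nc; ++j) out[j] = t + c[j];
}

// [[Rcpp::export(name = ".cpp_medpolish_summary")]]
NumericVector cpp_medpolish_summary(NumericMatrix x, double eps, int maxiter) {
  NumericVector out(x.ncol());
  medpolish_block(REAL(x), x.nrow(), x.ncol(), x.nrow(), eps, maxiter,
                  REAL(out));
  return out;
}

// Blocked median polish: rows of x are grouped into contiguous probe-set
// blocks (starts are 1-based, lens the block sizes); returns one summary row
// per block.
// [[Rcpp::export(name = ".cpp_medpolish_blocks")]]
NumericMatrix cpp_medpolish_blocks(NumericMatrix x, IntegerVector starts,
                                   IntegerVector lens, double eps,
                                   int maxiter) {
  const int nb = starts.size(), nc = x.ncol();
  NumericMatrix out(nb, nc);
  std::vector<double> row(nc);
  for (int b = 0; b < nb; ++b) {
    medpolish_block(REAL(x) + (starts[b] - 1), lens[b], nc, x.nrow(), eps,
                    maxiter, row.data());
    for (int j = 0; j < nc; ++j) out(b, j) = row[j];
  }
  return out;
}

// One-sided Wilcoxon signed-rank p-value for H1: median(d) > 0, on the
// already-differenced scores d = score - tau. Zeros are removed; if all are
// removed p = 1. Average ranks on tied |d|. Exact tail by counting sign
// assignments (dynamic program over the doubled-rank sum, equivalent to
// enumerating all 2^n sign patterns) for n <= exact_limit; above that,
// normal approximation with tie correction and 0.5 continuity correction.
static double signrank_p(std::vector<double>& d, int exact_limit) {
  d.erase(std::remove(d.begin(), d.end(), 0.0), d.end());
  const int n = (int)d.size();
  if (n == 0) return 1.0;
  // average ranks of |d|
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return std::abs(d[a]) < std::abs(d[b]);
  });
  std::vector<double> rank(n);
  std::vector<int> tiecnt;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && std::abs(d[idx[j]]) == std::abs(d[idx[i]])) ++j;
    double avg = (i + 1 + j) / 2.0;  // mean of ranks i+1 .. j
    for (int k = i; k < j; ++k) rank[idx[k]] = avg;
    tiecnt.push_back(j - i);
    i = j;
  }
  double W = 0.0;
  for (int k = 0; k < n; ++k)
    if (d[k] > 0) W += rank[k];
  if (n <= exact_limit) {
    // doubled ranks are exact integers; total doubled sum = n(n+1)
    const int total = n * (n + 1);
    std::vector<double> cnt(total + 1, 0.0);
    cnt[0] = 1.0;
    for (int k = 0; k < n; ++k) {
      const int r2 = (int)std::lround(2.0 * rank[k]);
      for (int s = total; s >= r2; --s) cnt[s] += cnt[s - r2];
    }
    const int w2 = (int)std::lround(2.0 * W);
    double tail = 0.0;
    for (int s = w2; s <= total; ++s) tail += cnt[s];
    return tail / std::pow(2.0, n);
  }
  double mu = n * (n + 1) / 4.0;
  double v = n * (n + 1) * (2.0 * n + 1) / 24.0;
  for (int t : tiecnt) v -= (std::pow((double)t, 3) - t) / 48.0;
  if (v <= 0) return 1.0;
  return R::pnorm((W - mu - 0.5) / std::sqrt(v), 0.0, 1.0, 0, 0);
}

// [[Rcpp::export(name = ".cpp_signrank_p")]]
double cpp_signrank_p(NumericVector d, int exact_limit) {
  std::vector<double> v(d.begin(), d.end());
  return signrank_p(v, exact_limit);
}

// Detection p-values for every (probe set, sample) cell: discrimination
// scores (pm-mm)/(pm+mm) per probe pair, then the one-sided signed-rank test
// of median(score) > tau per block and column.
// [[Rcpp::export(name = ".cpp_mas5_pvalues")]]
NumericMatrix cpp_mas5_pvalues(NumericMatrix pm, NumericMatrix mm,
                               IntegerVector starts, IntegerVector lens,
                               double tau, int exact_limit) {
  const int nb = starts.size(), nc = pm.ncol(), ld = pm.nrow();
  NumericMatrix out(nb, nc);
  std::vector<double> d;
  for (int b = 0; b < nb; ++b) {
    const int s0 = starts[b] - 1, len = lens[b];
    for (int j = 0; j < nc; ++j) {
      d.resize(len);
      const double* p = REAL(pm) + (size_t)j * ld + s0;
      const double* m = REAL(mm) + (size_t)j * ld + s0;
      for (int k = 0; k < len; ++k)
        d[k] = (p[k] - m[k]) / (p[k] + m[k]) - tau;
      out(b, j) = signrank_p(d, exact_limit);
    }
  }
  return out;
}

// Negative log-likelihood of the normal+exponential convolution at
// par = (mu, log sigma, log alpha), with the same Mills-ratio asymptotic
// branch as the R reference formulation (see dnormexp in R/normexp.R).
// [[Rcpp::export(name = ".cpp_normexp_nll")]]
double cpp_normexp_nll(NumericVector x, NumericVector par) {
  const double mu = par[0], sigma = std::exp(par[1]), alpha = std::exp(par[2]);
  if (!R_finite(mu) || !R_finite(sigma) || !R_finite(alpha) ||
      sigma <= 0 || alpha <= 0)
    return DBL_MAX / 2;
  const double la = std::log(alpha), cc = sigma / alpha;
  const double lhalf2pi = 0.5 * std::log(2.0 * M_PI);
  const int n = x.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double w = (x[i] - mu) / sigma;
    const double z = w - cc;
    double lf;
    if (z > -8.0) {
      lf = -la - cc * (w - cc / 2.0) + R::pnorm(z, 0.0, 1.0, 1, 1);
    } else {
      lf = -la - lhalf2pi - w * w / 2.0 - std::log(cc - w) +
        std::log1p(-1.0 / (z * z) + 3.0 / (z * z * z * z));
    }
    s -= lf;
  }
  return R_finite(s) ? s : DBL_MAX / 2;
}

// Gradient of cpp_normexp_nll in (mu, log sigma, log alpha).
// [[Rcpp::export(name = ".cpp_normexp_ngr")]]
NumericVector cpp_normexp_ngr(NumericVector x, NumericVector par) {
  const double mu = par[0], sigma = std::exp(par[1]), alpha = std::exp(par[2]);
  const int n = x.size();
  double dmu = 0.0, dsig = 0.0, dalp = 0.0;
  for (int i = 0; i < n; ++i) {
    const double w = (x[i] - mu) / sigma;
    const double z = w - sigma / alpha;
    const double h = std::exp(R::dnorm(z, 0.0, 1.0, 1) -
                              R::pnorm(z, 0.0, 1.0, 1, 1));
    dmu += 1.0 / alpha - h / sigma;
    dsig += sigma / alpha / alpha - h * (w / sigma + 1.0 / alpha);
    dalp += -1.0 / alpha + (x[i] - mu) / (alpha * alpha) -
      sigma * sigma / (alpha * alpha * alpha) + h * sigma / (alpha * alpha);
  }
  NumericVector g = NumericVector::create(-dmu, -dsig * sigma, -dalp * alpha);
  for (int k = 0; k < 3; ++k)
    if (!R_finite(g[k])) g[k] = 0.0;
  return g;
}
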