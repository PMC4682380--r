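#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Collapsed dual-unit chain over the 6 CpG states
//   0 (Up, basic) 1 (Up, second) 2 (Down, basic) 3 (Down, second)
//   4 (NoCh, basic) 5 (NoCh, second)
// Gap states are silent and only self-loop, so a gap run of length d >= 1
// collapses to the scalar closed form (d - 1) * log(a_i) on the entering
// state's gap, followed by that gap's exit distribution over CpG states.

static const int NS = 6;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int dir_of(int s) { return s / 2; } // 0 = Up, 1 = Down, 2 = NoCh

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse_vec(const double *x, int n) {
  double m = NEG_INF;
  for (int i = 0; i < n; ++i) if (x[i] > m) m = x[i];
  if (m == NEG_INF) return NEG_INF;
  long double s = 0.0L;
  for (int i = 0; i < n; ++i) s += std::exp((long double)(x[i] - m));
  return m + (double)std::log(s);
}

// log effective CpG-to-CpG kernel entry for gap length d >= 1
// (lexit is an R matrix, hence column-major)
static inline double lK(int d, int i, int j,
                        const double *lself, const double *lexit) {
  double g = (d > 1) ? (double)(d - 1) * lself[i] : 0.0;
  return g + lexit[j * NS + i];
}

// [[Rcpp::export]]
List cpp_forward(NumericMatrix em, IntegerVector gaps,
                 NumericVector lself, NumericVector lexit,
                 NumericVector lpi) {
  int L = em.nrow();
  if (L < 1) stop("empty chain");
  std::vector<double> a(NS), anew(NS), tmp(NS);
  for (int j = 0; j < NS; ++j) a[j] = lpi[j] + em(0, dir_of(j));
  for (int t = 0; t + 1 < L; ++t) {
    int d = gaps[t];
    if (d < 1) stop("gap length must be >= 1");
    for (int j = 0; j < NS; ++j) {
      for (int i = 0; i < NS; ++i)
        tmp[i] = a[i] + lK(d, i, j, lself.begin(), lexit.begin());
      anew[j] = lse_vec(tmp.data(), NS) + em(t + 1, dir_of(j));
    }
    a = anew;
  }
  double ll = lse_vec(a.data(), NS);
  return List::create(_["loglik"] = ll);
}

// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix em, IntegerVector gaps,
                          NumericVector lself, NumericVector lexit,
                          NumericVector lpi) {
  int L = em.nrow();
  if (L < 1) stop("empty chain");
  NumericMatrix alpha(L, NS), beta(L, NS), gamma(L, NS);
  std::vector<double> tmp(NS);

  for (int j = 0; j < NS; ++j) alpha(0, j) = lpi[j] + em(0, dir_of(j));
  for (int t = 0; t + 1 < L; ++t) {
    int d = gaps[t];
    if (d < 1) stop("gap length must be >= 1");
    for (int j = 0; j < NS; ++j) {
      for (int i = 0; i < NS; ++i)
        tmp[i] = alpha(t, i) + lK(d, i, j, lself.begin(), lexit.begin());
      alpha(t + 1, j) = lse_vec(tmp.data(), NS) + em(t + 1, dir_of(j));
    }
  }
  std::vector<double> last(NS);
  for (int j = 0; j < NS; ++j) last[j] = alpha(L - 1, j);
  double ll = lse_vec(last.data(), NS);

  for (int j = 0; j < NS; ++j) beta(L - 1, j) = 0.0;
  for (int t = L - 2; t >= 0; --t) {
    int d = gaps[t];
    for (int i = 0; i < NS; ++i) {
      for (int j = 0; j < NS; ++j)
        tmp[j] = lK(d, i, j, lself.begin(), lexit.begin()) +
                 em(t + 1, dir_of(j)) + beta(t + 1, j);
      beta(t, i) = lse_vec(tmp.data(), NS);
    }
  }

  double bcheck_tmp[NS];
  for (int j = 0; j < NS; ++j)
    bcheck_tmp[j] = lpi[j] + em(0, dir_of(j)) + beta(0, j);
  double ll_b = lse_vec(bcheck_tmp, NS);

  for (int t = 0; t < L; ++t)
    for (int j = 0; j < NS; ++j)
      gamma(t, j) = std::exp(alpha(t, j) + beta(t, j) - ll);

  NumericMatrix xi_sum(NS, NS);
  NumericVector selfw(NS);
  for (int t = 0; t + 1 < L; ++t) {
    int d = gaps[t];
    for (int i = 0; i < NS; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < NS; ++j) {
        double lx = alpha(t, i) + lK(d, i, j, lself.begin(), lexit.begin()) +
                    em(t + 1, dir_of(j)) + beta(t + 1, j) - ll;
        double x = std::exp(lx);
        xi_sum(i, j) += x;
        rowsum += x;
      }
      selfw[i] += (double)(d - 1) * rowsum;
    }
  }
  return List::create(_["loglik"] = ll, _["loglik_backward"] = ll_b,
                      _["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["selfw"] = selfw);
}

// Best log-probability over unit paths of the chain constrained to a fixed
// per-site direction labelling (1 = Up, 2 = Down, 3 = NoCh).
// [[Rcpp::export]]
double cpp_constrained_loglik(NumericMatrix em, IntegerVector gaps,
                              NumericVector lself, NumericVector lexit,
                              NumericVector lpi, IntegerVector labels) {
  int L = em.nrow();
  if (L < 1) stop("empty chain");
  if (labels.size() != L) stop("labels must have one entry per site");
  double v[2], vn[2];
  int s0 = (labels[0] - 1) * 2;
  for (int u = 0; u < 2; ++u) v[u] = lpi[s0 + u] + em(0, labels[0] - 1);
  for (int t = 0; t + 1 < L; ++t) {
    int d = gaps[t];
    if (d < 1) stop("gap length must be >= 1");
    int si = (labels[t] - 1) * 2, sj = (labels[t + 1] - 1) * 2;
    for (int un = 0; un < 2; ++un) {
      double b = NEG_INF;
      for (int u = 0; u < 2; ++u) {
        double x = v[u] + lK(d, si + u, sj + un, lself.begin(), lexit.begin());
        if (x > b) b = x;
      }
      vn[un] = b + em(t + 1, labels[t + 1] - 1);
    }
    v[0] = vn[0]; v[1] = vn[1];
  }
  return v[0] > v[1] ? v[0] : v[1];
}
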