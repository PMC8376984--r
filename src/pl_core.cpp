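#include <Rcpp.h>
using namespace Rcpp;

// Rankings are stored as an integer matrix, one row per ranking, items coded
// 1..n_items best-first, 0 = padding for rankings shorter than ncol. Stage k
// of a ranking of length L is a genuine multinomial choice only for k < L.

static double ll_range(const IntegerMatrix &ord, const NumericVector &w,
                       int lo, int hi, const std::vector<double> &alpha) {
  const int m = ord.ncol();
  double ll = 0.0;
  for (int r = lo; r < hi; ++r) {
    int len = 0;
    while (len < m && ord(r, len) > 0) ++len;
    double S = 0.0;
    for (int k = len - 1; k >= 0; --k) S += alpha[ord(r, k) - 1];
    double Srem = S;
    for (int k = 0; k < len - 1; ++k) {
      const double a = alpha[ord(r, k) - 1];
      ll += w[r] * (std::log(a) - std::log(Srem));
      Srem -= a;
    }
  }
  return ll;
}

// MM (minorize-maximize) fit over rows [lo, hi); alpha is modified in place.
// Returns iterations used; sets converged. Items absent from the range keep
// their incoming alpha. Items that never win are floored at a small value.
static int mm_range(const IntegerMatrix &ord, const NumericVector &w,
                    int lo, int hi, int n_items, std::vector<double> &alpha,
                    double tol, int max_iter, bool &converged) {
  const int m = ord.ncol();
  std::vector<double> wins(n_items, 0.0), den(n_items, 0.0);
  std::vector<bool> present(n_items, false);
  for (int r = lo; r < hi; ++r) {
    int len = 0;
    while (len < m && ord(r, len) > 0) ++len;
    for (int k = 0; k < len; ++k) {
      present[ord(r, k) - 1] = true;
      if (k < len - 1) wins[ord(r, k) - 1] += w[r];
    }
  }
  converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    std::fill(den.begin(), den.end(), 0.0);
    for (int r = lo; r < hi; ++r) {
      int len = 0;
      while (len < m && ord(r, len) > 0) ++len;
      double S = 0.0;
      for (int k = len - 1; k >= 0; --k) S += alpha[ord(r, k) - 1];
      double Srem = S, cum = 0.0;
      for (int k = 0; k < len; ++k) {
        if (k < len - 1) cum += 1.0 / Srem;   // stage k is a real choice
        den[ord(r, k) - 1] += w[r] * cum;
        Srem -= alpha[ord(r, k) - 1];
      }
    }
    double total = 0.0, delta = 0.0;
    std::vector<double> neu(alpha);
    for (int i = 0; i < n_items; ++i) {
      if (present[i] && den[i] > 0.0) {
        double a = wins[i] / den[i];
        if (!(a > 0.0)) a = 1e-12;
        neu[i] = a;
      }
      total += neu[i];
    }
    for (int i = 0; i < n_items; ++i) {
      neu[i] /= total;
      if (present[i] && wins[i] > 0.0) {
        double d = std::fabs(std::log(neu[i]) - std::log(alpha[i]));
        if (d > delta) delta = d;
      }
      alpha[i] = neu[i];
    }
    if (delta < tol) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;
  return it;
}

// [[Rcpp::export]]
double cpp_pl_ll(IntegerMatrix ord, NumericVector alpha, NumericVector w) {
  std::vector<double> a(alpha.begin(), alpha.end());
  return ll_range(ord, w, 0, ord.nrow(), a);
}

// [[Rcpp::export]]
List cpp_pl_mm(IntegerMatrix ord, int n_items, NumericVector w,
               NumericVector start, double tol, int max_iter) {
  std::vector<double> alpha(start.begin(), start.end());
  bool conv = false;
  int it = mm_range(ord, w, 0, ord.nrow(), n_items, alpha, tol, max_iter, conv);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iter"] = it, _["converged"] = conv,
                      _["loglik"] = ll_range(ord, w, 0, ord.nrow(), alpha));
}

// Per-item gradient pieces for the MAP fit: wins[i] and the stage-sum
// den[i] = sum over rankings/stages containing i of w / (remaining alpha sum),
// so that d loglik / d log alpha_i = wins[i] - alpha[i] * den[i].
// [[Rcpp::export]]
List cpp_pl_grad_parts(IntegerMatrix ord, int n_items, NumericVector alpha,
                       NumericVector w) {
  const int m = ord.ncol(), n = ord.nrow();
  NumericVector wins(n_items), den(n_items);
  for (int r = 0; r < n; ++r) {
    int len = 0;
    while (len < m && ord(r, len) > 0) ++len;
    double S = 0.0;
    for (int k = len - 1; k >= 0; --k) S += alpha[ord(r, k) - 1];
    double Srem = S, cum = 0.0;
    for (int k = 0; k < len; ++k) {
      if (k < len - 1) { wins[ord(r, k) - 1] += w[r]; cum += 1.0 / Srem; }
      den[ord(r, k) - 1] += w[r] * cum;
      Srem -= alpha[ord(r, k) - 1];
    }
  }
  return List::create(_["wins"] = wins, _["den"] = den);
}

// Warm-started scan over candidate split points. Rows of ord must already be
// sorted by the covariate; cut[j] = number of rows in the left child for
// candidate j (ascending). Children are refit by MM starting from the
// previous candidate's solution (parent alpha for the first).
// [[Rcpp::export]]
List cpp_split_scan(IntegerMatrix ord, int n_items, NumericVector w,
                    IntegerVector cut, NumericVector parent_alpha,
                    double tol, int max_iter) {
  const int n = ord.nrow(), J = cut.size();
  NumericVector ll_left(J), ll_right(J);
  std::vector<double> al(parent_alpha.begin(), parent_alpha.end());
  std::vector<double> ar(parent_alpha.begin(), parent_alpha.end());
  bool conv;
  for (int j = 0; j < J; ++j) {
    const int t = cut[j];
    mm_range(ord, w, 0, t, n_items, al, tol, max_iter, conv);
    mm_range(ord, w, t, n, n_items, ar, tol, max_iter, conv);
    ll_left[j] = ll_range(ord, w, 0, t, al);
    ll_right[j] = ll_range(ord, w, t, n, ar);
  }
  return List::create(_["ll_left"] = ll_left, _["ll_right"] = ll_right);
}
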