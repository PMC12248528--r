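#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// L2-regularised L1-loss (hinge) linear SVM solved by dual coordinate
// descent (Hsieh et al., ICML 2008, Algorithm 1) with a deterministic
// sweep order so repeated fits are bit-identical.  The bias is handled by
// augmenting a constant feature (regularised bias, liblinear -B 1 style).
//
// Problem:  min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w'x_i)
// y in {-1, +1}; x includes the trailing constant 1.

static void dcd_fit(const std::vector<double> &X, // n x d, column-major
                    const std::vector<double> &y, // +/-1
                    int n, int d, double C,
                    double tol, int max_iter,
                    std::vector<double> &w) {
  std::vector<double> alpha(n, 0.0);
  std::vector<double> Qii(n);
  w.assign(d, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double v = X[(size_t)j * n + i];
      s += v * v;
    }
    Qii[i] = s;
  }
  for (int iter = 0; iter < max_iter; ++iter) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (Qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X[(size_t)j * n + i];
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = (G < 0.0) ? G : 0.0;
      else if (alpha[i] >= C) PG = (G > 0.0) ? G : 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * X[(size_t)j * n + i];
      }
    }
    if (max_pg < tol) break;
  }
}

// [[Rcpp::export(name = ".cpp_linsvm_fit")]]
NumericVector cpp_linsvm_fit(NumericMatrix X, NumericVector y,
                             double C, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol(), d = p + 1;
  std::vector<double> Xa((size_t)d * n), yy(n);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) Xa[(size_t)j * n + i] = X(i, j);
  for (int i = 0; i < n; ++i) {
    Xa[(size_t)p * n + i] = 1.0;
    yy[i] = y[i] > 0 ? 1.0 : -1.0;
  }
  std::vector<double> w;
  dcd_fit(Xa, yy, n, d, C, tol, max_iter, w);
  NumericVector out(d);
  for (int j = 0; j < d; ++j) out[j] = w[j];
  return out; // p weights followed by the bias
}

static double mcc_from_counts(double tp, double fp, double fn, double tn) {
  double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den <= 0.0) return 0.0;
  return (tp * tn - fp * fn) / std::sqrt(den);
}

// Score every unordered feature couple by mean out-of-fold MCC (or
// accuracy) of a linear SVM fit on the couple's two columns within the
// supplied fold assignment.  Couples are emitted in lexicographic order
// (i < j, i ascending, then j), 1-based indices.
// [[Rcpp::export(name = ".cpp_score_couples")]]
NumericMatrix cpp_score_couples(NumericMatrix X, NumericVector y,
                                IntegerVector fold, double C,
                                double tol, int max_iter,
                                std::string metric) {
  int n = X.nrow(), p = X.ncol();
  int nfold = 0;
  for (int i = 0; i < n; ++i) if (fold[i] > nfold) nfold = fold[i];
  bool use_mcc = (metric == "mcc");
  int ncpl = p * (p - 1) / 2;
  NumericMatrix out(ncpl, 3);
  std::vector<double> yy(n);
  for (int i = 0; i < n; ++i) yy[i] = y[i] > 0 ? 1.0 : -1.0;

  std::vector<double> Xtr, ytr, w;
  int row = 0;
  for (int a = 0; a < p; ++a) {
    for (int b = a + 1; b < p; ++b) {
      double acc_score = 0.0;
      int used_folds = 0;
      for (int f = 1; f <= nfold; ++f) {
        int ntr = 0;
        for (int i = 0; i < n; ++i) if (fold[i] != f) ++ntr;
        if (ntr == 0 || ntr == n) continue;
        Xtr.assign((size_t)3 * ntr, 1.0); // cols: a, b, bias
        ytr.assign(ntr, 0.0);
        int k = 0;
        bool pos = false, neg = false;
        for (int i = 0; i < n; ++i) {
          if (fold[i] == f) continue;
          Xtr[k] = X(i, a);
          Xtr[(size_t)ntr + k] = X(i, b);
          ytr[k] = yy[i];
          if (yy[i] > 0) pos = true; else neg = true;
          ++k;
        }
        if (!pos || !neg) continue; // degenerate training fold
        dcd_fit(Xtr, ytr, ntr, 3, C, tol, max_iter, w);
        double tp = 0, fp = 0, fnc = 0, tn = 0;
        for (int i = 0; i < n; ++i) {
          if (fold[i] != f) continue;
          double s = w[0] * X(i, a) + w[1] * X(i, b) + w[2];
          bool pred = s > 0.0, truth = yy[i] > 0.0;
          if (pred && truth) ++tp;
          else if (pred && !truth) ++fp;
          else if (!pred && truth) ++fnc;
          else ++tn;
        }
        double sc;
        if (use_mcc) sc = mcc_from_counts(tp, fp, fnc, tn);
        else sc = (tp + tn) / (tp + fp + fnc + tn);
        acc_score += sc;
        ++used_folds;
      }
      out(row, 0) = a + 1;
      out(row, 1) = b + 1;
      out(row, 2) = used_folds > 0 ? acc_score / used_folds : 0.0;
      ++row;
    }
  }
  return out;
}
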