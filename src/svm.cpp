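#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin kernel SVM trained by SMO with maximal-violating-pair working
// set selection (Keerthi et al. style) on a precomputed Gram matrix.
// Candidate pools are small (<= a few hundred training rows), so O(n) pair
// selection and dense gradient updates are plenty fast.

struct SvmFit {
  std::vector<double> alpha;
  double b;
};

// K: ntr x ntr Gram over training rows; y in {-1,+1}
static SvmFit smo_train(const std::vector<double>& K, int n,
                        const std::vector<int>& y, double C,
                        double tol, int max_iter) {
  std::vector<double> alpha(n, 0.0);
  std::vector<double> F(n);          // F_i = sum_k a_k y_k K_ki - y_i
  for (int i = 0; i < n; ++i) F[i] = -y[i];

  int iter = 0;
  double b_up = 0.0, b_low = 0.0;
  while (iter++ < max_iter) {
    // working set: i = argmin F over I_up, j = argmax F over I_low
    int i = -1, j = -1;
    double fmin = R_PosInf, fmax = R_NegInf;
    for (int t = 0; t < n; ++t) {
      bool in_up  = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (in_up && F[t] < fmin) { fmin = F[t]; i = t; }
      if (in_low && F[t] > fmax) { fmax = F[t]; j = t; }
    }
    b_up = fmin; b_low = fmax;
    if (i < 0 || j < 0 || b_low - b_up < tol) break;

    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta < 1e-12) eta = 1e-12;
    double ai_old = alpha[i], aj_old = alpha[j];
    double s = (double)y[i] * y[j];
    // bounds for alpha[j]
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    double aj = aj_old + y[j] * (F[i] - F[j]) / eta;
    if (aj < L) aj = L; else if (aj > H) aj = H;
    double ai = ai_old + s * (aj_old - aj);
    if (std::fabs(aj - aj_old) < 1e-14) break;  // numerically stuck
    alpha[i] = ai; alpha[j] = aj;
    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    for (int t = 0; t < n; ++t)
      F[t] += di * K[(size_t)i * n + t] + dj * K[(size_t)j * n + t];
  }
  SvmFit fit;
  fit.alpha = alpha;
  fit.b = -(b_up + b_low) / 2.0;
  return fit;
}

// family: 0 = rbf exp(-sigma * ||x-z||^2), 1 = poly (x.z)^degree
static inline double kval(const double* X, int nrow, int p,
                          int a, int b, int family,
                          double sigma, double degree) {
  double acc = 0.0;
  if (family == 0) {
    for (int k = 0; k < p; ++k) {
      double d = X[(size_t)k * nrow + a] - X[(size_t)k * nrow + b];
      acc += d * d;
    }
    return std::exp(-sigma * acc);
  } else {
    for (int k = 0; k < p; ++k)
      acc += X[(size_t)k * nrow + a] * X[(size_t)k * nrow + b];
    return std::pow(acc, degree);
  }
}

// Mean k-fold CV accuracy of a one-vs-rest soft-margin SVM on X.
// y: class ids 0..(nclass-1); fold: fold ids 0..(nfold-1) per row.
// [[Rcpp::export(name = ".cv_svm_accuracy_cpp")]]
double cv_svm_accuracy_cpp(NumericMatrix X, IntegerVector y, IntegerVector fold,
                           int nclass, int nfold, int family, double sigma,
                           double degree, double C, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol();
  const double* Xp = REAL(X);
  // full Gram once; folds reuse sub-blocks
  std::vector<double> G((size_t)n * n);
  for (int a = 0; a < n; ++a) {
    G[(size_t)a * n + a] = kval(Xp, n, p, a, a, family, sigma, degree);
    for (int b = a + 1; b < n; ++b) {
      double v = kval(Xp, n, p, a, b, family, sigma, degree);
      G[(size_t)a * n + b] = v;
      G[(size_t)b * n + a] = v;
    }
  }
  double acc_sum = 0.0;
  int folds_used = 0;
  for (int f = 0; f < nfold; ++f) {
    std::vector<int> tr, te;
    tr.reserve(n); te.reserve(n);
    for (int t = 0; t < n; ++t) (fold[t] == f ? te : tr).push_back(t);
    if (te.empty() || tr.empty()) continue;
    int ntr = (int)tr.size(), nte = (int)te.size();
    std::vector<double> Ktr((size_t)ntr * ntr);
    for (int a = 0; a < ntr; ++a)
      for (int b = 0; b < ntr; ++b)
        Ktr[(size_t)a * ntr + b] = G[(size_t)tr[a] * n + tr[b]];

    // decision values per class (one-vs-rest); binary uses one machine
    int nmach = (nclass == 2) ? 1 : nclass;
    std::vector<double> dec((size_t)nte * nmach, 0.0);
    std::vector<bool> seen(nmach, false);
    for (int c = 0; c < nmach; ++c) {
      std::vector<int> yy(ntr);
      int npos = 0;
      for (int a = 0; a < ntr; ++a) {
        yy[a] = (y[tr[a]] == c) ? 1 : -1;
        if (yy[a] == 1) ++npos;
      }
      if (npos == 0 || npos == ntr) {
        // degenerate training labels: constant decision
        double v = (npos == ntr) ? 1.0 : -1.0;
        for (int t = 0; t < nte; ++t) dec[(size_t)t * nmach + c] = v;
        seen[c] = true;
        continue;
      }
      SvmFit fit = smo_train(Ktr, ntr, yy, C, tol, max_iter);
      for (int t = 0; t < nte; ++t) {
        double g = fit.b;
        for (int a = 0; a < ntr; ++a) {
          if (fit.alpha[a] > 0)
            g += fit.alpha[a] * yy[a] * G[(size_t)tr[a] * n + te[t]];
        }
        dec[(size_t)t * nmach + c] = g;
      }
      seen[c] = true;
    }
    int hits = 0;
    for (int t = 0; t < nte; ++t) {
      int pred;
      if (nclass == 2) {
        pred = dec[(size_t)t * nmach] >= 0 ? 0 : 1;
      } else {
        pred = 0;
        double best = R_NegInf;
        for (int c = 0; c < nmach; ++c) {
          double v = dec[(size_t)t * nmach + c];
          if (v > best) { best = v; pred = c; }
        }
      }
      if (pred == y[te[t]]) ++hits;
    }
    acc_sum += (double)hits / nte;
    ++folds_used;
  }
  if (folds_used == 0) return NA_REAL;
  return acc_sum / folds_used;
}

// Train on all rows of Xtr and report accuracy on Xte (held-out reporting).
// [[Rcpp::export(name = ".svm_holdout_accuracy_cpp")]]
double svm_holdout_accuracy_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                NumericMatrix Xte, IntegerVector yte,
                                int nclass, int family, double sigma,
                                double degree, double C, double tol,
                                int max_iter) {
  int ntr = Xtr.nrow(), nte = Xte.nrow(), p = Xtr.ncol();
  const double* A = REAL(Xtr);
  const double* B = REAL(Xte);
  std::vector<double> Ktr((size_t)ntr * ntr);
  for (int a = 0; a < ntr; ++a)
    for (int b = a; b < ntr; ++b) {
      double v = kval(A, ntr, p, a, b, family, sigma, degree);
      Ktr[(size_t)a * ntr + b] = v;
      Ktr[(size_t)b * ntr + a] = v;
    }
  auto kcross = [&](int a, int t) {
    double acc = 0.0;
    if (family == 0) {
      for (int k = 0; k < p; ++k) {
        double d = A[(size_t)k * ntr + a] - B[(size_t)k * nte + t];
        acc += d * d;
      }
      return std::exp(-sigma * acc);
    } else {
      for (int k = 0; k < p; ++k)
        acc += A[(size_t)k * ntr + a] * B[(size_t)k * nte + t];
      return std::pow(acc, degree);
    }
  };
  int nmach = (nclass == 2) ? 1 : nclass;
  std::vector<double> dec((size_t)nte * nmach, 0.0);
  for (int c = 0; c < nmach; ++c) {
    std::vector<int> yy(ntr);
    int npos = 0;
    for (int a = 0; a < ntr; ++a) {
      yy[a] = (ytr[a] == c) ? 1 : -1;
      if (yy[a] == 1) ++npos;
    }
    if (npos == 0 || npos == ntr) {
      double v = (npos == ntr) ? 1.0 : -1.0;
      for (int t = 0; t < nte; ++t) dec[(size_t)t * nmach + c] = v;
      continue;
    }
    SvmFit fit = smo_train(Ktr, ntr, yy, C, tol, max_iter);
    for (int t = 0; t < nte; ++t) {
      double g = fit.b;
      for (int a = 0; a < ntr; ++a)
        if (fit.alpha[a] > 0) g += fit.alpha[a] * yy[a] * kcross(a, t);
      dec[(size_t)t * nmach + c] = g;
    }
  }
  int hits = 0;
  for (int t = 0; t < nte; ++t) {
    int pred;
    if (nclass == 2) {
      pred = dec[(size_t)t * nmach] >= 0 ? 0 : 1;
    } else {
      pred = 0;
      double best = R_NegInf;
      for (int c = 0; c < nmach; ++c) {
        double v = dec[(size_t)t * nmach + c];
        if (v > best) { best = v; pred = c; }
      }
    }
    if (pred == yte[t]) ++hits;
  }
  return (double)hits / nte;
}
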