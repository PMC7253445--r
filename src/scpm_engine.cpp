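// Cross-validated sCPM engine.
//
// For one feature matrix and a batch of outcome vectors (observed outcome in
// column 0, permuted outcomes after it), runs the full cross-validation loop:
// in-fold Spearman feature selection (threshold on the t-approximation
// critical |r|), largest-drop fallback when nothing passes, per-network
// ordinary least squares of the outcome on mean network strength, prediction
// of held-out rows, and Spearman predictive power per outcome column.
//
// Fold-wise standardized feature ranks depend only on the feature matrix and
// the fold assignment, so they are computed once and shared across all
// outcome columns; this is what makes 10^5 permuted CV runs affordable.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Midranks (average ranks for ties), 1-based.
static std::vector<double> midrank_vec(const std::vector<double>& v) {
  const int n = static_cast<int>(v.size());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    const double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
  return r;
}

// Standardize to mean 0, sd 1 (denominator n-1); false if constant.
static bool standardize_vec(std::vector<double>& v) {
  const int n = static_cast<int>(v.size());
  double m = 0.0;
  for (double d : v) m += d;
  m /= n;
  double ss = 0.0;
  for (double d : v) ss += (d - m) * (d - m);
  if (ss <= 0.0) return false;
  const double s = std::sqrt(ss / (n - 1));
  for (double& d : v) d = (d - m) / s;
  return true;
}

// Spearman correlation of two equal-length vectors; NA if either constant.
static double spearman_cor(const std::vector<double>& x,
                           const std::vector<double>& y) {
  std::vector<double> rx = midrank_vec(x);
  std::vector<double> ry = midrank_vec(y);
  if (!standardize_vec(rx) || !standardize_vec(ry)) return NA_REAL;
  const int n = static_cast<int>(rx.size());
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += rx[i] * ry[i];
  return acc / (n - 1);
}

// Largest-drop fallback: rank |r| strongest to weakest, find the largest gap
// between successive coefficients (first occurrence on ties), keep everything
// above it. All-equal coefficients degenerate to keeping the single strongest.
static void largest_drop(const std::vector<double>& r,
                         const std::vector<int>& valid_ids,
                         std::vector<int>& sel) {
  const int q = static_cast<int>(valid_ids.size());
  if (q == 0) return;
  if (q == 1) {
    sel[valid_ids[0]] = (r[valid_ids[0]] >= 0.0) ? 1 : -1;
    return;
  }
  std::vector<int> ord(valid_ids);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return std::llround(std::fabs(r[a]) * 1e9) >
           std::llround(std::fabs(r[b]) * 1e9);
  });
  // gaps are compared at 1e-9 resolution (first occurrence wins) so that
  // exact rational ties in rank correlations are broken deterministically
  int X = 1;
  double best_gap = -1.0;
  for (int i = 0; i + 1 < q; ++i) {
    const double gap = std::fabs(r[ord[i]]) - std::fabs(r[ord[i + 1]]);
    if (gap > best_gap + 1e-9) {
      best_gap = gap;
      X = i + 1;
    }
  }
  for (int i = 0; i < X; ++i) sel[ord[i]] = (r[ord[i]] >= 0.0) ? 1 : -1;
}

struct FoldPre {
  std::vector<int> train, test;
  std::vector<double> Z;     // m x p column-major standardized feature ranks
  std::vector<char> valid;   // non-constant feature columns in the fold
  double rcrit;
  int m;
};

// Univariate OLS of y[train] on mean strength over ids; predicts test rows.
// Empty ids or degenerate strength -> intercept-only (training mean).
static void fit_predict_net(const NumericMatrix& X, const double* y,
                            const std::vector<int>& train,
                            const std::vector<int>& test,
                            const std::vector<int>& ids, double* pred,
                            double* b0_out, double* b1_out) {
  const int m = static_cast<int>(train.size());
  double ymean = 0.0;
  for (int i : train) ymean += y[i];
  ymean /= m;
  if (ids.empty()) {
    for (int i : test) pred[i] = ymean;
    *b0_out = ymean;
    *b1_out = NA_REAL;
    return;
  }
  const double k = static_cast<double>(ids.size());
  auto strength = [&](int row) {
    double s = 0.0;
    for (int j : ids) s += X(row, j);
    return s / k;
  };
  double smean = 0.0;
  for (int i : train) smean += strength(i);
  smean /= m;
  double sxx = 0.0, sxy = 0.0;
  for (int i : train) {
    const double d = strength(i) - smean;
    sxx += d * d;
    sxy += d * (y[i] - ymean);
  }
  double b1 = 0.0, b0 = ymean;
  if (sxx > 1e-12) {
    b1 = sxy / sxx;
    b0 = ymean - b1 * smean;
  }
  for (int i : test) pred[i] = b0 + b1 * strength(i);
  *b0_out = b0;
  *b1_out = b1;
}

// Combined two-predictor OLS on [1, pos strength, neg strength]; degenerate
// designs fall back to the available single network or the training mean.
static void fit_predict_combined(const NumericMatrix& X, const double* y,
                                 const std::vector<int>& train,
                                 const std::vector<int>& test,
                                 const std::vector<int>& pos,
                                 const std::vector<int>& neg, double* pred,
                                 double* b_out /* length 3 */) {
  b_out[0] = NA_REAL;
  b_out[1] = NA_REAL;
  b_out[2] = NA_REAL;
  if (pos.empty() || neg.empty()) {
    double d0, d1;
    const std::vector<int>& ids = pos.empty() ? neg : pos;
    fit_predict_net(X, y, train, test, ids, pred, &d0, &d1);
    b_out[0] = d0;
    if (pos.empty() && !neg.empty()) b_out[2] = d1;
    if (!pos.empty()) b_out[1] = d1;
    return;
  }
  const int m = static_cast<int>(train.size());
  auto strength = [&](int row, const std::vector<int>& ids) {
    double s = 0.0;
    for (int j : ids) s += X(row, j);
    return s / ids.size();
  };
  // normal equations for [1, sp, sn]
  double S[3][3] = {{0}}, b[3] = {0};
  for (int i : train) {
    const double v[3] = {1.0, strength(i, pos), strength(i, neg)};
    for (int a = 0; a < 3; ++a) {
      for (int c = 0; c < 3; ++c) S[a][c] += v[a] * v[c];
      b[a] += v[a] * y[i];
    }
  }
  // Gaussian elimination with partial pivoting
  double A[3][4];
  for (int a = 0; a < 3; ++a) {
    for (int c = 0; c < 3; ++c) A[a][c] = S[a][c];
    A[a][3] = b[a];
  }
  bool ok = true;
  for (int col = 0; col < 3 && ok; ++col) {
    int piv = col;
    for (int rr = col + 1; rr < 3; ++rr)
      if (std::fabs(A[rr][col]) > std::fabs(A[piv][col])) piv = rr;
    if (std::fabs(A[piv][col]) < 1e-10 * m) {
      ok = false;
      break;
    }
    if (piv != col)
      for (int c = 0; c < 4; ++c) std::swap(A[piv][c], A[col][c]);
    for (int rr = 0; rr < 3; ++rr) {
      if (rr == col) continue;
      const double f = A[rr][col] / A[col][col];
      for (int c = col; c < 4; ++c) A[rr][c] -= f * A[col][c];
    }
  }
  if (!ok) {
    double d0, d1;
    fit_predict_net(X, y, train, test, pos, pred, &d0, &d1);
    b_out[0] = d0;
    b_out[1] = d1;
    return;
  }
  const double beta[3] = {A[0][3] / A[0][0], A[1][3] / A[1][1],
                          A[2][3] / A[2][2]};
  for (int i : test)
    pred[i] = beta[0] + beta[1] * strength(i, pos) + beta[2] * strength(i, neg);
  b_out[0] = beta[0];
  b_out[1] = beta[1];
  b_out[2] = beta[2];
}

// [[Rcpp::export]]
List cpp_scpm_engine(NumericMatrix X, NumericMatrix Y, IntegerVector fold_id,
                     double p_thresh, bool detail) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int n_out = Y.ncol();
  if (Y.nrow() != n) stop("feature/outcome row mismatch");
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, fold_id[i] + 1);

  // ---- per-fold precomputation (features only) ----
  std::vector<FoldPre> folds(K);
  for (int f = 0; f < K; ++f) {
    for (int i = 0; i < n; ++i) {
      if (fold_id[i] == f)
        folds[f].test.push_back(i);
      else
        folds[f].train.push_back(i);
    }
    const int m = static_cast<int>(folds[f].train.size());
    if (m < 4) stop("fewer than 4 training rows in a fold");
    folds[f].m = m;
    folds[f].Z.assign(static_cast<size_t>(m) * p, 0.0);
    folds[f].valid.assign(p, 0);
    std::vector<double> col(m);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < m; ++i) col[i] = X(folds[f].train[i], j);
      std::vector<double> rk = midrank_vec(col);
      if (standardize_vec(rk)) {
        folds[f].valid[j] = 1;
        std::copy(rk.begin(), rk.end(),
                  folds[f].Z.begin() + static_cast<size_t>(j) * m);
      }
    }
    const double df = m - 2;
    const double tq = R::qt(1.0 - p_thresh / 2.0, df, 1, 0);
    folds[f].rcrit = tq / std::sqrt(df + tq * tq);
  }

  NumericMatrix rs(3, n_out);  // rows: pos, neg, combined
  LogicalMatrix ef_pos(p, n_out), ef_neg(p, n_out);

  IntegerMatrix sel_det;
  NumericMatrix corr_det, coef_det, pred_det;
  LogicalVector fb_det;
  if (detail) {
    sel_det = IntegerMatrix(K, p);
    corr_det = NumericMatrix(K, p);
    coef_det = NumericMatrix(K, 7);
    pred_det = NumericMatrix(n, 3);
    fb_det = LogicalVector(K);
  }

  std::vector<double> pred_pos(n), pred_neg(n), pred_comb(n);
  std::vector<double> yfull(n), r(p);
  std::vector<int> sel(p);

  for (int c = 0; c < n_out; ++c) {
    for (int i = 0; i < n; ++i) yfull[i] = Y(i, c);
    std::vector<int> cnt_pos(p, 0), cnt_neg(p, 0);

    for (int f = 0; f < K; ++f) {
      const FoldPre& F = folds[f];
      std::vector<double> ytr(F.m);
      for (int i = 0; i < F.m; ++i) ytr[i] = yfull[F.train[i]];
      std::vector<double> yr = midrank_vec(ytr);
      const bool y_ok = standardize_vec(yr);

      std::fill(r.begin(), r.end(), NA_REAL);
      std::fill(sel.begin(), sel.end(), 0);
      bool fb = false;
      std::vector<int> valid_ids;
      if (y_ok) {
        for (int j = 0; j < p; ++j) {
          if (!F.valid[j]) continue;
          const double* z = F.Z.data() + static_cast<size_t>(j) * F.m;
          double acc = 0.0;
          for (int i = 0; i < F.m; ++i) acc += z[i] * yr[i];
          r[j] = acc / (F.m - 1);
          valid_ids.push_back(j);
          if (std::fabs(r[j]) > F.rcrit) sel[j] = (r[j] > 0.0) ? 1 : -1;
        }
        bool any = false;
        for (int j = 0; j < p; ++j)
          if (sel[j] != 0) {
            any = true;
            break;
          }
        if (!any && !valid_ids.empty()) {
          largest_drop(r, valid_ids, sel);
          fb = true;
        }
      }

      std::vector<int> pos, neg;
      for (int j = 0; j < p; ++j) {
        if (sel[j] == 1) {
          pos.push_back(j);
          ++cnt_pos[j];
        } else if (sel[j] == -1) {
          neg.push_back(j);
          ++cnt_neg[j];
        }
      }

      double b0p, b1p, b0n, b1n, bc[3];
      fit_predict_net(X, yfull.data(), F.train, F.test, pos, pred_pos.data(),
                      &b0p, &b1p);
      fit_predict_net(X, yfull.data(), F.train, F.test, neg, pred_neg.data(),
                      &b0n, &b1n);
      fit_predict_combined(X, yfull.data(), F.train, F.test, pos, neg,
                           pred_comb.data(), bc);

      if (detail && c == 0) {
        for (int j = 0; j < p; ++j) {
          sel_det(f, j) = sel[j];
          corr_det(f, j) = r[j];
        }
        coef_det(f, 0) = b0p;
        coef_det(f, 1) = b1p;
        coef_det(f, 2) = b0n;
        coef_det(f, 3) = b1n;
        coef_det(f, 4) = bc[0];
        coef_det(f, 5) = bc[1];
        coef_det(f, 6) = bc[2];
        fb_det[f] = fb;
      }
    }

    for (int j = 0; j < p; ++j) {
      ef_pos(j, c) = (cnt_pos[j] == K);
      ef_neg(j, c) = (cnt_neg[j] == K);
    }
    rs(0, c) = spearman_cor(pred_pos, yfull);
    rs(1, c) = spearman_cor(pred_neg, yfull);
    rs(2, c) = spearman_cor(pred_comb, yfull);
    if (detail && c == 0) {
      for (int i = 0; i < n; ++i) {
        pred_det(i, 0) = pred_pos[i];
        pred_det(i, 1) = pred_neg[i];
        pred_det(i, 2) = pred_comb[i];
      }
    }
  }

  List out = List::create(_["rs"] = rs, _["everyfold_pos"] = ef_pos,
                          _["everyfold_neg"] = ef_neg);
  if (detail) {
    out["selection"] = sel_det;
    out["fold_corr"] = corr_det;
    out["fold_coef"] = coef_det;
    out["fallback"] = fb_det;
    out["predicted"] = pred_det;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_spearman(NumericVector x, NumericVector y) {
  std::vector<double> a(x.begin(), x.end()), b(y.begin(), y.end());
  return spearman_cor(a, b);
}
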