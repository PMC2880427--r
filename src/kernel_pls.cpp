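// Kernel-side PLS1 leave-one-out machinery.
//
// All NIPALS quantities for centered, unscaled predictors live in the
// row space of X, so leave-one-out refits can run on the n x n Gram
// matrix K0 = X X' instead of the n x p data: weights are W = X'R and
// coefficient vectors B = X'c for n-vectors accumulated here. The pure
// R implementations in R/pls.R are the readable reference; these loops
// are the hot path of the nested cross-validation and are verified
// against the R path in the test suite.
//
// The leave-one-out pass processes all n segments simultaneously:
// every segment's residual carrier lives in a column of an n x n
// matrix (zero at its held-out row, centered over its training rows),
// so the n kernel matvecs of one NIPALS step collapse into a single
// matrix product with the fold's Gram matrix. Dropping a sample and
// double-centering are applied implicitly through means, never by
// building per-segment submatrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct KFit {
  mat T;   // scores, m x A
  mat R;   // weight basis (W = X'R), m x A
  vec q;   // y-loadings
  vec tt;  // squared score norms
  mat V;   // P'W, A x A
  int A;   // effective number of components
};

// NIPALS PLS1 on a centered Gram matrix (single fit; used for the
// full-data coefficients)
KFit kfit(const mat& K, const vec& yc, const int A_max) {
  const uword m = yc.n_elem;
  KFit f;
  f.T.zeros(m, A_max);
  f.R.zeros(m, A_max);
  f.q.zeros(A_max);
  f.tt.zeros(A_max);
  mat KR(m, A_max, fill::zeros);  // columns K * R.col(a), reused for V
  f.A = 0;
  vec r = yc;
  for (int a = 0; a < A_max; ++a) {
    vec u = K * r;
    double wn2 = dot(r, u);
    if (wn2 < 1e-12) break;
    vec t = u;
    for (int i = 0; i < a; ++i)
      t -= f.T.col(i) * (dot(f.T.col(i), u) / f.tt(i));
    t /= std::sqrt(wn2);
    double t2 = dot(t, t);
    if (t2 < 1e-12) break;
    f.T.col(a) = t;
    f.R.col(a) = r / std::sqrt(wn2);
    KR.col(a) = u / std::sqrt(wn2);
    f.tt(a) = t2;
    f.q(a) = dot(yc, t) / t2;
    r -= t * (dot(t, yc) / t2);
    f.A = a + 1;
  }
  if (f.A > 0) {
    f.T = f.T.cols(0, f.A - 1);
    f.R = f.R.cols(0, f.A - 1);
    f.q = f.q.subvec(0, f.A - 1);
    f.tt = f.tt.subvec(0, f.A - 1);
    f.V = (f.T.t() * KR.cols(0, f.A - 1));
    f.V.each_col() /= f.tt;
  }
  return f;
}

// n-vector c with B = X_c' c at component count a (1-based)
vec kcvec(const KFit& f, const int a) {
  return f.R.cols(0, a - 1) *
         solve(f.V.submat(0, 0, a - 1, a - 1), f.q.subvec(0, a - 1));
}

// double-centered Gram over the index set idx
mat centered_gram(const mat& K0, const uvec& idx, vec& row_means,
                  double& grand_mean) {
  mat K = K0.submat(idx, idx);
  row_means = mean(K, 1);
  grand_mean = mean(row_means);
  K.each_col() -= row_means;
  K.each_row() -= row_means.t();
  K += grand_mean;
  return K;
}

}  // namespace

// One pass over all leave-one-out segments: held-out scores at every
// component count, plus the per-segment factors (weight basis R, V =
// P'W, y-loadings q) needed to assemble coefficient vectors at any
// component count afterwards without refitting.
// keep: 0-based indices into K0/y. Failed segments (one-class or
// rank-zero training sets) have NaN score rows and A = 0.
// [[Rcpp::export]]
Rcpp::List cpp_loo_fit(const arma::mat& K0, const arma::vec& y,
                       const arma::uvec& keep, const int A_max) {
  const uword n = keep.n_elem;
  const double nm1 = double(n) - 1.0;
  mat Kf = K0.submat(keep, keep);
  vec yk = y.elem(keep);
  vec S = sum(Kf, 1);          // Gram row sums, for implicit centering
  const double Stot = accu(S);
  const double ysum = accu(yk);

  mat Y0(n, n, fill::zeros);   // column m: centered training response
  mat Rcur(n, n, fill::zeros); // column m: current residual carrier
  vec ymean(n, fill::zeros);
  uvec alive(n, fill::zeros);
  for (uword m = 0; m < n; ++m) {
    // a constant training response (e.g. one-class split) cannot be fit
    bool constant = true;
    double first = datum::nan;
    for (uword i = 0; i < n; ++i) {
      if (i == m) continue;
      if (std::isnan(first)) first = yk(i);
      else if (yk(i) != first) { constant = false; break; }
    }
    if (constant) continue;
    ymean(m) = (ysum - yk(m)) / nm1;
    for (uword i = 0; i < n; ++i)
      if (i != m) Y0(i, m) = yk(i) - ymean(m);
    Rcur.col(m) = Y0.col(m);
    alive(m) = 1;
  }

  cube Tstore(n, A_max, n, fill::zeros);
  cube Rstore(n, A_max, n, fill::zeros);
  cube Vstore(A_max, A_max, n, fill::zeros);
  mat qstore(A_max, n, fill::zeros);
  mat ttm(A_max, n, fill::zeros);
  ivec Aeff(n, fill::zeros);

  for (int a = 0; a < A_max; ++a) {
    if (accu(alive) == 0) break;
    mat U = Kf * Rcur;  // all segments' kernel matvecs in one product
    for (uword m = 0; m < n; ++m) {
      if (!alive(m)) continue;
      vec u = U.col(m);
      u(m) = 0.0;  // held-out row never contributes
      double wn2 = dot(Rcur.col(m), u);
      if (wn2 < 1e-12) { alive(m) = 0; Rcur.col(m).zeros(); continue; }
      // center over the training support, then deflate
      double cmean = accu(u) / nm1;
      vec t = u - cmean;
      t(m) = 0.0;
      const mat& Tm = Tstore.slice(m);
      for (int i = 0; i < a; ++i)
        t -= Tm.col(i) * (dot(Tm.col(i), u) / ttm(i, m));
      double sw = std::sqrt(wn2);
      t /= sw;
      double t2 = dot(t, t);
      if (t2 < 1e-12) { alive(m) = 0; Rcur.col(m).zeros(); continue; }
      Tstore.slice(m).col(a) = t;
      ttm(a, m) = t2;
      Rstore.slice(m).col(a) = Rcur.col(m) / sw;
      qstore(a, m) = dot(Y0.col(m), t) / t2;
      for (int i = 0; i <= a; ++i)
        Vstore.slice(m)(i, a) =
            dot(Tstore.slice(m).col(i), u) / (sw * ttm(i, m));
      Rcur.col(m) -= t * (dot(t, Y0.col(m)) / t2);
      Aeff(m) = a + 1;
    }
  }

  // held-out prediction scores at every component count
  mat scores(n, A_max);
  scores.fill(datum::nan);
  for (uword m = 0; m < n; ++m) {
    int A = Aeff(m);
    if (A == 0) continue;
    // centered kernel vector between held-out m and its training rows
    double Sm = S(m);
    double gm = (Stot - 2.0 * Sm + Kf(m, m)) / (nm1 * nm1);
    double kmean = (Sm - Kf(m, m)) / nm1;
    vec ks(n, fill::zeros);
    for (uword i = 0; i < n; ++i)
      if (i != m)
        ks(i) = Kf(m, i) - kmean - (S(i) - Kf(i, m)) / nm1 + gm;
    vec ts(A);
    double cum = ymean(m);
    int col = 0;
    for (int a = 0; a < A; ++a) {
      double s = dot(Rstore.slice(m).col(a), ks);
      for (int i = 0; i < a; ++i) s -= ts(i) * Vstore.slice(m)(i, a);
      ts(a) = s;
      cum += s * qstore(a, m);
      scores(m, a) = cum;
      col = a;
    }
    for (int a = col + 1; a < A_max; ++a) scores(m, a) = scores(m, col);
  }

  return Rcpp::List::create(
      Rcpp::Named("scores") = scores, Rcpp::Named("Rstore") = Rstore,
      Rcpp::Named("Vstore") = Vstore, Rcpp::Named("qstore") = qstore,
      Rcpp::Named("A") = Aeff);
}

// Assemble per-segment coefficient carriers at component count a_opt
// (1-based) from the factors stored by cpp_loo_fit. Column m holds the
// training-sample weights of segment m in keep space (zero at the
// held-out row); B_m = X_tr' c_m - xbar_tr * sum(c_m) is assembled in
// R. Failed segments stay all-zero.
// [[Rcpp::export]]
arma::mat cpp_loo_cvecs(const arma::cube& Rstore, const arma::cube& Vstore,
                        const arma::mat& qstore,
                        const arma::ivec& Astore, const int a_opt) {
  const uword n = Rstore.n_slices;
  mat C(n, n, fill::zeros);
  for (uword m = 0; m < n; ++m) {
    if (Astore(m) == 0) continue;
    int a = std::min(a_opt, (int)Astore(m));
    C.col(m) = Rstore.slice(m).cols(0, a - 1) *
               solve(Vstore.slice(m).submat(0, 0, a - 1, a - 1),
                     qstore.col(m).subvec(0, a - 1));
  }
  return C;
}

// Full-data coefficient carrier at component count a (1-based):
// B = X_keep_c' c. Returns c (length n) with the attained component
// count appended.
// [[Rcpp::export]]
arma::vec cpp_full_cvec(const arma::mat& K0, const arma::vec& y,
                        const arma::uvec& keep, const int a) {
  vec yk = y.elem(keep);
  vec rm;
  double gm;
  mat Kc = centered_gram(K0, keep, rm, gm);
  KFit f = kfit(Kc, yk - mean(yk), a);
  if (f.A == 0) Rcpp::stop("no usable component");
  vec cv = kcvec(f, std::min(a, f.A));
  vec out(cv.n_elem + 1);
  out.subvec(0, cv.n_elem - 1) = cv;
  out(cv.n_elem) = f.A;
  return out;
}
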