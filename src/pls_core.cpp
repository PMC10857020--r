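// NIPALS PLS1 core and the piecewise-direct-standardization fitting loop.
// Kept in C++ because transfer tuning fits thousands of small local PLS
// models (one per wavelength per window per CV fold).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int nipals_path(const arma::mat& X, const arma::vec& y, int A,
                       arma::rowvec& x_mean, double& y_mean,
                       arma::mat& coefs);
static void pds_core(const arma::mat& field, const arma::mat& lab,
                     const arma::ivec& segment, int w, int A,
                     arma::cube& coefs, arma::mat& intercepts);
static arma::mat pds_apply_core(const arma::mat& field, const arma::mat& band,
                                const arma::vec& intercepts, int w);

// Sequential NIPALS extraction on mean-centered X, y (no variance scaling).
// Returns per-component weights W, x-loadings P, scores T, y-loadings q,
// explained sum of squares SS_a = q_a^2 * t_a't_a, and the cumulative
// regression coefficient matrix coefs (p x A): column a holds beta for a
// model truncated at a components.  Extraction stops early when the
// remaining covariance X'y is numerically zero.
// [[Rcpp::export]]
Rcpp::List cpp_pls_fit(const arma::mat& X, const arma::vec& y, int A) {
  const int n = X.n_rows, p = X.n_cols;
  const double tol = 1e-12;

  rowvec x_mean = mean(X, 0);
  double y_mean = mean(y);
  mat Xc = X.each_row() - x_mean;
  vec yc = y - y_mean;

  mat W(p, A, fill::zeros), P(p, A, fill::zeros), T(n, A, fill::zeros);
  mat R(p, A, fill::zeros), coefs(p, A, fill::zeros);
  vec q(A, fill::zeros), SS(A, fill::zeros);
  vec beta(p, fill::zeros);

  int a_used = 0;
  for (int a = 0; a < A; ++a) {
    vec w = Xc.t() * yc;
    double wn = norm(w, 2);
    if (wn < tol) break;
    w /= wn;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < tol) break;
    vec pl = Xc.t() * t / tt;
    double qa = dot(yc, t) / tt;

    // coefficients on the original centered scale: R = W (P'W)^{-1} by
    // forward substitution (P'W is unit upper triangular for NIPALS)
    vec r = w;
    for (int b = 0; b < a; ++b) r -= dot(P.col(b), w) * R.col(b);

    W.col(a) = w;
    P.col(a) = pl;
    T.col(a) = t;
    R.col(a) = r;
    q(a) = qa;
    SS(a) = qa * qa * tt;
    beta += qa * r;
    coefs.col(a) = beta;

    Xc -= t * pl.t();
    yc -= qa * t;
    ++a_used;
  }

  if (a_used < A) {
    W = W.cols(0, std::max(a_used - 1, 0));
    P = P.cols(0, std::max(a_used - 1, 0));
    T = T.cols(0, std::max(a_used - 1, 0));
    coefs = coefs.cols(0, std::max(a_used - 1, 0));
    q = q.subvec(0, std::max(a_used - 1, 0));
    SS = SS.subvec(0, std::max(a_used - 1, 0));
  }

  return Rcpp::List::create(
    Rcpp::Named("x_mean") = x_mean.t(),
    Rcpp::Named("y_mean") = y_mean,
    Rcpp::Named("W") = W, Rcpp::Named("P") = P, Rcpp::Named("T") = T,
    Rcpp::Named("q") = q, Rcpp::Named("SS") = SS,
    Rcpp::Named("coefs") = coefs, Rcpp::Named("A") = a_used);
}

// PDS: for each master (lab) wavelength i, a local PLS maps the slave
// (field) window [i-w, i+w] -- clipped at the boundaries of the contiguous
// grid segment holding i -- onto lab_i.  Returns, for every requested
// component count a = 1..A, the banded coefficients (p x (2w+1), column
// offset j-i+w) and intercepts.  Windows shorter than the requested ncomp
// use all available components (clipping handled by the NIPALS early stop).
// [[Rcpp::export]]
Rcpp::List cpp_pds_fit(const arma::mat& field, const arma::mat& lab,
                       const arma::ivec& segment, int w, int A) {
  arma::cube coefs;
  mat intercepts;
  pds_core(field, lab, segment, w, A, coefs, intercepts);
  return Rcpp::List::create(Rcpp::Named("coefs") = coefs,
                            Rcpp::Named("intercepts") = intercepts);
}

// --- internal helpers ---------------------------------------------------

// cumulative NIPALS coefficient paths: beta for every component count
// 1..A (columns); returns number of components actually extracted
static int nipals_path(const arma::mat& X, const arma::vec& y, int A,
                       arma::rowvec& x_mean, double& y_mean,
                       arma::mat& coefs) {
  const double tol = 1e-12;
  x_mean = mean(X, 0);
  y_mean = mean(y);
  mat Xc = X.each_row() - x_mean;
  vec yc = y - y_mean;
  const int p = X.n_cols;
  mat P(p, A, fill::zeros), R(p, A, fill::zeros);
  vec beta(p, fill::zeros);
  coefs.zeros(p, A);
  int a_used = 0;
  for (int a = 0; a < A; ++a) {
    vec w = Xc.t() * yc;
    double wn = norm(w, 2);
    if (wn < tol) break;
    w /= wn;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < tol) break;
    vec pl = Xc.t() * t / tt;
    double qa = dot(yc, t) / tt;
    vec r = w;
    for (int b = 0; b < a; ++b) r -= dot(P.col(b), w) * R.col(b);
    P.col(a) = pl; R.col(a) = r;
    beta += qa * r;
    coefs.col(a) = beta;
    Xc -= t * pl.t();
    yc -= qa * t;
    ++a_used;
  }
  return a_used;
}

// banded PDS fit: cube (p x (2w+1) x A) of cumulative local coefficients
static void pds_core(const arma::mat& field, const arma::mat& lab,
                     const arma::ivec& segment, int w, int A,
                     arma::cube& coefs, arma::mat& intercepts) {
  const int n = field.n_rows, p = field.n_cols;
  const int bw = 2 * w + 1;
  coefs.zeros(p, bw, A);
  intercepts.zeros(p, A);
  for (int i = 0; i < p; ++i) {
    int lo = std::max(0, i - w), hi = std::min(p - 1, i + w);
    while (segment(lo) != segment(i)) ++lo;
    while (segment(hi) != segment(i)) --hi;
    const int m = hi - lo + 1;
    int Aloc = std::min(A, std::min(m, n - 1));
    rowvec xm; double ym;
    mat cf;
    int a_used = nipals_path(field.cols(lo, hi), lab.col(i), Aloc, xm, ym, cf);
    vec beta(m, fill::zeros);
    for (int a = 0; a < A; ++a) {
      if (a < a_used) beta = cf.col(a);
      for (int j = 0; j < m; ++j) coefs(i, lo + j - i + w, a) = beta(j);
      intercepts(i, a) = ym - dot(xm.t(), beta);
    }
  }
}

static arma::mat pds_apply_core(const arma::mat& field, const arma::mat& band,
                                const arma::vec& intercepts, int w) {
  const int p = field.n_cols;
  mat out(field.n_rows, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    int lo = std::max(0, i - w), hi = std::min(p - 1, i + w);
    vec acc(field.n_rows, fill::zeros);
    for (int j = lo; j <= hi; ++j) {
      double c = band(i, j - i + w);
      if (c != 0.0) acc += field.col(j) * c;
    }
    out.col(i) = acc + intercepts(i);
  }
  return out;
}

// Leakage-free inner-CV tuning of PDS: for every inner fold the banded
// transform is refit on inner-training samples only, the corrected data
// are scored by a downstream PLS at every component count, and the pooled
// RMSE is returned as a cube (window x local ncomp x downstream ncomp).
// [[Rcpp::export]]
arma::cube cpp_pds_tune(const arma::mat& field, const arma::mat& lab,
                        const arma::vec& y, const arma::ivec& segment,
                        const arma::ivec& infold, const arma::ivec& wgrid,
                        int ncmax, int Amax) {
  const int kmax = infold.max();
  cube sse(wgrid.n_elem, ncmax, Amax, fill::zeros);
  int cnt = 0;
  for (int f = 1; f <= kmax; ++f) {
    uvec te = find(infold == f), tr = find(infold != f);
    if (te.n_elem == 0) continue;
    cnt += te.n_elem;
    mat Ftr = field.rows(tr), Ltr = lab.rows(tr), Fte = field.rows(te);
    vec ytr = y.elem(tr), yte = y.elem(te);
    int A_fit = std::min(Amax, (int)tr.n_elem - 1);
    for (size_t wi = 0; wi < wgrid.n_elem; ++wi) {
      int w = wgrid(wi);
      cube cf; mat ic;
      pds_core(Ftr, Ltr, segment, w, ncmax, cf, ic);
      for (int nc = 0; nc < ncmax; ++nc) {
        mat Xtr = pds_apply_core(Ftr, cf.slice(nc), ic.col(nc), w);
        mat Xte = pds_apply_core(Fte, cf.slice(nc), ic.col(nc), w);
        rowvec xm; double ym; mat coefs;
        int a_used = nipals_path(Xtr, ytr, A_fit, xm, ym, coefs);
        Xte.each_row() -= xm;
        double last = 0.0;
        for (int a = 0; a < Amax; ++a) {
          if (a < a_used) {
            vec resid = yte - (ym + Xte * coefs.col(a));
            last = dot(resid, resid);
          }
          sse(wi, nc, a) += last;
        }
      }
    }
  }
  return sqrt(sse / cnt);
}

// Pooled inner-CV RMSE per component count: for each fold, fit NIPALS on
// the remaining samples and score the held-out samples at every component
// count at once (cumulative coefficients).  Folds where fewer components
// can be extracted contribute their deepest model to the larger counts.
// [[Rcpp::export]]
arma::vec cpp_inner_rmse(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& fold, int A) {
  const double tol = 1e-12;
  const int n = X.n_rows;
  const int kmax = fold.max();
  vec sse(A, fill::zeros);
  int cnt = 0;
  for (int f = 1; f <= kmax; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    if (te.n_elem == 0) continue;
    mat Xtr = X.rows(tr);
    vec ytr = y.elem(tr);
    int Aloc = std::min(A, (int)tr.n_elem - 1);

    rowvec x_mean = mean(Xtr, 0);
    double y_mean = mean(ytr);
    mat Xc = Xtr.each_row() - x_mean;
    vec yc = ytr - y_mean;
    mat P(X.n_cols, Aloc, fill::zeros), R(X.n_cols, Aloc, fill::zeros);
    mat Xte = X.rows(te);
    Xte.each_row() -= x_mean;
    vec beta(X.n_cols, fill::zeros);
    vec yte = y.elem(te);
    int a_used = 0;
    vec last_sse(1, fill::zeros);
    for (int a = 0; a < Aloc; ++a) {
      vec w = Xc.t() * yc;
      double wn = norm(w, 2);
      if (wn < tol) break;
      w /= wn;
      vec t = Xc * w;
      double tt = dot(t, t);
      if (tt < tol) break;
      vec pl = Xc.t() * t / tt;
      double qa = dot(yc, t) / tt;
      vec r = w;
      for (int b = 0; b < a; ++b) r -= dot(P.col(b), w) * R.col(b);
      P.col(a) = pl; R.col(a) = r;
      beta += qa * r;
      Xc -= t * pl.t();
      yc -= qa * t;
      vec resid = yte - (y_mean + Xte * beta);
      sse(a) += dot(resid, resid);
      last_sse(0) = dot(resid, resid);
      ++a_used;
    }
    for (int a = a_used; a < A; ++a) sse(a) += last_sse(0);
    cnt += te.n_elem;
  }
  return sqrt(sse / cnt);
}

// Apply a banded PDS transform: corrected[, i] = sum_o field[, i+o] *
// coefs(i, o+w) + intercept_i, with the band implicitly zero outside the
// fitted window.
// [[Rcpp::export]]
arma::mat cpp_pds_apply(const arma::mat& field, const arma::mat& band,
                        const arma::vec& intercepts, int w) {
  return pds_apply_core(field, band, intercepts, w);
}
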