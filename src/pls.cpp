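// Single-response partial least squares (PLS1) kernels.
//
// pls_fit_cpp:       NIPALS with orthogonal scores on centred data,
//                    returning the coefficient path for 1..A factors.
// pls_loocv_cpp:     leave-one-out predictions for every factor count,
//                    by refitting NIPALS on each fold.
// pls_global_loo_cpp: the pair-deleted machinery behind the global LOO
//                    benchmark.  For predictand i the inner LOO-CV over
//                    folds {-i,-k} is computed via the Krylov-Galerkin form
//                    of PLS1 (the a-factor PLS1 coefficient is the Galerkin
//                    solution on span{s, Ms, ..., M^{a-1}s} with M = Xc'Xc,
//                    s = Xc'yc), so fold Gram matrices are rank-two
//                    downdates of one precomputed Gram matrix and fold
//                    bases are built by batched matrix products.  Each
//                    unordered pair {i,k} is fitted once and feeds both
//                    predictands' CV curves.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// NIPALS PLS1 coefficient path; B(p, A): column a-1 = coefficients using a
// factors (centred scale).  Stops early if the deflated covariance
// collapses; remaining columns repeat the last informative one.
static int nipals_path(const mat& X, const vec& y, int A,
                       rowvec& xc, double& yc, mat& B) {
  const int p = X.n_cols;
  xc = mean(X, 0);
  yc = mean(y);
  mat Xd = X.each_row() - xc;
  vec yd = y - yc;
  B.zeros(p, A);
  mat P(p, A), R(p, A);
  vec beta = zeros<vec>(p);
  double tol0 = -1.0;
  for (int a = 0; a < A; ++a) {
    vec w = Xd.t() * yd;
    double nw = norm(w);
    if (tol0 < 0) tol0 = (nw > 0 ? nw : 1.0) * 1e-12;
    if (nw <= tol0) {           // rank exhausted: path flattens
      for (int b = a; b < A; ++b) B.col(b) = beta;
      return a;
    }
    w /= nw;
    vec t = Xd * w;
    double tt = dot(t, t);
    vec pl = Xd.t() * t / tt;
    double q = dot(yd, t) / tt;
    Xd -= t * pl.t();
    yd -= q * t;
    vec r = w;
    for (int j = 0; j < a; ++j) r -= dot(P.col(j), w) * R.col(j);
    P.col(a) = pl;
    R.col(a) = r;
    beta += q * r;
    B.col(a) = beta;
  }
  return A;
}

// [[Rcpp::export]]
Rcpp::List pls_fit_cpp(const arma::mat& X, const arma::vec& y, int nFactors) {
  rowvec xc; double yc; mat B;
  int eff = nipals_path(X, y, nFactors, xc, yc, B);
  return Rcpp::List::create(Rcpp::Named("xCenter") = xc.t(),
                            Rcpp::Named("yCenter") = yc,
                            Rcpp::Named("coefficients") = B,
                            Rcpp::Named("nEffective") = eff);
}

// [[Rcpp::export]]
arma::mat pls_loocv_cpp(const arma::mat& X, const arma::vec& y,
                        int maxFactors) {
  const int n = X.n_rows;
  mat pred(n, maxFactors);
  for (int i = 0; i < n; ++i) {
    mat Xf(X);  Xf.shed_row(i);
    vec yf(y);  yf.shed_row(i);
    rowvec xc; double yc; mat B;
    nipals_path(Xf, yf, maxFactors, xc, yc, B);
    rowvec xi = X.row(i) - xc;
    pred.row(i) = yc + xi * B;
  }
  return pred;
}

// Galerkin solve helper: given T (kdim x kdim, symmetric completion of the
// projected Gram), snorm = ||s||, u = V'(x_test - xbar), return predictions
// for factor counts 1..A (capped at kdim; beyond it the path is flat).
static void krylov_predict(const mat& T, double snorm, const vec& u,
                           double ybar, int A, int kdim, double* out) {
  if (kdim == 0) { for (int a = 0; a < A; ++a) out[a] = ybar; return; }
  vec d = zeros<vec>(kdim);
  d(0) = snorm;
  double last = ybar;
  for (int a = 1; a <= A; ++a) {
    if (a <= kdim) {
      vec c = solve(symmatu(T.submat(0, 0, a - 1, a - 1)), d.head(a),
                    solve_opts::fast);
      last = ybar + dot(u.head(a), c);
    }
    out[a - 1] = last;
  }
}

// Build the Krylov basis for every fold of one batch.
//
// Folds exclude the common row `i` (when pairPhase) plus their own row k
// (k = kidx[j]).  On exit: Vc[j] (p x kdim_j) orthonormal basis, Tc[j] the
// projected Gram, snorm[j], xbar implicit via outputs ubark (V'(x_k-xbar))
// and ubari (V'(x_i-xbar)), ybar[j].
struct FoldBatch {
  std::vector<mat> T;
  std::vector<int> kdim;
  vec snorm, ybar;
  mat ui, uk;   // A x m: projected centred test points
};

static FoldBatch krylov_batch(const mat& X, const vec& y, const mat& G,
                              const vec& S1, const vec& Sxy, double sy,
                              int i, const uvec& kidx, int A,
                              bool pairPhase) {
  const int p = X.n_cols, n = X.n_rows, m = kidx.n_elem;
  const int q = n - (pairPhase ? 2 : 1);     // fold size
  vec xi = zeros<vec>(p);
  if (pairPhase) xi = X.row(i).t();
  double yi = pairPhase ? y(i) : 0.0;
  vec acom = S1 - xi;                         // sum of x over fold + x_k
  double sycom = sy - yi;
  mat Xk(p, m);                               // fold-specific excluded rows
  vec yk(m);
  for (int j = 0; j < m; ++j) { Xk.col(j) = X.row(kidx(j)).t(); yk(j) = y(kidx(j)); }

  FoldBatch fb;
  fb.T.assign(m, mat(A, A, fill::zeros));
  fb.kdim.assign(m, 0);
  fb.snorm.set_size(m); fb.ybar.set_size(m);
  fb.ui.zeros(A, m); fb.uk.zeros(A, m);

  // fold means and first Krylov direction s_f = Xc'yc of each fold
  mat Xbar(p, m); vec s0norm(m);
  mat S(p, m);                                // current (unnormalised) vectors
  for (int j = 0; j < m; ++j) {
    vec xb = (acom - Xk.col(j)) / q;
    double yb = (sycom - yk(j)) / q;
    Xbar.col(j) = xb;
    fb.ybar(j) = yb;
    S.col(j) = (Sxy - yi * xi - yk(j) * Xk.col(j)) - q * yb * xb;
  }
  std::vector<mat> V(m);                      // per-fold orthonormal bases
  std::vector<char> active(m, 1);
  mat Vcur(p, m, fill::zeros);
  vec tolv(m);
  for (int j = 0; j < m; ++j) {
    double ns = norm(S.col(j));
    fb.snorm(j) = ns;
    if (ns <= 1e-12 * (1.0 + norm(Sxy))) { active[j] = 0; continue; }
    V[j].set_size(p, A);
    V[j].col(0) = S.col(j) / ns;
    Vcur.col(j) = V[j].col(0);
    fb.kdim[j] = 1;
    tolv(j) = -1.0;
  }

  for (int step = 0; step < A; ++step) {
    bool any = false;
    for (int j = 0; j < m; ++j) if (active[j]) { any = true; break; }
    if (!any) break;
    // batched w_j = M_f v_j  (rank-2 + centring downdates of G)
    mat W = G * Vcur;                                   // p x m GEMM
    rowvec a1 = xi.t() * Vcur;                          // x_i' v
    rowvec aa = acom.t() * Vcur;                        // (S1 - x_i)' v
    rowvec a2 = sum(Xk % Vcur, 0);                      // x_k' v
    rowvec a3 = (aa - a2) / q;                          // xbar' v
    if (pairPhase) W -= xi * a1;
    W -= acom * a3;                                     // q*xbar*a3 = (acom-xk)a3
    W += Xk.each_row() % (a3 - a2);
    for (int j = 0; j < m; ++j) {
      if (!active[j]) continue;
      int kd = fb.kdim[j];                              // == step+1
      vec w = W.col(j);
      vec c = V[j].head_cols(kd).t() * w;               // T entries (exact)
      fb.T[j](span(0, kd - 1), span(kd - 1, kd - 1)) = c;
      w -= V[j].head_cols(kd) * c;
      w -= V[j].head_cols(kd) * (V[j].head_cols(kd).t() * w);  // reorth
      double nb = norm(w);
      if (tolv(j) < 0) tolv(j) = std::max(norm(W.col(j)), 1.0) * 1e-10;
      if (kd >= A || nb <= tolv(j)) {                   // basis complete
        active[j] = 0;
        Vcur.col(j).zeros();
        continue;
      }
      fb.T[j](kd, kd - 1) = nb;
      V[j].col(kd) = w / nb;
      Vcur.col(j) = V[j].col(kd);
      fb.kdim[j] = kd + 1;
    }
  }
  // projected, centred test points
  for (int j = 0; j < m; ++j) {
    int kd = fb.kdim[j];
    if (kd == 0) continue;
    vec xkc = Xk.col(j) - Xbar.col(j);
    fb.uk(span(0, kd - 1), span(j, j)) = V[j].head_cols(kd).t() * xkc;
    if (pairPhase) {
      vec xic = xi - Xbar.col(j);
      fb.ui(span(0, kd - 1), span(j, j)) = V[j].head_cols(kd).t() * xic;
    }
  }
  return fb;
}

// [[Rcpp::export]]
Rcpp::List pls_global_loo_cpp(const arma::mat& X, const arma::vec& y,
                              int maxFactors) {
  const int n = X.n_rows;
  const int A = maxFactors;
  mat G = X.t() * X;
  vec S1 = sum(X, 0).t();
  vec Sxy = X.t() * y;
  double sy = accu(y);

  mat sse(n, A, fill::zeros);                 // inner CV squared errors
  std::vector<double> buf(A);
  // phase 1: all unordered pairs {i,k}; each fit scores both CV curves
  for (int i = 0; i < n - 1; ++i) {
    uvec kidx = regspace<uvec>(i + 1, n - 1);
    FoldBatch fb = krylov_batch(X, y, G, S1, Sxy, sy, i, kidx, A, true);
    for (unsigned j = 0; j < kidx.n_elem; ++j) {
      int k = kidx(j);
      krylov_predict(fb.T[j], fb.snorm(j), fb.uk.col(j), fb.ybar(j), A,
                     fb.kdim[j], buf.data());
      for (int a = 0; a < A; ++a) {
        double e = y(k) - buf[a];
        sse(i, a) += e * e;
      }
      krylov_predict(fb.T[j], fb.snorm(j), fb.ui.col(j), fb.ybar(j), A,
                     fb.kdim[j], buf.data());
      for (int a = 0; a < A; ++a) {
        double e = y(i) - buf[a];
        sse(k, a) += e * e;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  mat rmsecv = sqrt(sse / (n - 1));
  ivec chosen(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int a = 1; a < A; ++a)
      if (rmsecv(i, a) < rmsecv(i, best)) best = a;  // ties: smallest a
    chosen(i) = best + 1;
  }
  // phase 2: one single-deletion fit per predictand, predict at chosen a
  vec pred(n);
  uvec allk = regspace<uvec>(0, n - 1);
  FoldBatch fb = krylov_batch(X, y, G, S1, Sxy, sy, -1, allk, A, false);
  for (int i = 0; i < n; ++i) {
    krylov_predict(fb.T[i], fb.snorm(i), fb.uk.col(i), fb.ybar(i), A,
                   fb.kdim[i], buf.data());
    pred(i) = buf[chosen(i) - 1];
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("chosenFactors") = chosen,
                            Rcpp::Named("rmsecv") = rmsecv);
}
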