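// Cross-validated QDA error: the scoring primitive of the block search.
// The search evaluates thousands of (fold x class) plug-in fits per run,
// so the fold loop lives here rather than in R. Must mirror fit_qda() /
// qda_predict() exactly: covariance denominator n_c - 1, adaptive ridge
// 1e-6 * trace(S)/p when ridge < 0, tie at score 0 -> class 0.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ClassFit {
  vec mu;
  mat L;          // lower Cholesky factor of the regularized covariance
  double logdet;
};

ClassFit fit_class(const mat& Xc, double ridge, int cls) {
  ClassFit f;
  const uword p = Xc.n_cols;
  f.mu = mean(Xc, 0).t();
  mat S = (Xc.n_rows > 1) ? cov(Xc) : mat(p, p, fill::zeros);
  double r = (ridge < 0) ? 1e-6 * trace(S) / p : ridge;
  S.diag() += r;
  if (!chol(f.L, S, "lower")) {
    Rcpp::stop("regularized covariance of class %d is not positive-definite "
               "(n_%d = %d, p = %d); increase ridge",
               cls, cls, (int)Xc.n_rows, (int)p);
  }
  f.logdet = 2.0 * sum(log(f.L.diag()));
  return f;
}

inline double quad_form(const ClassFit& f, const rowvec& x) {
  vec z = solve(trimatl(f.L), x.t() - f.mu);
  return dot(z, z);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cv_qda(const arma::mat& X, const arma::ivec& y,
                      const arma::ivec& folds, int k,
                      int prior_code, const arma::vec& prior_values,
                      double ridge) {
  const uword n = X.n_rows;
  if (y.n_elem != n || folds.n_elem != n) {
    Rcpp::stop("X, y and folds must agree in length");
  }
  vec fold_errors(k, fill::zeros);
  int total_miss = 0;

  for (int f = 1; f <= k; ++f) {
    uvec test = find(folds == f);
    uvec train = find(folds != f);
    if (test.n_elem == 0) continue;

    uvec ytr = conv_to<uvec>::from(y.elem(train));
    uvec tr0 = train.elem(find(ytr == 0));
    uvec tr1 = train.elem(find(ytr == 1));
    if (tr0.n_elem == 0 || tr1.n_elem == 0) {
      Rcpp::stop("fold %d leaves a one-class training set; use stratified "
                 "folds or fewer folds", f);
    }

    ClassFit f0 = fit_class(X.rows(tr0), ridge, 0);
    ClassFit f1 = fit_class(X.rows(tr1), ridge, 1);

    double pi0, pi1;
    if (prior_code == 0) {            // empirical, from the training fold
      pi0 = (double)tr0.n_elem / train.n_elem;
      pi1 = (double)tr1.n_elem / train.n_elem;
    } else if (prior_code == 1) {     // balanced
      pi0 = pi1 = 0.5;
    } else {                          // explicit
      pi0 = prior_values[0];
      pi1 = prior_values[1];
    }

    const double c0 = std::log(pi0) - 0.5 * f0.logdet;
    const double c1 = std::log(pi1) - 0.5 * f1.logdet;

    int miss = 0;
    for (uword i = 0; i < test.n_elem; ++i) {
      const rowvec x = X.row(test[i]);
      double score = (c1 - 0.5 * quad_form(f1, x)) -
                     (c0 - 0.5 * quad_form(f0, x));
      int pred = score > 0 ? 1 : 0;
      if (pred != y[test[i]]) ++miss;
    }
    fold_errors[f - 1] = (double)miss / test.n_elem;
    total_miss += miss;
  }

  return Rcpp::List::create(
    Rcpp::Named("error_rate") = (double)total_miss / n,
    Rcpp::Named("fold_errors") = fold_errors);
}
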