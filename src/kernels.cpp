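// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Percent variance explained by the first singular value for each probe
// block of a row-centered matrix. Blocks are consecutive runs of `sizes`
// rows taken from `rows0` (0-based row indices into `xc`). Works on the
// p x p Gram matrix (p = probes per gene), which is small (<= ~26) even
// when the sample count is large: the nonzero eigenvalues of B B^T are
// the squared singular values of B.
// [[Rcpp::export]]
NumericVector cpp_gic_blocks(const arma::mat& xc,
                             const IntegerVector& rows0,
                             const IntegerVector& sizes) {
  const int ngene = sizes.size();
  NumericVector out(ngene);
  int pos = 0;
  for (int g = 0; g < ngene; ++g) {
    const int p = sizes[g];
    if (p == 1) {
      // single-probe block: one nonzero singular value by construction
      const arma::rowvec r = xc.row(rows0[pos]);
      out[g] = arma::accu(arma::square(r)) > 0.0 ? 1.0 : 0.0;
      pos += 1;
      continue;
    }
    arma::uvec idx(p);
    for (int j = 0; j < p; ++j) idx[j] = (arma::uword)rows0[pos + j];
    pos += p;
    const arma::mat b = xc.rows(idx);
    const double total = arma::accu(arma::square(b));
    if (total <= 0.0) { out[g] = 0.0; continue; }
    const arma::mat gram = b * b.t();
    arma::vec ev;
    arma::eig_sym(ev, gram);
    out[g] = ev.max() / total;
  }
  return out;
}

// Tukey median polish of a probe x sample block, iterating rows then
// columns, midpoint medians, convergence on the relative change in the
// sum of absolute residuals (the classic additive-fit algorithm).
// Returns the probe-set summary pieces: overall + column (sample)
// effects, plus row effects and residuals for diagnostics.
// [[Rcpp::export]]
List cpp_median_polish(const arma::mat& x, const double eps, const int maxiter) {
  arma::mat z = x;
  const arma::uword nr = x.n_rows, nc = x.n_cols;
  double overall = 0.0;
  arma::vec rowe(nr, arma::fill::zeros);
  arma::vec cole(nc, arma::fill::zeros);
  double oldsum = 0.0;
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= maxiter; ++iter) {
    arma::vec rdelta = arma::median(z, 1);
    z.each_col() -= rdelta;
    rowe += rdelta;
    double delta = arma::median(cole);
    cole -= delta;
    overall += delta;
    arma::rowvec cdelta = arma::median(z, 0);
    z.each_row() -= cdelta;
    cole += cdelta.t();
    delta = arma::median(rowe);
    rowe -= delta;
    overall += delta;
    const double newsum = arma::accu(arma::abs(z));
    converged = (newsum == 0.0) || (std::abs(newsum - oldsum) < eps * newsum);
    if (converged) break;
    oldsum = newsum;
  }
  return List::create(_["overall"] = overall,
                      _["row"] = NumericVector(rowe.begin(), rowe.end()),
                      _["col"] = NumericVector(cole.begin(), cole.end()),
                      _["residuals"] = wrap(z),
                      _["iter"] = iter > maxiter ? maxiter : iter,
                      _["converged"] = converged);
}
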