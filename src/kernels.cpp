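#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Assemble diploid dosages by random mating from a SNP-major haplotype
// pool (m x H, one haplotype per contiguous column): genotype column j is
// pool column i1[j] + pool column i2[j] (indices 1-based).  Explicit loops:
// this is the per-replicate hot path of the simulation suite.
// [[Rcpp::export]]
NumericMatrix cpp_draw_t(const NumericMatrix& poolT,
                         const IntegerVector& i1, const IntegerVector& i2) {
  const R_xlen_t m = poolT.nrow(), n = i1.size();
  NumericMatrix x(m, n);
  const double* pool = &poolT[0];
  double* X = &x[0];
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* a = pool + (R_xlen_t)(i1[j] - 1) * m;
    const double* b = pool + (R_xlen_t)(i2[j] - 1) * m;
    double* out = X + j * m;
    for (R_xlen_t k = 0; k < m; ++k) out[k] = a[k] + b[k];
  }
  return x;
}

// Fused cohort assembly + per-SNP standardization in SNP-major layout:
// returns the m x n standardized genotype matrix (rows mean 0, population
// variance 1) plus per-SNP dosage means and SDs.  Zero-variance rows are
// centered but left unscaled; their sd is reported so callers can drop
// them.
// [[Rcpp::export]]
List cpp_draw_std_t(const NumericMatrix& poolT,
                    const IntegerVector& i1, const IntegerVector& i2) {
  const R_xlen_t m = poolT.nrow(), n = i1.size();
  NumericMatrix x(m, n);
  std::vector<double> sum(m, 0.0), sumsq(m, 0.0);
  const double* pool = &poolT[0];
  double* X = &x[0];
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* a = pool + (R_xlen_t)(i1[j] - 1) * m;
    const double* b = pool + (R_xlen_t)(i2[j] - 1) * m;
    double* out = X + j * m;
    for (R_xlen_t k = 0; k < m; ++k) {
      const double v = a[k] + b[k];
      out[k] = v;
      sum[k] += v;
      sumsq[k] += v * v;
    }
  }
  NumericVector mu(m), sd(m);
  std::vector<double> inv(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    mu[k] = sum[k] / n;
    const double v = sumsq[k] / n - mu[k] * mu[k];
    sd[k] = v > 0 ? std::sqrt(v) : 0.0;
    inv[k] = sd[k] > 0 ? 1.0 / sd[k] : 1.0;
  }
  for (R_xlen_t j = 0; j < n; ++j) {
    double* out = X + j * m;
    for (R_xlen_t k = 0; k < m; ++k) out[k] = (out[k] - mu[k]) * inv[k];
  }
  return List::create(_["x"] = x, _["mean"] = mu, _["sd"] = sd);
}

// Assembly plus per-SNP moments, without standardizing: callers that only
// need crossproducts against the standardized matrix can work on the raw
// dosages and fold the mean/SD in algebraically, saving a full pass.
// [[Rcpp::export]]
List cpp_draw_moments_t(const NumericMatrix& poolT,
                        const IntegerVector& i1, const IntegerVector& i2) {
  const R_xlen_t m = poolT.nrow(), n = i1.size();
  NumericMatrix x(m, n);
  std::vector<double> sum(m, 0.0), sumsq(m, 0.0);
  const double* pool = &poolT[0];
  double* X = &x[0];
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* a = pool + (R_xlen_t)(i1[j] - 1) * m;
    const double* b = pool + (R_xlen_t)(i2[j] - 1) * m;
    double* out = X + j * m;
    for (R_xlen_t k = 0; k < m; ++k) {
      const double v = a[k] + b[k];
      out[k] = v;
      sum[k] += v;
      sumsq[k] += v * v;
    }
  }
  NumericVector mu(m), sd(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    mu[k] = sum[k] / n;
    const double v = sumsq[k] / n - mu[k] * mu[k];
    sd[k] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["x"] = x, _["mean"] = mu, _["sd"] = sd);
}

// Center and scale columns to mean 0, population variance 1 (divide by n).
// Zero-variance columns are centered but left unscaled; their sd is
// reported so callers can drop them.
// [[Rcpp::export]]
List cpp_standardize_cols(arma::mat x) {
  arma::rowvec mu = arma::mean(x, 0);
  x.each_row() -= mu;
  arma::rowvec sd = arma::sqrt(arma::mean(arma::square(x), 0));
  arma::rowvec sc = sd;
  sc.replace(0.0, 1.0);
  x.each_row() /= sc;
  return List::create(_["x"] = x, _["mean"] = mu, _["sd"] = sd);
}
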