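// Compiled workhorses for the differential-correlation subsampling test:
// (1) per-subnetwork within-cluster / whole-network adjacency densities,
// (2) batched gamma-family logit-link IRLS for the permutation refits.
// A pure-R reference implementation of both exists and is cross-checked in
// the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double int_pow(double x, int b) {
  double acc = 1.0, base = x;
  int e = b;
  while (e > 0) {
    if (e & 1) acc *= base;
    base *= base;
    e >>= 1;
  }
  return acc;
}

// rows standardised (over the given columns) so that Z * Z^T is the
// correlation matrix: Pearson (centred, unit norm) or biweight
// midcorrelation (median/MAD weights, tuning constant 9; Pearson fallback
// for zero-MAD rows). Zero-variance rows are zeroed (correlation 0).
static arma::mat standardise_rows(const arma::mat& X, const arma::uvec& cols,
                                  bool bicor) {
  const arma::uword n = X.n_rows, m = cols.n_elem;
  arma::mat Z(n, m);
  arma::vec row(m), dev(m), w(m);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < m; ++j) row(j) = X(i, cols(j));
    bool done = false;
    if (bicor) {
      arma::vec tmp = row;
      double med = arma::median(tmp);
      dev = row - med;
      arma::vec absdev = arma::abs(dev);
      double madv = arma::median(absdev);
      if (madv > 0) {
        for (arma::uword j = 0; j < m; ++j) {
          double u = dev(j) / (9.0 * madv);
          double wt = (std::abs(u) < 1.0) ? (1.0 - u * u) * (1.0 - u * u) : 0.0;
          w(j) = dev(j) * wt;
        }
        done = true;
      }
    }
    if (!done) {
      double mu = arma::mean(row);
      w = row - mu;
    }
    double nrm = std::sqrt(arma::dot(w, w));
    if (nrm > 0) {
      Z.row(i) = (w / nrm).t();
    } else {
      Z.row(i).zeros();
    }
  }
  return Z;
}

// [[Rcpp::export]]
List subnet_density_engine(NumericMatrix values, IntegerVector cluster_of,
                           int n_clusters, List retained_idx, int beta,
                           bool bicor) {
  const arma::mat X(values.begin(), values.nrow(), values.ncol(), false);
  const int n = X.n_rows;
  const int n_sub = retained_idx.size();
  arma::mat cl_dens(n_sub, n_clusters, arma::fill::value(NA_REAL));
  arma::vec net_dens(n_sub);

  for (int s = 0; s < n_sub; ++s) {
    IntegerVector ri = retained_idx[s];
    arma::uvec cols(ri.size());
    for (int j = 0; j < ri.size(); ++j) cols(j) = ri[j];
    arma::mat Z = standardise_rows(X, cols, bicor);
    arma::mat R = Z * Z.t();
    double tot = 0.0;
    long npairs = 0;
    std::vector<double> csum(n_clusters, 0.0);
    std::vector<long> ccnt(n_clusters, 0);
    for (int i = 0; i < n; ++i) {
      const int ci = cluster_of[i];
      for (int j = i + 1; j < n; ++j) {
        double r = R(i, j);
        if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
        double a = int_pow(std::abs(r), beta);
        tot += a;
        ++npairs;
        if (ci >= 0 && ci == cluster_of[j]) {
          csum[ci] += a;
          ++ccnt[ci];
        }
      }
    }
    net_dens(s) = tot / npairs;
    for (int c = 0; c < n_clusters; ++c) {
      if (ccnt[c] > 0) cl_dens(s, c) = csum[c] / ccnt[c];
    }
  }
  return List::create(_["cluster_density"] = cl_dens,
                      _["net_density"] = net_dens);
}

// [[Rcpp::export]]
List gamma_logit_batch(const arma::mat& X, const arma::mat& Y,
                       const arma::uvec& coef_idx,
                       int max_iter = 50, double tol = 1e-9) {
  const arma::uword n = X.n_rows, p = X.n_cols, nfit = Y.n_cols,
                    k = coef_idx.n_elem;
  arma::mat coef(nfit, k), se(nfit, k);
  arma::ivec conv(nfit, arma::fill::zeros);

  for (arma::uword f = 0; f < nfit; ++f) {
    arma::vec y = Y.col(f);
    // start from the saturated linear predictor (y is in (0,1))
    arma::vec eta = arma::log(y / (1.0 - y));
    arma::vec beta_hat(p, arma::fill::zeros);
    bool ok = false;
    arma::mat XtWX(p, p);
    for (int it = 0; it < max_iter; ++it) {
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec dmu = mu % (1.0 - mu);              // d mu / d eta
      arma::vec wv = (1.0 - mu) % (1.0 - mu);       // dmu^2 / V(mu), V = mu^2
      arma::vec z = eta + (y - mu) / dmu;
      arma::mat Xw = X.each_col() % wv;
      XtWX = X.t() * Xw;
      arma::vec Xtz = Xw.t() * z;
      arma::vec bnew;
      if (!arma::solve(bnew, XtWX, Xtz,
                       arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
        break;
      }
      double step = arma::max(arma::abs(bnew - beta_hat));
      beta_hat = bnew;
      eta = X * beta_hat;
      if (step < tol * (1.0 + arma::max(arma::abs(beta_hat)))) {
        ok = true;
        break;
      }
    }
    if (ok) {
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      double phi = arma::accu(arma::square((y - mu) / mu)) / (n - p);
      arma::mat cov;
      if (arma::inv_sympd(cov, XtWX)) {
        for (arma::uword j = 0; j < k; ++j) {
          coef(f, j) = beta_hat(coef_idx(j));
          se(f, j) = std::sqrt(phi * cov(coef_idx(j), coef_idx(j)));
        }
        conv(f) = 1;
      }
    }
    if (!conv(f)) {
      for (arma::uword j = 0; j < k; ++j) {
        coef(f, j) = NA_REAL;
        se(f, j) = NA_REAL;
      }
    }
  }
  return List::create(_["coef"] = coef, _["se"] = se, _["converged"] = conv);
}
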