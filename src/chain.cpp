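// Inner loop of the data-augmentation sampler. Mirrors the R reference
// implementation (imputeY / imputeX / updateParameters) with every block
// updated; uses R's RNG so runs are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// draw from N(Q^{-1} b, Q^{-1}) for a small precision matrix Q
static arma::vec drawGaussPrec(const arma::mat& Q, const arma::vec& b) {
  arma::mat R = arma::chol(Q);  // upper, Q = R'R
  arma::vec m = arma::solve(arma::trimatu(R),
                            arma::solve(arma::trimatl(R.t()), b));
  arma::vec z(Q.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(R), z);
}

static double logInvGammaC(double x, double shape, double rate) {
  return shape * std::log(rate) - R::lgammafn(shape) -
         (shape + 1.0) * std::log(x) - rate / x;
}

// [[Rcpp::export(name = ".chainCpp")]]
NumericMatrix chainCpp(const arma::mat& Z, const arma::mat& X0,
                       const arma::vec& Y0, const IntegerVector& group,
                       const arma::umat& loadings,
                       const List& priors, const List& config,
                       const List& init) {
  const int n = Z.n_rows;
  const int K = loadings.n_cols;
  const int nAlpha = arma::accu(loadings);

  // priors
  const double betaMean = priors["betaMean"], betaSd = priors["betaSd"];
  const double alphaMean = priors["alphaMean"], alphaSd = priors["alphaSd"];
  const double deltaSd = priors["deltaSd"], omegaSd = priors["omegaSd"];
  const double uVar = priors["uVar"];
  const double sigShape = priors["sigmaShape"], sigRate = priors["sigmaRate"];

  // config
  const int nIter = config["nIter"], nWarmup = config["nWarmup"];
  const bool conditional = config["conditional"];
  const bool mhOnSd = config["mhOnSd"];
  const double mhStep = config["mhStep"];

  // state
  arma::vec beta = init["beta"], alpha = init["alpha"], delta = init["delta"],
            omega = init["omega"], sigma = init["sigma"], U = init["U"];
  arma::mat Xc = X0;      // completed exposures (C rows overwritten)
  arma::vec Yc = Y0;      // completed outcomes (B rows overwritten)
  const arma::vec YimpInit = init["Yimp"];
  const arma::mat XimpInit = init["Ximp"];

  std::vector<int> rowsB, rowsC;
  for (int i = 0; i < n; ++i) {
    if (group[i] == 1) rowsB.push_back(i);
    else if (group[i] == 2) rowsC.push_back(i);
  }
  for (size_t r = 0; r < rowsB.size(); ++r) Yc(rowsB[r]) = YimpInit(r);
  for (size_t r = 0; r < rowsC.size(); ++r)
    Xc.row(rowsC[r]) = XimpInit.row(r);

  // instruments per exposure; alpha edge index per exposure (column-major)
  std::vector<std::vector<int> > instr(K);
  std::vector<std::vector<int> > edge(K);
  {
    int e = 0;
    for (int k = 0; k < K; ++k)
      for (arma::uword j = 0; j < loadings.n_rows; ++j)
        if (loadings(j, k)) { instr[k].push_back(j); edge[k].push_back(e++); }
  }

  const int nPar = K + nAlpha + 2 * (K + 1) + (K + 1);
  const int nKeep = nIter - nWarmup;
  NumericMatrix draws(nKeep, nPar);

  arma::mat A(loadings.n_rows, K);  // loading matrix with alpha values
  arma::mat muX(n, K);

  for (int t = 0; t < nIter; ++t) {
    // instrument-driven exposure means at current alpha/omega
    A.zeros();
    for (int k = 0; k < K; ++k)
      for (size_t m = 0; m < instr[k].size(); ++m)
        A(instr[k][m], k) = alpha(edge[k][m]);
    muX = Z * A;
    muX.each_row() += omega.subvec(0, K - 1).t();

    // Step 2a: impute missing outcomes (group B)
    for (size_t r = 0; r < rowsB.size(); ++r) {
      int i = rowsB[r];
      double mu = omega(K) + arma::dot(beta, Xc.row(i));
      if (conditional) mu += delta(K) * U(i);
      Yc(i) = R::rnorm(mu, sigma(K));
    }

    // Step 2b: impute missing exposures (group C)
    if (!rowsC.empty()) {
      if (!conditional) {
        for (size_t r = 0; r < rowsC.size(); ++r) {
          int i = rowsC[r];
          for (int k = 0; k < K; ++k)
            Xc(i, k) = R::rnorm(muX(i, k), sigma(k));
        }
      } else {
        arma::vec sig2 = arma::square(sigma.subvec(0, K - 1));
        double sigY2 = sigma(K) * sigma(K);
        arma::mat Q = arma::diagmat(1.0 / sig2) + beta * beta.t() / sigY2;
        arma::mat S = arma::inv_sympd(Q);
        arma::mat RS = arma::chol(S);  // upper, S = RS'RS
        for (size_t r = 0; r < rowsC.size(); ++r) {
          int i = rowsC[r];
          arma::vec pm = muX.row(i).t() + delta.subvec(0, K - 1) * U(i);
          double resY = Yc(i) - omega(K) - delta(K) * U(i);
          arma::vec b = pm / sig2 + beta * (resY / sigY2);
          arma::vec z(K);
          for (int k = 0; k < K; ++k) z(k) = R::norm_rand();
          Xc.row(i) = (S * b + RS.t() * z).t();
        }
      }
    }

    // Step 4: exposure-equation coefficients (omega_k, alpha_(k), delta_k)
    for (int k = 0; k < K; ++k) {
      int m = instr[k].size();
      int p = 2 + m;
      arma::mat D(n, p);
      D.col(0).ones();
      for (int j = 0; j < m; ++j) D.col(1 + j) = Z.col(instr[k][j]);
      D.col(p - 1) = U;
      arma::vec pm(p), prec(p);
      pm(0) = 0.0; prec(0) = 1.0 / (omegaSd * omegaSd);
      for (int j = 0; j < m; ++j) {
        pm(1 + j) = alphaMean; prec(1 + j) = 1.0 / (alphaSd * alphaSd);
      }
      pm(p - 1) = 0.0; prec(p - 1) = 1.0 / (deltaSd * deltaSd);
      double s2 = sigma(k) * sigma(k);
      arma::mat Q = D.t() * D / s2 + arma::diagmat(prec);
      arma::vec b = D.t() * Xc.col(k) / s2 + prec % pm;
      arma::vec th = drawGaussPrec(Q, b);
      omega(k) = th(0);
      for (int j = 0; j < m; ++j) alpha(edge[k][j]) = th(1 + j);
      delta(k) = th(p - 1);
    }

    // outcome-equation coefficients (omega_Y, beta, delta_Y)
    {
      int p = K + 2;
      arma::mat D(n, p);
      D.col(0).ones();
      D.cols(1, K) = Xc;
      D.col(p - 1) = U;
      arma::vec pm(p), prec(p);
      pm(0) = 0.0; prec(0) = 1.0 / (omegaSd * omegaSd);
      for (int k = 0; k < K; ++k) {
        pm(1 + k) = betaMean; prec(1 + k) = 1.0 / (betaSd * betaSd);
      }
      pm(p - 1) = 0.0; prec(p - 1) = 1.0 / (deltaSd * deltaSd);
      double s2 = sigma(K) * sigma(K);
      arma::mat Q = D.t() * D / s2 + arma::diagmat(prec);
      arma::vec b = D.t() * Yc / s2 + prec % pm;
      arma::vec th = drawGaussPrec(Q, b);
      omega(K) = th(0);
      beta = th.subvec(1, K);
      delta(K) = th(p - 1);
    }

    // refresh exposure means (alpha/omega moved)
    A.zeros();
    for (int k = 0; k < K; ++k)
      for (size_t m = 0; m < instr[k].size(); ++m)
        A(instr[k][m], k) = alpha(edge[k][m]);
    muX = Z * A;
    muX.each_row() += omega.subvec(0, K - 1).t();

    // latent confounders
    {
      double prc = 1.0 / uVar;
      for (int k = 0; k <= K; ++k) prc += delta(k) * delta(k) /
        (sigma(k) * sigma(k));
      double sdU = std::sqrt(1.0 / prc);
      arma::vec resY = Yc - omega(K) - Xc * beta;
      for (int i = 0; i < n; ++i) {
        double num = delta(K) * resY(i) / (sigma(K) * sigma(K));
        for (int k = 0; k < K; ++k)
          num += delta(k) * (Xc(i, k) - muX(i, k)) / (sigma(k) * sigma(k));
        U(i) = R::rnorm(num / prc, sdU);
      }
    }

    // residual scales
    for (int k = 0; k <= K; ++k) {
      double SS;
      if (k < K) {
        arma::vec res = Xc.col(k) - muX.col(k) - delta(k) * U;
        SS = arma::dot(res, res);
      } else {
        arma::vec res = Yc - omega(K) - Xc * beta - delta(K) * U;
        SS = arma::dot(res, res);
      }
      if (mhOnSd) {
        double cur = sigma(k);
        double prop = cur * std::exp(mhStep * R::norm_rand());
        double la =
          (-n * std::log(prop) - SS / (2 * prop * prop) +
            logInvGammaC(prop, sigShape, sigRate) + std::log(prop)) -
          (-n * std::log(cur) - SS / (2 * cur * cur) +
            logInvGammaC(cur, sigShape, sigRate) + std::log(cur));
        if (std::log(R::unif_rand()) < la) sigma(k) = prop;
      } else {
        double v = 1.0 / R::rgamma(sigShape + n / 2.0,
                                   1.0 / (sigRate + SS / 2.0));
        sigma(k) = std::sqrt(v);
      }
    }

    if (!beta.is_finite() || !sigma.is_finite())
      stop("non-finite parameter values encountered in the update sweep");

    if (t >= nWarmup) {
      int row = t - nWarmup, c = 0;
      for (int k = 0; k < K; ++k) draws(row, c++) = beta(k);
      for (int e = 0; e < nAlpha; ++e) draws(row, c++) = alpha(e);
      for (int k = 0; k <= K; ++k) draws(row, c++) = delta(k);
      for (int k = 0; k <= K; ++k) draws(row, c++) = omega(k);
      for (int k = 0; k <= K; ++k) draws(row, c++) = sigma(k);
    }
  }
  return draws;
}
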