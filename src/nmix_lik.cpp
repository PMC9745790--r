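#include <Rcpp.h>
using namespace Rcpp;

// Shared machinery for the marginal likelihoods of site-structured abundance
// models.  The latent site abundance N is summed out over N = max(y) .. K
// (binomial support starts at the largest observed count), in log space.

namespace {

inline double logsumexp(const std::vector<double> &v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// log prior mass of the abundance mixture at N
// mixture: 0 Poisson, 1 NB (size = alpha, mu = lambda), 2 ZIP
inline double log_abund(int N, double lam, int mixture, double alpha,
                        double psi) {
  switch (mixture) {
  case 1:
    return R::dnbinom_mu(N, alpha, lam, 1);
  case 2: {
    double lp = R::dpois(N, lam, 1);
    if (N == 0) {
      // log(psi + (1 - psi) * dpois(0, lam)), stable for psi near 0/1
      double a = std::log(psi), b = std::log1p(-psi) + lp;
      double m = std::max(a, b);
      return m + std::log(std::exp(a - m) + std::exp(b - m));
    }
    return std::log1p(-psi) + lp;
  }
  default:
    return R::dpois(N, lam, 1);
  }
}

inline double clamp_eta(double eta) {
  if (eta > 500.0) return 500.0;
  if (eta < -500.0) return -500.0;
  return eta;
}

} // namespace

// Negative marginal log-likelihood of the binomial N-mixture model.
//
// y       R x J counts, NA for missing cells
// Xs      R x ps abundance design matrix (log link)
// Xd      (R*J) x pd detection design matrix (logit link); row i*J + j is
//         site i (0-based), column j
// beta    abundance coefficients; alpha detection coefficients
// mixture 0 Poisson, 1 NB, 2 ZIP
// aux     log(dispersion) for NB, logit(psi) for ZIP, ignored otherwise
// K       latent-count truncation bound
// [[Rcpp::export(name = ".nmix_negloglik_cpp")]]
double nmix_negloglik_cpp(IntegerMatrix y, NumericMatrix Xs, NumericMatrix Xd,
                          NumericVector beta, NumericVector alpha, int mixture,
                          double aux, int K) {
  const int R = y.nrow(), J = y.ncol();
  const int ps = Xs.ncol(), pd = Xd.ncol();

  double disp = 1.0, psi = 0.0;
  if (mixture == 1) disp = std::exp(std::min(aux, 500.0));
  if (mixture == 2) psi = 1.0 / (1.0 + std::exp(-aux));

  // lgamma table for binomial coefficients: lgam[n] = lgamma(n + 1)
  std::vector<double> lgam(K + 2);
  for (int n = 0; n <= K + 1; ++n) lgam[n] = std::lgamma((double)n + 1.0);

  std::vector<double> buf;
  buf.reserve(K + 1);
  std::vector<int> yy(J);
  std::vector<double> lp(J), l1mp(J);

  double total = 0.0;
  for (int i = 0; i < R; ++i) {
    double eta = 0.0;
    for (int k = 0; k < ps; ++k) eta += Xs(i, k) * beta[k];
    double lam = std::exp(clamp_eta(eta));

    int nobs = 0, ymax = 0;
    for (int j = 0; j < J; ++j) {
      int yij = y(i, j);
      if (yij == NA_INTEGER) continue;
      double etad = 0.0;
      for (int k = 0; k < pd; ++k) etad += Xd(i * J + j, k) * alpha[k];
      etad = clamp_eta(etad);
      double p = 1.0 / (1.0 + std::exp(-etad));
      yy[nobs] = yij;
      lp[nobs] = -std::log1p(std::exp(-etad));      // log(p)
      l1mp[nobs] = -etad - std::log1p(std::exp(-etad)); // log(1 - p)
      (void)p;
      if (yij > ymax) ymax = yij;
      ++nobs;
    }
    if (nobs == 0) stop("site %d has no observed occasions", i + 1);
    if (ymax > K) stop("observed count %d exceeds truncation bound K = %d",
                       ymax, K);

    buf.clear();
    for (int N = ymax; N <= K; ++N) {
      double ll = log_abund(N, lam, mixture, disp, psi);
      for (int c = 0; c < nobs; ++c) {
        int yc = yy[c];
        ll += lgam[N] - lgam[yc] - lgam[N - yc] + yc * lp[c] +
              (N - yc) * l1mp[c];
      }
      buf.push_back(ll);
    }
    total += logsumexp(buf);
  }
  if (!R_FINITE(total)) return 1e10; // keep the optimizer inside the domain
  return -total;
}

// Negative marginal log-likelihood of the Royle-Nichols model on
// detection/non-detection data: P(w = 1 | N) = 1 - (1 - r)^N, N ~ Poisson.
//
// w  R x J binary matrix, NA for missing; Xs as above for log(lambda);
// Xd as above for logit(r)
// [[Rcpp::export(name = ".rn_negloglik_cpp")]]
double rn_negloglik_cpp(IntegerMatrix w, NumericMatrix Xs, NumericMatrix Xd,
                        NumericVector beta, NumericVector alpha, int K) {
  const int R = w.nrow(), J = w.ncol();
  const int ps = Xs.ncol(), pd = Xd.ncol();

  std::vector<double> buf;
  buf.reserve(K + 1);
  std::vector<int> ww(J);
  std::vector<double> l1mr(J);

  double total = 0.0;
  for (int i = 0; i < R; ++i) {
    double eta = 0.0;
    for (int k = 0; k < ps; ++k) eta += Xs(i, k) * beta[k];
    double lam = std::exp(clamp_eta(eta));

    int nobs = 0;
    for (int j = 0; j < J; ++j) {
      int wij = w(i, j);
      if (wij == NA_INTEGER) continue;
      if (wij != 0 && wij != 1) stop("RN model requires binary data");
      double etad = 0.0;
      for (int k = 0; k < pd; ++k) etad += Xd(i * J + j, k) * alpha[k];
      etad = clamp_eta(etad);
      ww[nobs] = wij;
      l1mr[nobs] = -etad - std::log1p(std::exp(-etad)); // log(1 - r)
      ++nobs;
    }
    if (nobs == 0) stop("site %d has no observed occasions", i + 1);

    buf.clear();
    for (int N = 0; N <= K; ++N) {
      double ll = R::dpois(N, lam, 1);
      for (int c = 0; c < nobs; ++c) {
        double lq = N * l1mr[c]; // log P(w = 0 | N)
        if (ww[c] == 1) {
          // log(1 - exp(lq)), guarded for N = 0 where lq = 0
          ll += (lq >= 0.0) ? R_NegInf : std::log1p(-std::exp(lq));
        } else {
          ll += lq;
        }
      }
      buf.push_back(ll);
    }
    total += logsumexp(buf);
  }
  if (!R_FINITE(total)) return 1e10;
  return -total;
}
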