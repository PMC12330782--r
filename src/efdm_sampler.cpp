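// Core MCMC machinery for multinomial / DM / FDM / EFDM mean regression.
//
// All model parameters are handled on an unconstrained scale:
//   coefficients   : identity
//   precision a+   : log
//   mixing weights : stick-breaking (Stan convention)
//   wtilde, theta  : logit
// The log-posterior includes the log-Jacobians of these maps so that the
// stated priors apply on the constrained scale.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

struct ModelSpec {
  arma::mat Y;          // N x D counts
  arma::mat X;          // N x (K+1), leading intercept column
  arma::vec n_i;        // row sums of Y
  arma::vec countConst; // lgamma(n+1) - sum lgamma(y+1), per sample
  int N, D, K1;         // K1 = K + 1
  int baseline;         // 0-based taxon index with null coefficient vector
  int family;           // 0 mult, 1 dm, 2 fdm, 3 efdm
  bool spike;           // spike-and-slab prior on covariate blocks
  double likWeight;     // 0 disables the likelihood (prior checks)
  // priors
  double coeffSd, interceptSd;
  double gamShape, gamRate;
  arma::vec dirConc;
  double wtA, wtB;
  double slabVar, spikeVar, thetaA, thetaB;
};

int nCoef(const ModelSpec& m) { return (m.D - 1) * m.K1; }

int nPar(const ModelSpec& m) {
  int P = nCoef(m);
  if (m.family >= 1) P += 1;              // log alpha+
  if (m.family >= 2) P += m.D - 1;        // stick(p)
  if (m.family == 2) P += 1;              // common wtilde
  if (m.family == 3) P += m.D;            // wtilde vector
  if (m.spike) P += m.K1 - 1;             // logit(theta_k)
  return P;
}

// full D x K1 coefficient matrix with a zero baseline row
arma::mat coefMatrix(const ModelSpec& m, const arma::vec& theta) {
  arma::mat B(m.D, m.K1, arma::fill::zeros);
  int idx = 0;
  for (int r = 0; r < m.D; ++r) {
    if (r == m.baseline) continue;
    for (int k = 0; k < m.K1; ++k) B(r, k) = theta[idx++];
  }
  return B;
}

// stick-breaking simplex transform; returns log-Jacobian via logJ
arma::vec stickSimplex(const arma::vec& z, double* logJ) {
  int Dm1 = z.n_elem;
  arma::vec p(Dm1 + 1);
  double rest = 1.0, lj = 0.0;
  for (int k = 0; k < Dm1; ++k) {
    double zk = z[k] - std::log((double)(Dm1 - k));
    double v = 1.0 / (1.0 + std::exp(-zk));
    p[k] = rest * v;
    lj += std::log(v) + std::log1p(-v) + std::log(rest);
    rest -= p[k];
  }
  p[Dm1] = rest;
  if (logJ) *logJ = lj;
  return p;
}

double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Per-sample log-likelihood vector given unconstrained parameters.
// Returns false if anything non-finite is produced.
bool logLikVec(const ModelSpec& m, const arma::vec& theta, arma::vec& ll) {
  const int D = m.D;
  arma::mat B = coefMatrix(m, theta);
  arma::mat eta = m.X * B.t(); // N x D
  int idx = nCoef(m);
  double ap = 0.0;
  arma::vec p, wt;
  if (m.family >= 1) ap = std::exp(theta[idx++]);
  if (m.family >= 2) {
    p = stickSimplex(theta.subvec(idx, idx + D - 2), nullptr);
    idx += D - 1;
    wt.set_size(D);
    if (m.family == 2) wt.fill(logistic(theta[idx++]));
    else { for (int r = 0; r < D; ++r) wt[r] = logistic(theta[idx + r]); idx += D; }
  }
  if (!std::isfinite(ap) && m.family >= 1) return false;

  ll.set_size(m.N);
  for (int i = 0; i < m.N; ++i) {
    arma::rowvec e = eta.row(i);
    double mx = e.max();
    arma::rowvec ex = arma::exp(e - mx);
    arma::rowvec mu = ex / arma::accu(ex);
    const double n = m.n_i[i];
    double li = m.countConst[i];
    if (m.family == 0) {
      for (int r = 0; r < D; ++r)
        if (m.Y(i, r) > 0) li += m.Y(i, r) * std::log(mu[r]);
    } else if (m.family == 1) {
      li += std::lgamma(ap) - std::lgamma(ap + n);
      for (int r = 0; r < D; ++r) {
        double c = ap * mu[r];
        li += std::lgamma(c + m.Y(i, r)) - std::lgamma(c);
      }
    } else {
      // map (mu, ap, p, wt) -> (alpha, tau) for this sample
      arma::vec w(D), a(D), tau(D);
      double S = 0.0;
      for (int r = 0; r < D; ++r) {
        double ratio = mu[r] / p[r];
        w[r] = wt[r] * (ratio < 1.0 ? ratio : 1.0);
        if (w[r] > 1.0 - 1e-12) w[r] = 1.0 - 1e-12;
        S += p[r] * w[r];
      }
      if (S >= 1.0 - 1e-14) return false;
      double baseSum = 0.0;
      arma::vec lrf(D); // lgamma(a_j + y_j) - lgamma(a_j)
      for (int r = 0; r < D; ++r) {
        a[r] = ap * (mu[r] - p[r] * w[r]) / (1.0 - S);
        if (a[r] <= 0.0) return false;
        tau[r] = ap * w[r] / (1.0 - w[r]);
        lrf[r] = std::lgamma(a[r] + m.Y(i, r)) - std::lgamma(a[r]);
        baseSum += lrf[r];
      }
      // mixture over components: only coordinate r's concentration differs
      // from the shared alpha, so adjust the shared sum per component
      double lse = NEG_INF;
      for (int r = 0; r < D; ++r) {
        if (p[r] <= 0.0) continue;
        double C = ap + tau[r];
        double t = std::log(p[r]) + std::lgamma(C) - std::lgamma(C + n)
                   + baseSum - lrf[r]
                   + std::lgamma(a[r] + tau[r] + m.Y(i, r))
                   - std::lgamma(a[r] + tau[r]);
        if (t > lse) lse = t + std::log1p(std::exp(lse - t));
        else lse += std::log1p(std::exp(t - lse));
      }
      li += lse;
    }
    if (!std::isfinite(li)) return false;
    ll[i] = li;
  }
  return true;
}

double dnormLog(double x, double sd) {
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) - 0.5 * x * x / (sd * sd);
}

// Log-prior (plus Jacobians) on the unconstrained scale.
double logPrior(const ModelSpec& m, const arma::vec& theta) {
  const int D = m.D;
  double lp = 0.0;
  int idx = 0;
  // theta_k live at the tail; locate them first when needed
  int thetaOff = nPar(m) - (m.spike ? (m.K1 - 1) : 0);
  int coefPerCat = m.K1;
  // coefficients, category-major
  std::vector<double> slabLog(m.K1 - 1, 0.0), spikeLog(m.K1 - 1, 0.0);
  for (int r = 0; r < D - 1; ++r) {
    for (int k = 0; k < coefPerCat; ++k) {
      double b = theta[idx++];
      if (!m.spike) {
        lp += dnormLog(b, k == 0 ? m.interceptSd : m.coeffSd);
      } else if (k == 0) {
        lp += dnormLog(b, m.interceptSd);
      } else {
        slabLog[k - 1] += dnormLog(b, std::sqrt(m.slabVar));
        spikeLog[k - 1] += dnormLog(b, std::sqrt(m.spikeVar));
      }
    }
  }
  if (m.spike) {
    for (int k = 0; k < m.K1 - 1; ++k) {
      double t = theta[thetaOff + k];
      double th = logistic(t);
      double lth = std::log(th), l1th = std::log1p(-th);
      // marginalized two-component normal mixture over the inclusion indicator
      double s1 = lth + slabLog[k], s0 = l1th + spikeLog[k];
      double mx = std::max(s1, s0);
      lp += mx + std::log(std::exp(s1 - mx) + std::exp(s0 - mx));
      // Beta prior on theta_k plus logit Jacobian
      lp += (m.thetaA - 1.0) * lth + (m.thetaB - 1.0) * l1th
            - R::lbeta(m.thetaA, m.thetaB) + lth + l1th;
    }
  }
  if (m.family >= 1) {
    double la = theta[idx++];
    double ap = std::exp(la);
    // Gamma(shape, rate) density plus log Jacobian (d ap / d la = ap)
    lp += m.gamShape * std::log(m.gamRate) - std::lgamma(m.gamShape)
          + (m.gamShape - 1.0) * la - m.gamRate * ap + la;
  }
  if (m.family >= 2) {
    double lj = 0.0;
    arma::vec p = stickSimplex(theta.subvec(idx, idx + D - 2), &lj);
    idx += D - 1;
    double lbet = 0.0, csum = 0.0;
    for (int r = 0; r < D; ++r) {
      lp += (m.dirConc[r] - 1.0) * std::log(p[r]);
      lbet += std::lgamma(m.dirConc[r]);
      csum += m.dirConc[r];
    }
    lp += std::lgamma(csum) - lbet + lj;
    int nw = (m.family == 2) ? 1 : D;
    for (int r = 0; r < nw; ++r) {
      double v = theta[idx++];
      double wtr = logistic(v);
      lp += (m.wtA - 1.0) * std::log(wtr) + (m.wtB - 1.0) * std::log1p(-wtr)
            - R::lbeta(m.wtA, m.wtB) + std::log(wtr) + std::log1p(-wtr);
    }
  }
  return lp;
}

ModelSpec buildSpec(const arma::mat& Y, const arma::mat& X, int baseline,
                    int family, bool spike, double likWeight, List prior) {
  ModelSpec m;
  m.Y = Y; m.X = X;
  m.N = Y.n_rows; m.D = Y.n_cols; m.K1 = X.n_cols;
  m.baseline = baseline; m.family = family; m.spike = spike;
  m.likWeight = likWeight;
  m.n_i = arma::sum(Y, 1);
  m.countConst.set_size(m.N);
  for (int i = 0; i < m.N; ++i) {
    double c = std::lgamma(m.n_i[i] + 1.0);
    for (int r = 0; r < m.D; ++r) c -= std::lgamma(Y(i, r) + 1.0);
    m.countConst[i] = c;
  }
  m.coeffSd = as<double>(prior["coeffSd"]);
  m.interceptSd = as<double>(prior["interceptSd"]);
  m.gamShape = as<double>(prior["gamShape"]);
  m.gamRate = as<double>(prior["gamRate"]);
  m.dirConc = as<arma::vec>(prior["dirConc"]);
  m.wtA = as<double>(prior["wtBetaA"]);
  m.wtB = as<double>(prior["wtBetaB"]);
  m.slabVar = as<double>(prior["slabVar"]);
  m.spikeVar = as<double>(prior["spikeVar"]);
  m.thetaA = as<double>(prior["thetaA"]);
  m.thetaB = as<double>(prior["thetaB"]);
  return m;
}

double logPost(const ModelSpec& m, const arma::vec& theta, arma::vec& ll,
               bool* ok) {
  *ok = true;
  double lp = logPrior(m, theta);
  if (!std::isfinite(lp)) { *ok = false; return NEG_INF; }
  if (m.likWeight != 0.0) {
    if (!logLikVec(m, theta, ll)) { *ok = false; return NEG_INF; }
    lp += m.likWeight * arma::accu(ll);
  } else {
    ll.zeros(m.N);
  }
  return lp;
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_reg_loglik(const arma::mat& Y, const arma::mat& X,
                                   const arma::vec& theta, int baseline,
                                   int family, Rcpp::List prior) {
  ModelSpec m = buildSpec(Y, X, baseline, family, false, 1.0, prior);
  arma::vec ll;
  if (!logLikVec(m, theta, ll))
    Rcpp::stop("non-finite log-likelihood for the supplied parameters");
  return Rcpp::wrap(ll);
}

// [[Rcpp::export]]
double cpp_log_posterior(const arma::mat& Y, const arma::mat& X,
                         const arma::vec& theta, int baseline, int family,
                         bool spike, double likWeight, Rcpp::List prior) {
  ModelSpec m = buildSpec(Y, X, baseline, family, spike, likWeight, prior);
  arma::vec ll;
  bool ok;
  return logPost(m, theta, ll, &ok);
}

namespace {

// adaptation state for one proposal block (a contiguous index range, or the
// full vector for the joint move)
struct Block {
  int lo, len;
  arma::vec mean;
  arma::mat cov, L;
  double logScale = 0.0;
  long accepted = 0, proposed = 0;

  void initFrom(const arma::vec& cur, int lo_, int len_) {
    lo = lo_; len = len_;
    mean = cur.subvec(lo, lo + len - 1);
    cov = arma::eye(len, len) * 1e-4;
    L = arma::eye(len, len) * 0.05;
  }
  void adapt(const arma::vec& cur, double acc, double target, int t) {
    double w = 1.0 / (t + 2.0);
    arma::vec x = cur.subvec(lo, lo + len - 1);
    arma::vec dlt = x - mean;
    mean += w * dlt;
    cov = (1.0 - w) * (cov + w * dlt * dlt.t());
    logScale += std::pow((double)(t + 1), -0.6) * (acc - target);
    if ((t + 1) % 50 == 0 && t + 1 >= std::max(100, 2 * len)) {
      double base = 2.38 / std::sqrt((double)len);
      arma::mat C = base * base * (cov + 1e-8 * arma::eye(len, len));
      arma::mat Lnew;
      if (arma::chol(Lnew, C, "lower")) L = Lnew;
    }
  }
};

} // namespace

// Blocked adaptive random-walk Metropolis. The coefficient block and the
// family/auxiliary block get their own Haario empirical-covariance proposals
// (plus one joint full-vector move per iteration to track cross-block
// correlation), each with Robbins-Monro scaling toward the target acceptance
// rate; all adaptation is frozen at the end of warmup. Uses R's RNG so runs
// are reproducible via set.seed().
// [[Rcpp::export]]
Rcpp::List cpp_run_am(const arma::mat& Y, const arma::mat& X,
                      const arma::vec& init, int baseline, int family,
                      bool spike, double likWeight, Rcpp::List prior,
                      int warmup, int samples, int thin,
                      double targetAccept) {
  ModelSpec m = buildSpec(Y, X, baseline, family, spike, likWeight, prior);
  const int P = init.n_elem;
  if (P != nPar(m)) Rcpp::stop("parameter vector has wrong length");

  arma::vec cur = init, curLL;
  bool ok;
  double curLP = logPost(m, cur, curLL, &ok);
  if (!ok) Rcpp::stop("non-finite log-posterior at initialization");

  std::vector<Block> blocks;
  int nB = nCoef(m);
  if (nB > 0 && nB < P) {
    Block b1; b1.initFrom(cur, 0, nB); blocks.push_back(b1);
    Block b2; b2.initFrom(cur, nB, P - nB); blocks.push_back(b2);
  }
  Block joint; joint.initFrom(cur, 0, P); blocks.push_back(joint);

  int S = samples / thin;
  arma::mat draws(S, P);
  arma::mat llmat(S, m.N);
  int stored = 0;

  RNGScope scope;
  int nIter = warmup + samples;
  for (int t = 0; t < nIter; ++t) {
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block& b = blocks[bi];
      arma::vec z(b.len);
      for (int j = 0; j < b.len; ++j) z[j] = R::norm_rand();
      arma::vec prop = cur;
      prop.subvec(b.lo, b.lo + b.len - 1) += std::exp(b.logScale) * (b.L * z);
      arma::vec propLL;
      bool pok;
      double propLP = logPost(m, prop, propLL, &pok);
      double acc = 0.0;
      if (pok) {
        double lr = propLP - curLP;
        acc = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < acc) {
          cur = prop; curLP = propLP; curLL = propLL;
          ++b.accepted;
        }
      }
      ++b.proposed;
      if (t < warmup) b.adapt(cur, acc, targetAccept, t);
    }
    if (t >= warmup) {
      int s = t - warmup;
      if ((s + 1) % thin == 0 && stored < S) {
        draws.row(stored) = cur.t();
        if (m.likWeight == 0.0) {
          if (!logLikVec(m, cur, curLL)) curLL.zeros(m.N);
        }
        llmat.row(stored) = curLL.t();
        ++stored;
      }
    }
  }

  arma::vec accRates(blocks.size());
  for (size_t bi = 0; bi < blocks.size(); ++bi)
    accRates[bi] = (double)blocks[bi].accepted / (double)blocks[bi].proposed;

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("loglik") = llmat,
      Rcpp::Named("acceptRate") = arma::mean(accRates),
      Rcpp::Named("blockAcceptRates") = accRates);
}
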