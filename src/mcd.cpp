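// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Minimum covariance determinant subset search.
//
// Exact mode enumerates every h-subset (used when choose(n, h) is small,
// which also serves tiny-instance verification); otherwise FAST-MCD:
// nsamp random (d+1)-element starts, each expanded until its covariance is
// nonsingular, two concentration steps per start, then full convergence on
// the ten best candidates.  Randomness comes from R's RNG so set.seed()
// governs reproducibility.

static const double LOGDET_SINGULAR = -690.0;  // ~ det < 1e-300

static double subset_logdet(const arma::mat &X, const arma::uvec &idx,
                            arma::vec &mu, arma::mat &S) {
  const arma::mat Xs = X.rows(idx);
  mu = arma::mean(Xs, 0).t();
  S = arma::cov(Xs);
  double ld, sign;
  arma::log_det(ld, sign, S);
  if (sign <= 0.0) return -arma::datum::inf;
  return ld;
}

// one concentration step: h points with smallest Mahalanobis distance
static arma::uvec c_step(const arma::mat &X, const arma::vec &mu,
                         const arma::mat &S, int h) {
  arma::mat Sinv;
  if (!arma::inv_sympd(Sinv, arma::symmatu(S)))
    return arma::uvec();  // numerically singular: caller abandons start
  arma::mat Xc = X.each_row() - mu.t();
  arma::vec d2 = arma::sum((Xc * Sinv) % Xc, 1);
  arma::uvec ord = arma::sort_index(d2);
  return arma::sort(ord.head(h));
}

static double concentrate(const arma::mat &X, arma::uvec &idx, int h,
                          int max_iter, arma::vec &mu, arma::mat &S) {
  double ld = subset_logdet(X, idx, mu, S);
  for (int it = 0; it < max_iter; ++it) {
    if (!std::isfinite(ld) || ld < LOGDET_SINGULAR) break;
    arma::uvec nxt = c_step(X, mu, S, h);
    if (nxt.n_elem == 0) break;  // singular inverse
    if (nxt.n_elem == idx.n_elem && arma::all(nxt == idx)) break;
    arma::vec mu2;
    arma::mat S2;
    double ld2 = subset_logdet(X, nxt, mu2, S2);
    if (ld2 >= ld - 1e-12) {  // converged (C-steps never increase det)
      if (ld2 < ld) { idx = nxt; mu = mu2; S = S2; ld = ld2; }
      break;
    }
    idx = nxt;
    mu = mu2;
    S = S2;
    ld = ld2;
  }
  return ld;
}

// next h-combination of {0..n-1} in lexicographic order; false when done
static bool next_comb(arma::uvec &c, int n) {
  const int h = c.n_elem;
  int i = h - 1;
  while (i >= 0 && c[i] == static_cast<unsigned>(n - h + i)) --i;
  if (i < 0) return false;
  ++c[i];
  for (int j = i + 1; j < h; ++j) c[j] = c[j - 1] + 1;
  return true;
}

// [[Rcpp::export]]
List cpp_mcd(const arma::mat &X, int h, int nsamp, bool exhaustive) {
  const int n = X.n_rows;
  const int d = X.n_cols;

  arma::uvec best_idx;
  arma::vec best_mu;
  arma::mat best_S;
  double best_ld = arma::datum::inf;

  if (exhaustive) {
    arma::uvec c = arma::regspace<arma::uvec>(0, h - 1);
    do {
      arma::vec mu;
      arma::mat S;
      double ld = subset_logdet(X, c, mu, S);
      if (std::isfinite(ld) && ld < best_ld) {
        best_ld = ld;
        best_idx = c;
        best_mu = mu;
        best_S = S;
      }
    } while (next_comb(c, n));
  } else {
    const int keep = 10;
    std::vector<arma::uvec> top_idx;
    std::vector<double> top_ld;

    for (int rep = 0; rep < nsamp; ++rep) {
      // random (d+1)-subset, expanded while singular
      arma::uvec perm(n);
      {
        // Fisher-Yates with R's RNG
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = n - 1; i > 0; --i) {
          int j = static_cast<int>(unif_rand() * (i + 1));
          std::swap(perm[i], perm[j]);
        }
      }
      int m = d + 1;
      arma::vec mu;
      arma::mat S;
      double ld = -arma::datum::inf;
      while (m <= n) {
        arma::uvec idx = arma::sort(perm.head(m));
        ld = subset_logdet(X, idx, mu, S);
        if (std::isfinite(ld) && ld > LOGDET_SINGULAR) break;
        ++m;
      }
      if (m > n) continue;
      arma::uvec idx = c_step(X, mu, S, h);  // C-step 1 from the start
      if (idx.n_elem == 0) continue;
      ld = concentrate(X, idx, h, 1, mu, S);  // C-step 2
      if (!std::isfinite(ld)) continue;

      if (static_cast<int>(top_idx.size()) < keep) {
        top_idx.push_back(idx);
        top_ld.push_back(ld);
      } else {
        int worst = 0;
        for (int k = 1; k < keep; ++k)
          if (top_ld[k] > top_ld[worst]) worst = k;
        if (ld < top_ld[worst]) {
          top_idx[worst] = idx;
          top_ld[worst] = ld;
        }
      }
    }

    for (size_t k = 0; k < top_idx.size(); ++k) {
      arma::uvec idx = top_idx[k];
      arma::vec mu;
      arma::mat S;
      double ld = concentrate(X, idx, h, 100, mu, S);
      if (std::isfinite(ld) && ld < best_ld) {
        best_ld = ld;
        best_idx = idx;
        best_mu = mu;
        best_S = S;
      }
    }
  }

  if (!std::isfinite(best_ld))
    stop("MCD failed: every candidate h-subset had a singular covariance");

  return List::create(_["subset"] = best_idx + 1, _["center"] = best_mu,
                      _["cov"] = best_S, _["log_det"] = best_ld);
}
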