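// Numerical core of the outlier-sum Gibbs sampler.
//
// The R-level conditional_weights()/os_regress() pair defines the reference
// semantics; this file mirrors them exactly (same perfect-fit rule, same
// sentinel cap, same target-exclusion rule) and is validated against the R
// path in the test suite.

#include <RcppArmadillo.h>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// t statistics of the coefficient `jidx` when regressing each column of Y on
// the design F (intercept included in F). Perfect fits and non-positive
// variances are reported at +/- cap, every |t| clamped at cap.
// symmetric eigenvalue pseudo-inverse, same truncation rule as the R path
static mat pinv_sym(const mat& G) {
  vec ev;
  mat V;
  eig_sym(ev, V, G);
  double cut = 1e-10 * std::max(ev.max(), 1e-300);
  mat C(G.n_rows, G.n_cols, fill::zeros);
  for (uword k = 0; k < ev.n_elem; ++k)
    if (ev(k) > cut) C += V.col(k) * V.col(k).t() / ev(k);
  return C;
}

static void seed_tstats(const mat& F, const mat& Y, uword jidx, double dof,
                        double cap, vec& tout) {
  mat G = F.t() * F;
  mat C = pinv_sym(G);
  mat T = F.t() * Y;   // P x n
  mat B = C * T;       // P x n
  rowvec yty = sum(Y % Y, 0);
  rowvec rss = yty - sum(T % B, 0);
  double cjj = C(jidx, jidx);
  tout.set_size(Y.n_cols);
  for (uword k = 0; k < Y.n_cols; ++k) {
    double r = rss(k) < 0 ? 0.0 : rss(k);
    bool perfect = r <= 1e-9 * (yty(k) + 1e-300);
    double b = B(jidx, k);
    double t;
    double se2 = (r / dof) * cjj;
    if (perfect || se2 <= 0) {
      t = (b >= 0) ? cap : -cap;
    } else {
      t = b / std::sqrt(se2);
      if (t > cap) t = cap;
      if (t < -cap) t = -cap;
    }
    tout(k) = t;
  }
}

// Conditional sampling weights for TF j given the other seeds.
static vec cond_weights(const mat& Xt, const uvec& seeds, uword j,
                        const std::vector<uvec>& pools, bool joint,
                        double tau, double dof, double cap, bool signed_os) {
  const uvec& pool = pools[j];
  uword K = Xt.n_rows, M = seeds.n_elem, nc = pool.n_elem;
  vec os(nc, fill::zeros);
  std::set<uword> excl;
  if (joint)
    for (uword m = 0; m < M; ++m) if (m != j) excl.insert(seeds(m));
  uword jidx = joint ? j + 1 : 1;
  mat F;
  if (joint) {
    F.set_size(K, M + 1);
    F.col(0).ones();
    for (uword m = 0; m < M; ++m) F.col(m + 1) = Xt.col(seeds(m));
  } else {
    F.set_size(K, 2);
    F.col(0).ones();
  }
  for (uword ci = 0; ci < nc; ++ci) {
    uword cand = pool(ci);
    std::vector<uword> tg;
    tg.reserve(nc);
    for (uword k = 0; k < nc; ++k) {
      uword g = pool(k);
      if (g == cand || excl.count(g)) continue;
      tg.push_back(g);
    }
    if (tg.empty()) continue;
    F.col(jidx) = Xt.col(cand);
    mat Y(K, tg.size());
    for (uword k = 0; k < tg.size(); ++k) Y.col(k) = Xt.col(tg[k]);
    vec t;
    seed_tstats(F, Y, jidx, dof, cap, t);
    double s = 0.0;
    if (signed_os) {
      for (uword k = 0; k < t.n_elem; ++k) if (t(k) >= tau) s += t(k);
    } else {
      for (uword k = 0; k < t.n_elem; ++k) {
        double a = std::fabs(t(k));
        if (a >= tau) s += a;
      }
    }
    os(ci) = s;
  }
  double tot = accu(os);
  if (tot <= 0) {
    os.fill(1.0 / nc);
    return os;
  }
  return os / tot;
}

static std::vector<uvec> convert_pools(const Rcpp::List& pools) {
  std::vector<uvec> out(pools.size());
  for (int j = 0; j < pools.size(); ++j) {
    Rcpp::IntegerVector p = pools[j];
    uvec v(p.size());
    for (int k = 0; k < p.size(); ++k) v(k) = (uword)(p[k] - 1);
    out[j] = v;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cw_cpp(const arma::mat& Xt, const arma::ivec& seeds1, int j1,
                 const Rcpp::List& pools, bool joint, double tau, double dof,
                 double cap, bool signed_os) {
  std::vector<uvec> pl = convert_pools(pools);
  uvec seeds(seeds1.n_elem);
  for (uword m = 0; m < seeds1.n_elem; ++m) seeds(m) = (uword)(seeds1(m) - 1);
  return cond_weights(Xt, seeds, (uword)(j1 - 1), pl, joint, tau, dof, cap,
                      signed_os);
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix gibbs_cpp(const arma::mat& Xt, const Rcpp::List& pools,
                              int n_iter, bool joint, double tau, double dof,
                              double cap, bool signed_os) {
  std::vector<uvec> pl = convert_pools(pools);
  uword M = pl.size();
  uvec seeds(M);
  for (uword j = 0; j < M; ++j) {
    uword Kj = pl[j].n_elem;
    uword pick = (uword)(unif_rand() * Kj);
    if (pick >= Kj) pick = Kj - 1;
    seeds(j) = pl[j](pick);
  }
  Rcpp::IntegerMatrix trace(M, n_iter);
  for (int it = 0; it < n_iter; ++it) {
    for (uword j = 0; j < M; ++j) {
      vec w = cond_weights(Xt, seeds, j, pl, joint, tau, dof, cap, signed_os);
      double u = unif_rand();
      double acc = 0.0;
      uword pick = w.n_elem - 1;
      for (uword k = 0; k < w.n_elem; ++k) {
        acc += w(k);
        if (u <= acc) { pick = k; break; }
      }
      seeds(j) = pl[j](pick);
      trace(j, it) = (int)seeds(j) + 1;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return trace;
}
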