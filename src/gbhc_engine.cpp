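// Core numerics for Gaussian Bayesian hierarchical clustering.
//
// All cluster-level quantities are carried as per-dimension sufficient
// statistics (count, mean, sum of squared deviations); all probability
// arithmetic is in log space. The greedy agglomeration and the per-merger
// conjugate-gradient hyperparameter optimization live here because the NODE
// scheme runs O(n^2) small optimizations.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logsumexp2(double x, double y) {
  if (x == NEG_INF) return y;
  if (y == NEG_INF) return x;
  double m = (x > y) ? x : y;
  return m + std::log(std::exp(x - m) + std::exp(y - m));
}

// ---------------------------------------------------------------------------
// Normal-gamma marginal likelihood and NODE objective/gradient.
//
// Per-dimension posterior updates with the prior mean fixed at zero:
//   c_n = c + n,  a_n = a + n/2,
//   b_n = b + ssd/2 + c n mean^2 / (2 (c + n)).
// Log marginal per dimension:
//   lgamma(a_n) - lgamma(a) + a log b - a_n log b_n
//     + (log c - log c_n)/2 - (n/2) log 2*pi.
// ---------------------------------------------------------------------------

struct ClusterStatsC {
  double n;
  std::vector<double> mean;
  std::vector<double> ssd;
};

static double marg_loglik_stats(const ClusterStatsC& s,
                                double c, double a, double b) {
  const int d = (int) s.mean.size();
  const double n = s.n;
  if (n <= 0.0) return 0.0;
  const double cn = c + n;
  const double an = a + 0.5 * n;
  const double base = R::lgammafn(an) - R::lgammafn(a) + a * std::log(b)
    + 0.5 * (std::log(c) - std::log(cn))
    - 0.5 * n * std::log(2.0 * M_PI);
  double tot = 0.0;
  for (int j = 0; j < d; ++j) {
    const double bn = b + 0.5 * s.ssd[j]
      + c * n * s.mean[j] * s.mean[j] / (2.0 * cn);
    tot += base - an * std::log(bn);
  }
  return tot;
}

// gradient of the log marginal w.r.t. (c, a, b), summed over dimensions
static void marg_grad_stats(const ClusterStatsC& s,
                            double c, double a, double b,
                            double grad[3]) {
  const int d = (int) s.mean.size();
  const double n = s.n;
  grad[0] = grad[1] = grad[2] = 0.0;
  if (n <= 0.0) return;
  const double cn = c + n;
  const double an = a + 0.5 * n;
  const double dig = R::digamma(an) - R::digamma(a);
  double sum_logbn = 0.0, sum_invbn = 0.0, sum_dbdc = 0.0;
  for (int j = 0; j < d; ++j) {
    const double m2 = s.mean[j] * s.mean[j];
    const double bn = b + 0.5 * s.ssd[j] + c * n * m2 / (2.0 * cn);
    sum_logbn += std::log(bn);
    sum_invbn += 1.0 / bn;
    // d b_n / d c = n^2 mean^2 / (2 (c+n)^2)
    sum_dbdc += (n * n * m2 / (2.0 * cn * cn)) / bn;
  }
  grad[0] = 0.5 * d * (1.0 / c - 1.0 / cn) - an * sum_dbdc;       // d/dc
  grad[1] = d * (dig + std::log(b)) - sum_logbn;                   // d/da
  grad[2] = d * a / b - an * sum_invbn;                            // d/db
}

// log gamma-prior density and its gradient; shape/rate per hyperparameter
static double prior_logpdf(const double hp[3],
                           const double shape[3], const double rate[3]) {
  double tot = 0.0;
  for (int i = 0; i < 3; ++i)
    tot += R::dgamma(hp[i], shape[i], 1.0 / rate[i], 1);
  return tot;
}

static void prior_grad(const double hp[3],
                       const double shape[3], const double rate[3],
                       double grad[3]) {
  for (int i = 0; i < 3; ++i)
    grad[i] = (shape[i] - 1.0) / hp[i] - rate[i];
}

// NODE objective: log marginal + log gamma hyper-priors
static double node_objective_stats(const ClusterStatsC& s, const double hp[3],
                                   const double shape[3], const double rate[3]) {
  return marg_loglik_stats(s, hp[0], hp[1], hp[2]) + prior_logpdf(hp, shape, rate);
}

static void node_gradient_stats(const ClusterStatsC& s, const double hp[3],
                                const double shape[3], const double rate[3],
                                double grad[3]) {
  double gl[3], gp[3];
  marg_grad_stats(s, hp[0], hp[1], hp[2], gl);
  prior_grad(hp, shape, rate, gp);
  for (int i = 0; i < 3; ++i) grad[i] = gl[i] + gp[i];
}

// ---------------------------------------------------------------------------
// Conjugate-gradient ascent (Polak-Ribiere+ with Armijo backtracking) on
// theta = (log c, log a, log b); positivity by reparameterization.
// ---------------------------------------------------------------------------

static const double THETA_CLAMP = 25.0;  // keeps exp(theta) finite

struct OptResult {
  double hp[3];
  double objective;
  bool converged;
  int iterations;
};

static inline void theta_to_hp(const double th[3], double hp[3]) {
  for (int i = 0; i < 3; ++i) {
    double t = th[i];
    if (t > THETA_CLAMP) t = THETA_CLAMP;
    if (t < -THETA_CLAMP) t = -THETA_CLAMP;
    hp[i] = std::exp(t);
  }
}

static double obj_theta(const ClusterStatsC& s, const double th[3],
                        const double shape[3], const double rate[3]) {
  double hp[3];
  theta_to_hp(th, hp);
  return node_objective_stats(s, hp, shape, rate);
}

static void grad_theta(const ClusterStatsC& s, const double th[3],
                       const double shape[3], const double rate[3],
                       double g[3]) {
  double hp[3], gx[3];
  theta_to_hp(th, hp);
  node_gradient_stats(s, hp, shape, rate, gx);
  for (int i = 0; i < 3; ++i) g[i] = gx[i] * hp[i];  // chain rule
}

static OptResult cg_optimize(const ClusterStatsC& s,
                             const double init[3],
                             const double shape[3], const double rate[3],
                             int maxit, double gtol, double ftol) {
  double th[3], g[3], dir[3];
  for (int i = 0; i < 3; ++i) th[i] = std::log(init[i]);
  double f = obj_theta(s, th, shape, rate);
  grad_theta(s, th, shape, rate, g);
  for (int i = 0; i < 3; ++i) dir[i] = g[i];
  bool converged = false;
  int iter = 0;
  int small_steps = 0;  // consecutive iterations with negligible ascent
  for (iter = 0; iter < maxit; ++iter) {
    double gnorm = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
    if (gnorm < gtol) { converged = true; break; }
    double slope = g[0]*dir[0] + g[1]*dir[1] + g[2]*dir[2];
    if (slope <= 0.0) {  // restart along the gradient
      for (int i = 0; i < 3; ++i) dir[i] = g[i];
      slope = gnorm * gnorm;
    }
    // Armijo backtracking
    double step = 1.0, fnew = NEG_INF;
    double thn[3];
    bool moved = false;
    while (step > 1e-14) {
      for (int i = 0; i < 3; ++i) thn[i] = th[i] + step * dir[i];
      fnew = obj_theta(s, thn, shape, rate);
      if (R_finite(fnew) && fnew >= f + 1e-4 * step * slope) { moved = true; break; }
      step *= 0.5;
    }
    if (!moved) { converged = true; break; }  // no ascent direction left
    double gnew[3];
    grad_theta(s, thn, shape, rate, gnew);
    double num = 0.0, den = 0.0;
    for (int i = 0; i < 3; ++i) {
      num += gnew[i] * (gnew[i] - g[i]);
      den += g[i] * g[i];
    }
    double beta = (den > 0.0) ? num / den : 0.0;
    if (beta < 0.0) beta = 0.0;  // PR+
    for (int i = 0; i < 3; ++i) {
      th[i] = thn[i];
      dir[i] = gnew[i] + beta * dir[i];
      g[i] = gnew[i];
    }
    double df = fnew - f;
    f = fnew;
    // a single tiny improvement can be a backtracked step far from the
    // optimum; demand two in a row before declaring convergence
    small_steps = (std::fabs(df) < ftol) ? small_steps + 1 : 0;
    if (small_steps >= 2) { converged = true; break; }
  }
  OptResult res;
  theta_to_hp(th, res.hp);
  res.objective = f;
  res.converged = converged;
  res.iterations = iter;
  return res;
}

// ---------------------------------------------------------------------------
// Exported scalar entry points
// ---------------------------------------------------------------------------

static ClusterStatsC make_stats(double n, NumericVector mean, NumericVector ssd) {
  if (mean.size() != ssd.size())
    stop("'mean' and 'ssd' must have equal length");
  ClusterStatsC s;
  s.n = n;
  s.mean = std::vector<double>(mean.begin(), mean.end());
  s.ssd = std::vector<double>(ssd.begin(), ssd.end());
  return s;
}

// [[Rcpp::export(name = ".cppMargLogLik")]]
double cpp_marg_loglik(double n, NumericVector mean, NumericVector ssd,
                       double c, double a, double b) {
  return marg_loglik_stats(make_stats(n, mean, ssd), c, a, b);
}

// [[Rcpp::export(name = ".cppNodeObjective")]]
double cpp_node_objective(double n, NumericVector mean, NumericVector ssd,
                          NumericVector hp, NumericVector shape, NumericVector rate) {
  double h[3] = { hp[0], hp[1], hp[2] };
  double sh[3] = { shape[0], shape[1], shape[2] };
  double rt[3] = { rate[0], rate[1], rate[2] };
  return node_objective_stats(make_stats(n, mean, ssd), h, sh, rt);
}

// [[Rcpp::export(name = ".cppNodeGradient")]]
NumericVector cpp_node_gradient(double n, NumericVector mean, NumericVector ssd,
                                NumericVector hp, NumericVector shape,
                                NumericVector rate) {
  double h[3] = { hp[0], hp[1], hp[2] };
  double sh[3] = { shape[0], shape[1], shape[2] };
  double rt[3] = { rate[0], rate[1], rate[2] };
  double g[3];
  node_gradient_stats(make_stats(n, mean, ssd), h, sh, rt, g);
  NumericVector out = NumericVector::create(
    Named("c") = g[0], Named("a") = g[1], Named("b") = g[2]);
  return out;
}

// [[Rcpp::export(name = ".cppOptimizeNode")]]
List cpp_optimize_node(double n, NumericVector mean, NumericVector ssd,
                       NumericVector init, NumericVector shape, NumericVector rate,
                       int maxit, double gtol, double ftol) {
  double in[3] = { init[0], init[1], init[2] };
  double sh[3] = { shape[0], shape[1], shape[2] };
  double rt[3] = { rate[0], rate[1], rate[2] };
  OptResult r = cg_optimize(make_stats(n, mean, ssd), in, sh, rt, maxit, gtol, ftol);
  return List::create(
    Named("c") = r.hp[0], Named("a") = r.hp[1], Named("b") = r.hp[2],
    Named("objective") = r.objective,
    Named("converged") = r.converged,
    Named("iterations") = r.iterations);
}

// ---------------------------------------------------------------------------
// Greedy agglomeration.
//
// Node ids: 1..N are leaves, N+t is the cluster created at merge t. The
// candidate pair with maximal posterior merge probability r is merged; ties
// break toward the lexicographically smallest pair of positions in the
// creation-ordered active list.
// ---------------------------------------------------------------------------

struct NodeC {
  ClusterStatsC stats;
  double logd, logpi, logmlh1, logmltree, r;
  double hp[3];
  int left, right;  // 0 for leaves (1-based ids otherwise)
};

static void merge_stats(const ClusterStatsC& x, const ClusterStatsC& y,
                        ClusterStatsC& out) {
  const int d = (int) x.mean.size();
  const double n = x.n + y.n;
  out.n = n;
  out.mean.resize(d);
  out.ssd.resize(d);
  for (int j = 0; j < d; ++j) {
    const double m = (x.n * x.mean[j] + y.n * y.mean[j]) / n;
    const double delta = x.mean[j] - y.mean[j];
    out.mean[j] = m;
    out.ssd[j] = x.ssd[j] + y.ssd[j] + x.n * y.n * delta * delta / n;
  }
}

struct PairScore {
  double r, logd, logpi, logmlh1, logmltree;
  double hp[3];
};

// score a candidate merger of nodes u, v
static PairScore score_pair(const NodeC& u, const NodeC& v, double log_alpha,
                            bool node_scheme, const double fixed_hp[3],
                            const double shape[3], const double rate[3],
                            int maxit, double gtol, double ftol) {
  PairScore p;
  ClusterStatsC merged;
  merge_stats(u.stats, v.stats, merged);
  const double nk = merged.n;
  const double lg = log_alpha + R::lgammafn(nk);
  p.logd = logsumexp2(lg, u.logd + v.logd);
  p.logpi = lg - p.logd;
  if (node_scheme) {
    // warm start from the larger child's optimized hyperparameters
    const double* w = (u.stats.n >= v.stats.n) ? u.hp : v.hp;
    double init[3] = { w[0], w[1], w[2] };
    OptResult o = cg_optimize(merged, init, shape, rate, maxit, gtol, ftol);
    p.hp[0] = o.hp[0]; p.hp[1] = o.hp[1]; p.hp[2] = o.hp[2];
  } else {
    p.hp[0] = fixed_hp[0]; p.hp[1] = fixed_hp[1]; p.hp[2] = fixed_hp[2];
  }
  p.logmlh1 = marg_loglik_stats(merged, p.hp[0], p.hp[1], p.hp[2]);
  // r = 1 / (1 + exp(t2 - t1)) with t1 = logpi + logmlh1 and
  // t2 = log(1-pi) + children's tree marginals. Computing t2 - t1 as below
  // cancels logd_k exactly, avoiding the loss of precision in logpi itself
  // when alpha*Gamma(n_k) dominates d_i*d_j near the root.
  const double t1 = p.logpi + p.logmlh1;
  const double diff = (u.logd + v.logd + u.logmltree + v.logmltree)
    - (lg + p.logmlh1);
  if (diff == NEG_INF) {  // pi = 1: the split hypothesis has no prior mass
    p.logmltree = p.logmlh1;
    p.r = 1.0;
  } else {
    const double l1p = (diff > 0.0)
      ? diff + std::log1p(std::exp(-diff))
      : std::log1p(std::exp(diff));
    p.logmltree = t1 + l1p;
    double r = 1.0 / (1.0 + std::exp(diff));
    if (r > 1.0) r = 1.0;
    if (r < 0.0) r = 0.0;
    p.r = r;
  }
  return p;
}

// [[Rcpp::export(name = ".cppBuildTree")]]
List cpp_build_tree(NumericMatrix X, double alpha, bool node_scheme,
                    NumericVector fixed_hp, NumericVector shape,
                    NumericVector rate, NumericVector init,
                    int maxit, double gtol, double ftol) {
  const int N = X.nrow();
  const int D = X.ncol();
  if (N < 1) stop("need at least one observation");
  if (alpha <= 0.0) stop("'alpha' must be positive");
  const double log_alpha = std::log(alpha);
  const int M = 2 * N - 1;
  double fhp[3] = { fixed_hp[0], fixed_hp[1], fixed_hp[2] };
  double sh[3] = { shape[0], shape[1], shape[2] };
  double rt[3] = { rate[0], rate[1], rate[2] };
  double in0[3] = { init[0], init[1], init[2] };

  std::vector<NodeC> nodes(M);
  // leaves
  for (int i = 0; i < N; ++i) {
    NodeC& nd = nodes[i];
    nd.stats.n = 1.0;
    nd.stats.mean.resize(D);
    nd.stats.ssd.assign(D, 0.0);
    for (int j = 0; j < D; ++j) nd.stats.mean[j] = X(i, j);
    nd.logd = log_alpha;
    nd.logpi = 0.0;
    nd.left = nd.right = 0;
    if (node_scheme) {
      OptResult o = cg_optimize(nd.stats, in0, sh, rt, maxit, gtol, ftol);
      nd.hp[0] = o.hp[0]; nd.hp[1] = o.hp[1]; nd.hp[2] = o.hp[2];
    } else {
      nd.hp[0] = fhp[0]; nd.hp[1] = fhp[1]; nd.hp[2] = fhp[2];
    }
    nd.logmlh1 = marg_loglik_stats(nd.stats, nd.hp[0], nd.hp[1], nd.hp[2]);
    nd.logmltree = nd.logmlh1;
    nd.r = 1.0;
  }

  // active clusters in creation order; score cache indexed by node-id pairs
  std::vector<int> active(N);
  for (int i = 0; i < N; ++i) active[i] = i;
  std::vector<double> rscore((size_t) M * M, NEG_INF);
  auto rs = [&](int u, int v) -> double& {
    return rscore[(size_t) u * M + v];
  };
  for (int ai = 0; ai + 1 < (int) active.size(); ++ai)
    for (int bi = ai + 1; bi < (int) active.size(); ++bi) {
      int u = active[ai], v = active[bi];
      rs(u, v) = score_pair(nodes[u], nodes[v], log_alpha, node_scheme,
                            fhp, sh, rt, maxit, gtol, ftol).r;
    }

  for (int t = 0; t < N - 1; ++t) {
    // greedy argmax; strict > keeps the lexicographically smallest tie
    int bi = -1, bj = -1;
    double best = NEG_INF;
    const int A = (int) active.size();
    for (int ai = 0; ai + 1 < A; ++ai)
      for (int aj = ai + 1; aj < A; ++aj) {
        double val = rs(active[ai], active[aj]);
        if (val > best) { best = val; bi = ai; bj = aj; }
      }
    const int u = active[bi], v = active[bj];
    const int k = N + t;
    PairScore p = score_pair(nodes[u], nodes[v], log_alpha, node_scheme,
                             fhp, sh, rt, maxit, gtol, ftol);
    NodeC& nd = nodes[k];
    merge_stats(nodes[u].stats, nodes[v].stats, nd.stats);
    nd.logd = p.logd; nd.logpi = p.logpi;
    nd.logmlh1 = p.logmlh1; nd.logmltree = p.logmltree; nd.r = p.r;
    nd.hp[0] = p.hp[0]; nd.hp[1] = p.hp[1]; nd.hp[2] = p.hp[2];
    nd.left = u + 1; nd.right = v + 1;
    active.erase(active.begin() + bj);
    active.erase(active.begin() + bi);
    for (int m : active)
      rs(std::min(m, k), std::max(m, k)) =
        score_pair(nodes[std::min(m, k)], nodes[std::max(m, k)],
                   log_alpha, node_scheme, fhp, sh, rt, maxit, gtol, ftol).r;
    active.push_back(k);
  }

  IntegerVector left(M), right(M), nk(M);
  NumericVector logd(M), logpi(M), logmlh1(M), logmltree(M), rr(M);
  NumericMatrix hps(M, 3), means(M, D), ssds(M, D);
  for (int i = 0; i < M; ++i) {
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    nk[i] = (int) nodes[i].stats.n;
    logd[i] = nodes[i].logd; logpi[i] = nodes[i].logpi;
    logmlh1[i] = nodes[i].logmlh1; logmltree[i] = nodes[i].logmltree;
    rr[i] = nodes[i].r;
    for (int j = 0; j < 3; ++j) hps(i, j) = nodes[i].hp[j];
    for (int j = 0; j < D; ++j) {
      means(i, j) = nodes[i].stats.mean[j];
      ssds(i, j) = nodes[i].stats.ssd[j];
    }
  }
  colnames(hps) = CharacterVector::create("c", "a", "b");
  return List::create(
    Named("left") = left, Named("right") = right, Named("nK") = nk,
    Named("logD") = logd, Named("logPi") = logpi,
    Named("logMlH1") = logmlh1, Named("logMlTree") = logmltree,
    Named("r") = rr, Named("hp") = hps,
    Named("means") = means, Named("ssds") = ssds);
}

// Root log marginal likelihood of a fixed tree structure under shared
// hyperparameters; used by the TREE scheme's inner optimization.
// [[Rcpp::export(name = ".cppRootLogLikFixed")]]
double cpp_root_loglik_fixed(IntegerVector left, IntegerVector right,
                             NumericVector nk, NumericMatrix means,
                             NumericMatrix ssds, double alpha,
                             double c, double a, double b) {
  const int M = left.size();
  const int D = means.ncol();
  const double log_alpha = std::log(alpha);
  std::vector<double> logd(M), logml(M), logmltree(M);
  for (int i = 0; i < M; ++i) {
    ClusterStatsC s;
    s.n = nk[i];
    s.mean.resize(D);
    s.ssd.resize(D);
    for (int j = 0; j < D; ++j) { s.mean[j] = means(i, j); s.ssd[j] = ssds(i, j); }
    logml[i] = marg_loglik_stats(s, c, a, b);
    if (left[i] == 0) {
      logd[i] = log_alpha;
      logmltree[i] = logml[i];
    } else {
      const int li = left[i] - 1, ri = right[i] - 1;
      const double lg = log_alpha + R::lgammafn(nk[i]);
      logd[i] = logsumexp2(lg, logd[li] + logd[ri]);
      const double logpi = lg - logd[i];
      // same cancellation-free form as in score_pair
      const double diff = (logd[li] + logd[ri] + logmltree[li] + logmltree[ri])
        - (lg + logml[i]);
      if (diff == NEG_INF) {
        logmltree[i] = logml[i];
      } else {
        const double l1p = (diff > 0.0)
          ? diff + std::log1p(std::exp(-diff))
          : std::log1p(std::exp(diff));
        logmltree[i] = logpi + logml[i] + l1p;
      }
    }
  }
  return logmltree[M - 1];
}
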