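#include <Rcpp.h>
using namespace Rcpp;

// Core Monte Carlo kernels for the sequence-learning student.
// All randomness goes through R's RNG so set.seed() makes every
// simulation bit-reproducible from R.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Simulate one episode on the chain prefix 1..k and apply K-step TD
// updates to q in place. Only correct (rewarded-chain) actions carry a
// learned value; incorrect actions are fixed at value 0 and update
// nothing. Updates are applied in temporal order: the n-step target for
// step i reads q[i+K] before that entry is itself updated.
//
// Returns the failure step (1-based), or 0 on success.
static int episode_inplace(double* q, const double* eps, double alpha,
                           int k, int K, double rew) {
  int fail = 0;
  for (int i = 0; i < k; ++i) {
    double p = sigmoid(q[i] + eps[i]);
    if (unif_rand() >= p) { fail = i + 1; break; }
  }
  int last_correct = (fail == 0) ? k : fail - 1;
  if (alpha > 0.0) {
    for (int i = 1; i <= last_correct; ++i) {
      double target;
      if (fail == 0) {
        // terminal reward lies inside the K-step window once i+K > k
        target = (i + K > k) ? rew : q[i + K - 1];
      } else {
        // no reward; bootstrap only if state i+K was actually reached
        target = (i + K <= fail) ? q[i + K - 1] : 0.0;
      }
      q[i - 1] += alpha * (target - q[i - 1]);
    }
  }
  return fail;
}

// [[Rcpp::export]]
List cpp_run_episode(NumericVector q, NumericVector eps, double alpha,
                     int k, int K, double rew) {
  NumericVector qq = clone(q);
  int fail = episode_inplace(REAL(qq), REAL(eps), alpha, k, K, rew);
  int outcome = (fail == 0) ? 1 : 0;
  int steps = (fail == 0) ? k : fail;
  IntegerVector trace(steps, 1);
  if (fail > 0) trace[steps - 1] = 0;
  return List::create(_["outcome"] = outcome, _["steps"] = steps,
                      _["trace"] = trace, _["q"] = qq);
}

// [[Rcpp::export]]
List cpp_run_interaction(NumericVector q, NumericVector eps, double alpha,
                         int k, int T, int K, double rew) {
  NumericVector qq = clone(q);
  IntegerVector outcomes(T);
  for (int t = 0; t < T; ++t) {
    int fail = episode_inplace(REAL(qq), REAL(eps), alpha, k, K, rew);
    outcomes[t] = (fail == 0) ? 1 : 0;
  }
  return List::create(_["outcomes"] = outcomes, _["q"] = qq);
}

// [[Rcpp::export]]
double cpp_episode_success_prob(NumericVector q, NumericVector eps, int k) {
  double p = 1.0;
  for (int i = 0; i < k; ++i) p *= sigmoid(q[i] + eps[i]);
  return p;
}

// Advance one particle's q through an episode whose outcome is known.
// On success the trace is unique (all steps correct). On failure the
// failure step is drawn from its exact conditional distribution
// P(fail at j | failure) = prod_{i<j} p_i (1-p_j) / (1 - prod p_i).
static void conditional_episode(double* q, const double* eps, double alpha,
                                int k, int K, int outcome, double rew) {
  int fail = 0;
  if (outcome == 0) {
    double psucc = 1.0, cum = 1.0;
    for (int i = 0; i < k; ++i) psucc *= sigmoid(q[i] + eps[i]);
    double denom = 1.0 - psucc;
    if (denom <= 0.0) { fail = k; }
    else {
      double u = unif_rand() * denom, acc = 0.0;
      fail = k; // fallback for numerical leftovers
      for (int j = 0; j < k; ++j) {
        double pj = sigmoid(q[j] + eps[j]);
        acc += cum * (1.0 - pj);
        if (u < acc) { fail = j + 1; break; }
        cum *= pj;
      }
    }
  }
  int last_correct = (fail == 0) ? k : fail - 1;
  if (alpha > 0.0) {
    for (int i = 1; i <= last_correct; ++i) {
      double target;
      if (fail == 0) target = (i + K > k) ? rew : q[i + K - 1];
      else target = (i + K <= fail) ? q[i + K - 1] : 0.0;
      q[i - 1] += alpha * (target - q[i - 1]);
    }
  }
}

// Particle-filter sweep over one interaction block: for each particle,
// multiply the weight by the likelihood of each observed outcome in
// order and advance the particle's q by a sampled trace consistent with
// that outcome. Returns updated log-weights and q matrix.
// [[Rcpp::export]]
List cpp_belief_update(NumericMatrix qmat, NumericVector eps_mat,
                       NumericVector alpha, NumericVector logw,
                       int k, IntegerVector outcomes, int K, double rew) {
  int n = qmat.nrow(), N = qmat.ncol(), T = outcomes.size();
  NumericMatrix qout = clone(qmat);
  NumericVector lw = clone(logw);
  // eps_mat is n x N in column-major order (one row per particle)
  std::vector<double> qi(N), ei(N);
  for (int p = 0; p < n; ++p) {
    for (int j = 0; j < N; ++j) {
      qi[j] = qout(p, j);
      ei[j] = eps_mat[p + (R_xlen_t)n * j];
    }
    double a = alpha[p];
    for (int t = 0; t < T; ++t) {
      double psucc = 1.0;
      for (int i = 0; i < k; ++i) psucc *= sigmoid(qi[i] + ei[i]);
      double like = outcomes[t] == 1 ? psucc : 1.0 - psucc;
      lw[p] += (like > 0.0) ? std::log(like) : R_NegInf;
      conditional_episode(qi.data(), ei.data(), a, k, K, outcomes[t], rew);
    }
    for (int j = 0; j < N; ++j) qout(p, j) = qi[j];
  }
  return List::create(_["logw"] = lw, _["q"] = qout);
}

// Rollout for POMCP: from a sampled student state, follow the
// incremental teacher rule on the simulated success-rate tracker and
// return the discounted return (1 discounted to the interaction at
// which the simulated student crosses tau on the full task; 0 if the
// horizon is exhausted first).
// [[Rcpp::export]]
double cpp_rollout(NumericVector q, NumericVector eps, double alpha,
                   int level, NumericVector shat, int N, int T,
                   double tau, double beta, double gamma, int max_depth,
                   int K, double rew) {
  std::vector<double> qq(q.begin(), q.end());
  std::vector<double> s(shat.begin(), shat.end());
  double disc = 1.0;
  int lev = level;
  for (int d = 0; d < max_depth; ++d) {
    for (int t = 0; t < T; ++t) {
      int fail = episode_inplace(qq.data(), REAL(eps), alpha, lev, K, rew);
      double x = (fail == 0) ? 1.0 : 0.0;
      s[lev - 1] = (1.0 - beta) * s[lev - 1] + beta * x;
    }
    if (lev == N && s[N - 1] >= tau) return disc;
    if (s[lev - 1] >= tau && lev < N) ++lev;
    disc *= gamma;
  }
  return 0.0;
}
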