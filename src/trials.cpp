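// Monte-Carlo engine for nAFC decision trials.
//
// A trial starts from the uniform prior on the belief simplex, draws one
// isotropic Gaussian evidence sample per step from the true hypothesis,
// performs the Bayesian update in the log domain (log-sum-exp marginal),
// and stops at the first step where some posterior component strictly
// exceeds the boundary F(P; theta, alpha, beta).
//
// RNG is counter-based: each (stream, trial) pair gets its own generator
// seeded by a splitmix64 hash of (master_seed, stream, trial), so batches
// are bit-reproducible regardless of evaluation order and independent of
// R's RNG state. Normal deviates use an explicit Box-Muller transform to
// avoid implementation-defined std::normal_distribution behavior.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct TrialRng {
  uint64_t s;
  bool has_spare;
  double spare;
  explicit TrialRng(uint64_t seed) : s(seed), has_spare(false), spare(0.0) {}
  uint64_t next_u64() { s = splitmix64(s); return s; }
  // uniform in [0, 1)
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  // integer in [0, k)
  int below(int k) { return (int)(unif() * k) % k; }
};

enum Family { FLAT = 0, CURVE = 1, POWER = 2, OSCIL = 3 };

// shape function f(dmax; beta) with 0^0 := 1
inline double shape_f(int family, double dmax, double beta) {
  switch (family) {
    case FLAT:  return 0.0;
    case CURVE: return 1.0;
    case POWER: return (dmax == 0.0 && beta == 0.0) ? 1.0
                       : std::pow(dmax, beta);
    default:    return std::cos(6.283185307179586476925286766559 * beta * dmax);
  }
}

// F(P) = theta * [1 + alpha/C * sum_j f(dmax_j) * prod_j P_i]
inline double boundary_F(const std::vector<double>& P, int n,
                         const std::vector<int>& trips, int ntrip,
                         int family, double theta, double alpha, double beta) {
  if (family == FLAT || alpha == 0.0 || n < 3) return theta;
  double s = 0.0;
  for (int r = 0; r < ntrip; ++r) {
    double a = P[trips[3 * r]], b = P[trips[3 * r + 1]],
           c = P[trips[3 * r + 2]];
    double mx = a > b ? (a > c ? a : c) : (b > c ? b : c);
    double mn = a < b ? (a < c ? a : c) : (b < c ? b : c);
    s += shape_f(family, mx - mn, beta) * a * b * c;
  }
  return theta * (1.0 + alpha * s / ntrip);
}

}  // namespace

// Run a batch of decision trials. means: n x (n-1) matrix of hypothesis
// means; family: 0 flat, 1 curve, 2 power, 3 oscil; true_index: fixed
// zero-based truth, or -1 to draw uniformly per trial; master_seed/stream
// index the deterministic substream.
// [[Rcpp::export]]
DataFrame cpp_run_trials(NumericMatrix means, double sigma, int family,
                         double theta, double alpha, double beta,
                         double W, double cost_c, int n_trials, int max_steps,
                         double master_seed, int stream, int true_index) {
  const int n = means.nrow();
  const int d = means.ncol();
  if (n < 2) stop("need at least 2 hypotheses");
  if (true_index >= n) stop("true_index out of range");

  // triplet subspaces (zero-based, strictly increasing)
  std::vector<int> trips;
  int ntrip = 0;
  if (n >= 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k) {
          trips.push_back(i); trips.push_back(j); trips.push_back(k);
          ++ntrip;
        }
  }

  const uint64_t base =
      splitmix64((uint64_t)(int64_t)master_seed ^
                 splitmix64((uint64_t)(uint32_t)stream * 0xD6E8FEB86659FD93ULL));

  IntegerVector out_true(n_trials), out_chosen(n_trials), out_T(n_trials),
      out_err(n_trials);
  NumericVector out_reward(n_trials), out_belief(n_trials);
  LogicalVector out_term(n_trials);

  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> x(d), logp(n), logL(n), P(n);

  for (int tr = 0; tr < n_trials; ++tr) {
    TrialRng rng(splitmix64(base ^ ((uint64_t)(uint32_t)tr *
                                    0xA0761D6478BD642FULL)));
    int truth = (true_index >= 0) ? true_index : rng.below(n);
    out_true[tr] = truth;

    for (int i = 0; i < n; ++i) logp[i] = -std::log((double)n);

    int chosen = NA_INTEGER, T = 0;
    double belief = NA_REAL;
    bool done = false;

    for (int t = 1; t <= max_steps && !done; ++t) {
      for (int k = 0; k < d; ++k)
        x[k] = means(truth, k) + sigma * rng.normal();
      // log-likelihoods up to a common constant (absorbed by normalization)
      for (int i = 0; i < n; ++i) {
        double sq = 0.0;
        for (int k = 0; k < d; ++k) {
          double dlt = x[k] - means(i, k);
          sq += dlt * dlt;
        }
        logL[i] = -sq * inv2s2;
      }
      double mx = -INFINITY;
      for (int i = 0; i < n; ++i) {
        logp[i] += logL[i];
        if (logp[i] > mx) mx = logp[i];
      }
      double se = 0.0;
      for (int i = 0; i < n; ++i) se += std::exp(logp[i] - mx);
      double lse = mx + std::log(se);
      double pmax = -1.0;
      for (int i = 0; i < n; ++i) {
        logp[i] -= lse;
        P[i] = std::exp(logp[i]);
        if (P[i] > pmax) pmax = P[i];
      }
      double F = boundary_F(P, n, trips, ntrip, family, theta, alpha, beta);
      if (pmax > F) {
        // winner: argmax belief (any crosser is dominated by the maximum,
        // which therefore also crosses); exact ties uniform from the stream
        int nties = 0;
        for (int i = 0; i < n; ++i) if (P[i] == pmax) ++nties;
        int pick = (nties > 1) ? rng.below(nties) : 0;
        for (int i = 0; i < n; ++i)
          if (P[i] == pmax && pick-- == 0) { chosen = i; break; }
        belief = pmax;
        T = t;
        done = true;
      }
    }

    out_term[tr] = done;
    if (done) {
      int err = (chosen == truth) ? 0 : 1;
      out_chosen[tr] = chosen;
      out_err[tr] = err;
      out_T[tr] = T;
      out_belief[tr] = belief;
      out_reward[tr] = -W * err - cost_c * T;
    } else {
      out_chosen[tr] = NA_INTEGER;
      out_err[tr] = NA_INTEGER;
      out_T[tr] = NA_INTEGER;
      out_belief[tr] = NA_REAL;
      out_reward[tr] = NA_REAL;
    }
  }

  return DataFrame::create(
      _["trial_id"] = seq_len(n_trials), _["true_index"] = out_true,
      _["chosen"] = out_chosen, _["error"] = out_err, _["T"] = out_T,
      _["reward"] = out_reward, _["crossing_belief"] = out_belief,
      _["terminated"] = out_term);
}
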