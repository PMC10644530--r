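#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward-time simulation of a single replicate population.
//
// The random-draw order is a fixed contract shared with the pure-R stepper
// (advance_step): per time-step, first the parent draws (N uniforms in the
// high regime, one in the low regime, inverted through the cumulative
// relative-fitness vector), then per offspring in index order:
//   deletion uniform (only if d > 0 and the parent carries the locus),
//   jump uniform (only if jump_prob > 0),
//   beneficial/deleterious uniform, one gamma deviate,
//   and, when expression is tracked, magnitude and sign uniforms for dE.
// Both implementations therefore produce bit-identical streams from the
// same R RNG state, which the test suite exploits.

// Inverse-CDF categorical sampling accelerated by a bucket index over
// the cumulative weights: the answer (smallest i with cum[i] > target)
// is identical to a plain binary search, found by a short scan inside
// the pre-located bucket.
struct CumIndex {
  static const int K = 256;
  int start[K];
  double total;
  void build(const std::vector<double>& cum, int N) {
    total = cum[N - 1];
    int ptr = 0;
    for (int k = 0; k < K; ++k) {
      double thr = total * ((double)k / K);
      while (ptr < N - 1 && cum[ptr] <= thr) ++ptr;
      start[k] = ptr;
    }
  }
  int pick(const std::vector<double>& cum, int N, double u) const {
    double target = u * total;
    int k = (int)(u * K);
    if (k >= K) k = K - 1;
    int i = start[k];
    while (i < N - 1 && cum[i] <= target) ++i;
    return i;
  }
};

// [[Rcpp::export]]
List cpp_run_replicate(int N, int T, bool low_regime, double d,
                       double p, double f, double n, double s,
                       double jump_prob, double jump_effect,
                       double E0, double Emin, double Emax,
                       double alpha, double dEmin,
                       double fitness_threshold,
                       bool track_expression,
                       bool keep_ancestry,
                       bool collect_delta_A) {
  std::vector<double> F(N, 0.0), E(N, E0), Fn(N), En(N);
  std::vector<int> L(N, 1), Ln(N);
  std::vector<double> cum(N);
  std::vector<int> par(N);
  CumIndex idx;
  // hot path used by parameter sweeps: no deletion, no jump atom and
  // no expression tracking, so L stays 1 and E stays E0 throughout
  const bool fast_path = !track_expression && d == 0.0 && jump_prob == 0.0;

  // archives needed for LCA tracing: F per step, parents per step
  std::vector<double> F_arch((size_t)(T + 1) * N);
  std::vector<int> P_arch((size_t)T * N, -1);
  std::copy(F.begin(), F.end(), F_arch.begin());

  NumericMatrix traj(T + 1, 5); // mean_F, sd_F, mean_E, mean_A, n_carriers
  NumericVector fixed_fitness(low_regime ? T : 0);
  std::vector<double> dA;
  if (collect_delta_A) dA.reserve((size_t)T * N);

  const double scale_p = p / s, scale_n = n / s;
  const double inv_am1 = -1.0 / (alpha - 1.0);

  bool extinct = false;
  int steps_run = 0;

  // t = 0 summary row
  traj(0, 0) = 0.0; traj(0, 1) = 0.0; traj(0, 2) = E0; traj(0, 3) = 0.0;
  traj(0, 4) = N;

  for (int t = 0; t < T; ++t) {
    // viability, minfit, cumulative selection weights
    double minfit = R_PosInf;
    int n_viable = 0;
    for (int i = 0; i < N; ++i) {
      if (F[i] > -1.0) { ++n_viable; if (F[i] < minfit) minfit = F[i]; }
    }
    if (n_viable == 0) { extinct = true; break; }
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = (F[i] > -1.0) ? (1.0 + F[i] - minfit) : 0.0;
      acc += w;
      cum[i] = acc;
    }

    // parent selection
    idx.build(cum, N);
    if (low_regime) {
      int a = idx.pick(cum, N, unif_rand());
      std::fill(par.begin(), par.end(), a);
      fixed_fitness[t] = F[a];
    } else {
      for (int j = 0; j < N; ++j) par[j] = idx.pick(cum, N, unif_rand());
    }
    std::copy(par.begin(), par.end(), P_arch.begin() + (size_t)t * N);

    // offspring
    int carriers = 0;
    if (fast_path) {
      // d = 0, no jump, expression untracked: every offspring carries
      // the locus and only the fitness update remains
      for (int j = 0; j < N; ++j) {
        double dF = (unif_rand() < f) ? R::rgamma(s, scale_p)
                                      : -R::rgamma(s, scale_n);
        Fn[j] = F[par[j]] + dF;
      }
      carriers = N;
    } else {
    for (int j = 0; j < N; ++j) {
      int i = par[j];
      bool lost = (L[i] == 0);
      if (!lost && d > 0.0 && unif_rand() < d) lost = true;
      if (lost) {
        Ln[j] = 0; Fn[j] = 0.0; En[j] = 0.0;
        continue;
      }
      double dF;
      if (jump_prob > 0.0 && unif_rand() < jump_prob) {
        dF = jump_effect;
      } else if (unif_rand() < f) {
        dF = R::rgamma(s, scale_p);
      } else {
        dF = -R::rgamma(s, scale_n);
      }
      Fn[j] = F[i] + dF;
      if (track_expression) {
        double mag = dEmin * std::pow(1.0 - unif_rand(), inv_am1);
        double dE = (unif_rand() < 0.5) ? -mag : mag;
        double e = E[i] + dE;
        if (e < Emin) e = Emin; else if (e > Emax) e = Emax;
        En[j] = e;
        if (collect_delta_A) dA.push_back(Fn[j] / e - F[i] / E[i]);
      } else {
        En[j] = E0;
      }
      Ln[j] = 1;
      ++carriers;
    }
    }
    std::swap(F, Fn);
    if (!fast_path) { std::swap(E, En); std::swap(L, Ln); }
    std::copy(F.begin(), F.end(), F_arch.begin() + (size_t)(t + 1) * N);
    steps_run = t + 1;

    // per-step summaries
    double sF = 0.0, sF2 = 0.0, sE = 0.0, sA = 0.0;
    for (int i = 0; i < N; ++i) {
      sF += F[i]; sF2 += F[i] * F[i];
      if (L[i] == 1) { sE += E[i]; sA += F[i] / E[i]; }
    }
    double mF = sF / N;
    double var = (sF2 - N * mF * mF) / (N - 1);
    traj(t + 1, 0) = mF;
    traj(t + 1, 1) = var > 0.0 ? std::sqrt(var) : 0.0;
    traj(t + 1, 2) = carriers > 0 ? sE / carriers : NA_REAL;
    traj(t + 1, 3) = carriers > 0 ? sA / carriers : NA_REAL;
    traj(t + 1, 4) = carriers;

    if (carriers == 0) {
      // locus lost from the whole population: dynamics are frozen at F = 0
      for (int tt = t + 1; tt < T; ++tt) {
        traj(tt + 1, 0) = 0.0; traj(tt + 1, 1) = 0.0;
        traj(tt + 1, 2) = NA_REAL; traj(tt + 1, 3) = NA_REAL;
        traj(tt + 1, 4) = 0;
        if (low_regime && tt < T) fixed_fitness[tt] = 0.0;
      }
      std::fill(F_arch.begin() + (size_t)(t + 2) * N, F_arch.end(), 0.0);
      // ancestry beyond this point is irrelevant for retention/crossing;
      // mark each later offspring as descending from individual 0
      for (int tt = t + 1; tt < T; ++tt)
        std::fill(P_arch.begin() + (size_t)tt * N, P_arch.begin() + (size_t)(tt + 1) * N, 0);
      steps_run = T;
      break;
    }
  }

  // an extinct replicate (no viable individual left) retains nothing
  bool retained = false;
  if (!extinct)
    for (int i = 0; i < N; ++i) if (L[i] == 1) { retained = true; break; }

  // trace the last common ancestor from the final completed step backwards
  double lca_fitness = 0.0;
  int lca_time = 0, lca_index = NA_INTEGER;
  bool coalesced = false;
  if (!extinct && steps_run == T) {
    std::vector<char> in_set(N, 0), nxt(N, 0);
    int set_size = 0;
    const int* row = &P_arch[(size_t)(T - 1) * N];
    for (int j = 0; j < N; ++j) if (!in_set[row[j]]) { in_set[row[j]] = 1; ++set_size; }
    int k = 1; // X after k backward steps lives in population T - k
    while (set_size > 1 && k < T) {
      const int* r = &P_arch[(size_t)(T - k - 1) * N];
      std::fill(nxt.begin(), nxt.end(), 0);
      int m = 0;
      for (int j = 0; j < N; ++j)
        if (in_set[j] && !nxt[r[j]]) { nxt[r[j]] = 1; ++m; }
      std::swap(in_set, nxt);
      set_size = m;
      ++k;
    }
    if (set_size == 1) {
      coalesced = true;
      for (int j = 0; j < N; ++j) if (in_set[j]) { lca_index = j + 1; break; }
      lca_time = T - k;
      lca_fitness = F_arch[(size_t)lca_time * N + (lca_index - 1)];
    } else {
      // population never coalesced within the run: the founding clone
      // (fitness 0) is the de facto common ancestor
      coalesced = false;
      lca_time = 0;
      lca_fitness = 0.0;
    }
  }

  bool crossed = retained && (lca_fitness > fitness_threshold);
  bool ever_crossed = crossed;
  if (low_regime && !extinct) {
    for (int t = 0; t < steps_run; ++t)
      if (fixed_fitness[t] > fitness_threshold) { ever_crossed = true; break; }
  }

  List out = List::create(
    _["trajectory"] = traj,
    _["retained"] = retained,
    _["crossed"] = crossed,
    _["ever_crossed"] = ever_crossed,
    _["extinct"] = extinct,
    _["coalesced"] = coalesced,
    _["lca_time"] = lca_time,
    _["lca_index"] = lca_index,
    _["lca_fitness"] = lca_fitness,
    _["steps_run"] = steps_run,
    _["final_F"] = NumericVector(F.begin(), F.end()),
    _["final_E"] = NumericVector(E.begin(), E.end()),
    _["final_L"] = IntegerVector(L.begin(), L.end()));
  if (low_regime) out["fixed_fitness"] = fixed_fitness;
  if (collect_delta_A) out["delta_A"] = NumericVector(dA.begin(), dA.end());
  if (keep_ancestry) {
    IntegerMatrix P(T, N);
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < N; ++j) P(t, j) = P_arch[(size_t)t * N + j] + 1;
    out["parents"] = P;
    NumericMatrix FA(T + 1, N);
    for (int t = 0; t <= T; ++t)
      for (int j = 0; j < N; ++j) FA(t, j) = F_arch[(size_t)t * N + j];
    out["F_archive"] = FA;
  }
  return out;
}

// Monte-Carlo classification census helper: draws `m` mutational effects
// from the two-sided gamma DFE and tallies the threshold classes in one
// pass without materialising the draws in R.
// [[Rcpp::export]]
List cpp_classify_draws(double p, double f, double n, double s,
                        double m, double threshold) {
  double n_pos = 0, n_neu = 0, n_neg = 0, sum_pos = 0, sum_neg = 0;
  const double scale_p = p / s, scale_n = n / s;
  for (double k = 0; k < m; ++k) {
    double x;
    if (unif_rand() < f) x = R::rgamma(s, scale_p);
    else x = -R::rgamma(s, scale_n);
    if (x >= threshold) { ++n_pos; sum_pos += x; }
    else if (x <= -threshold) { ++n_neg; sum_neg -= x; }
    else ++n_neu;
  }
  return List::create(
    _["n_positive"] = n_pos, _["n_neutral"] = n_neu, _["n_negative"] = n_neg,
    _["mean_abs_positive"] = n_pos > 0 ? sum_pos / n_pos : NA_REAL,
    _["mean_abs_negative"] = n_neg > 0 ? sum_neg / n_neg : NA_REAL);
}
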