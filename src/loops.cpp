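#include <Rcpp.h>
using namespace Rcpp;

// Greedy cycle peeling of a nonnegative, flux-conserving matrix J.
// Policy: start each search at the smallest-index state with positive
// out-flux; follow the largest outgoing entry (ties -> smallest column
// index); on the first revisit of a state on the current walk, peel the
// enclosed cycle by its minimum edge value. Entries below floor_val are
// zeroed before and during peeling, which guarantees termination (each
// peel removes at least one positive entry).
// [[Rcpp::export]]
List peel_loops_cpp(NumericMatrix J, double floor_val) {
  const int N = J.nrow();
  NumericMatrix W(clone(J));
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (W(i, j) < floor_val) W(i, j) = 0.0;

  std::vector< std::vector<int> > loops;
  std::vector<double> fluxes;
  std::vector<int> walk; walk.reserve(N + 1);
  std::vector<int> pos(N, -1);
  int start_scan = 0;

  for (;;) {
    int s = -1;
    for (int i = start_scan; i < N; ++i) {
      bool any = false;
      for (int j = 0; j < N; ++j) if (W(i, j) > 0) { any = true; break; }
      if (any) { s = i; break; }
      if (i == start_scan) ++start_scan;
    }
    if (s < 0) break;

    walk.clear();
    int cur = s;
    for (;;) {
      pos[cur] = (int)walk.size();
      walk.push_back(cur);
      int best = -1; double bv = 0.0;
      for (int j = 0; j < N; ++j) {
        double v = W(cur, j);
        if (v > bv) { bv = v; best = j; }
      }
      if (best < 0) {
        // dead end from numerical imbalance below the floor: drop the edge
        // that led here and restart the search
        for (size_t k = 0; k < walk.size(); ++k) pos[walk[k]] = -1;
        if (walk.size() >= 2) W(walk[walk.size() - 2], walk.back()) = 0.0;
        else W(cur, cur) = 0.0;
        break;
      }
      if (pos[best] >= 0) {
        const int p0 = pos[best];
        std::vector<int> cyc(walk.begin() + p0, walk.end());
        const int m = (int)cyc.size();
        double r = R_PosInf;
        for (int k = 0; k < m; ++k) {
          const double v = W(cyc[k], cyc[(k + 1) % m]);
          if (v < r) r = v;
        }
        for (int k = 0; k < m; ++k) {
          double &v = W(cyc[k], cyc[(k + 1) % m]);
          v -= r;
          if (v < floor_val) v = 0.0;
        }
        loops.push_back(cyc);
        fluxes.push_back(r);
        for (size_t k = 0; k < walk.size(); ++k) pos[walk[k]] = -1;
        break;
      }
      cur = best;
    }
  }

  List out_loops(loops.size());
  for (size_t k = 0; k < loops.size(); ++k) {
    IntegerVector v(loops[k].begin(), loops[k].end());
    out_loops[k] = v + 1;  // 1-based; R side converts to canonical indices
  }
  return List::create(_["states"] = out_loops,
                      _["flux"] = NumericVector(fluxes.begin(), fluxes.end()));
}

// Synchronous stochastic Boolean sampler. p_on is the 2^n x n matrix of
// per-node on-probabilities for every from-state (row = state index + 1).
// Returns 0-based state indices, length n_steps + 1. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector simulate_boolean_cpp(NumericMatrix p_on, int n_nodes,
                                   int n_steps, int start) {
  IntegerVector out(n_steps + 1);
  int cur = start;
  out[0] = cur;
  for (int t = 1; t <= n_steps; ++t) {
    int nxt = 0;
    for (int i = 0; i < n_nodes; ++i)
      if (unif_rand() < p_on(cur, i)) nxt |= (1 << i);
    cur = nxt;
    out[t] = cur;
  }
  return out;
}

// Generic finite-chain sampler by inverse CDF per row. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector simulate_markov_cpp(NumericMatrix T, int n_steps, int start) {
  const int N = T.nrow();
  IntegerVector out(n_steps + 1);
  int cur = start;
  out[0] = cur;
  for (int t = 1; t <= n_steps; ++t) {
    const double u = unif_rand();
    double acc = 0.0;
    int nxt = N - 1;
    for (int j = 0; j < N; ++j) {
      acc += T(cur, j);
      if (u < acc) { nxt = j; break; }
    }
    cur = nxt;
    out[t] = cur;
  }
  return out;
}
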