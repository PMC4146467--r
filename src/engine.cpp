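#include <Rcpp.h>
using namespace Rcpp;

// Shared synchronous-update kernel for batches of network states.
//
// States are held column-major (one column per node). Truth tables are
// indexed in canonical mixed-radix row order: row = sum_k value(reg_k) *
// weight_k, with the first regulator most significant. Clamped nodes skip
// their tables entirely and are pinned to the clamp value.

namespace {

struct Compiled {
  int n_nodes;
  std::vector<std::vector<int>> regs;     // 0-based regulator indices
  std::vector<std::vector<int>> weights;  // row strides
  std::vector<std::vector<int>> tables;   // canonical-order outputs
  std::vector<int> clamp_value;           // -1 when unclamped
};

Compiled compile(List tables, List reg_idx, List weights,
                 IntegerVector clamp_idx, IntegerVector clamp_val) {
  Compiled c;
  c.n_nodes = tables.size();
  c.regs.resize(c.n_nodes);
  c.weights.resize(c.n_nodes);
  c.tables.resize(c.n_nodes);
  c.clamp_value.assign(c.n_nodes, -1);
  for (int i = 0; i < c.n_nodes; ++i) {
    IntegerVector r = reg_idx[i];
    NumericVector w = weights[i];
    IntegerVector t = tables[i];
    c.regs[i].assign(r.begin(), r.end());
    for (int &x : c.regs[i]) x -= 1;  // to 0-based
    c.weights[i].resize(w.size());
    for (int k = 0; k < w.size(); ++k) c.weights[i][k] = (int)w[k];
    c.tables[i].assign(t.begin(), t.end());
  }
  for (int k = 0; k < clamp_idx.size(); ++k)
    c.clamp_value[clamp_idx[k] - 1] = clamp_val[k];
  return c;
}

// one synchronous step: read cur, write nxt (both M x N column-major)
inline void step_all(const Compiled &c, const int *cur, int *nxt, int M) {
  for (int i = 0; i < c.n_nodes; ++i) {
    int *out = nxt + (size_t)i * M;
    if (c.clamp_value[i] >= 0) {
      const int v = c.clamp_value[i];
      for (int m = 0; m < M; ++m) out[m] = v;
      continue;
    }
    const std::vector<int> &regs = c.regs[i];
    const std::vector<int> &w = c.weights[i];
    const std::vector<int> &tab = c.tables[i];
    const int k = (int)regs.size();
    if (k == 0) {
      const int v = tab[0];
      for (int m = 0; m < M; ++m) out[m] = v;
    } else {
      for (int m = 0; m < M; ++m) {
        int idx = 0;
        for (int q = 0; q < k; ++q) idx += cur[(size_t)regs[q] * M + m] * w[q];
        out[m] = tab[idx];
      }
    }
  }
}

// one step of a single state vector (length N)
inline void step_one(const Compiled &c, const int *cur, int *nxt) {
  for (int i = 0; i < c.n_nodes; ++i) {
    if (c.clamp_value[i] >= 0) { nxt[i] = c.clamp_value[i]; continue; }
    const std::vector<int> &regs = c.regs[i];
    const int k = (int)regs.size();
    int idx = 0;
    for (int q = 0; q < k; ++q) idx += cur[regs[q]] * c.weights[i][q];
    nxt[i] = c.tables[i][k == 0 ? 0 : idx];
  }
}

} // namespace

// Evolve a batch of states a fixed number of steps; returns the final batch.
// [[Rcpp::export]]
IntegerMatrix engine_evolve(IntegerMatrix S, List tables, List reg_idx,
                            List weights, IntegerVector clamp_idx,
                            IntegerVector clamp_val, int steps) {
  Compiled c = compile(tables, reg_idx, weights, clamp_idx, clamp_val);
  const int M = S.nrow();
  IntegerMatrix A = clone(S);
  IntegerMatrix B(S.nrow(), S.ncol());
  int *a = INTEGER(A), *b = INTEGER(B);
  for (int t = 0; t < steps; ++t) {
    step_all(c, a, b, M);
    std::swap(a, b);
  }
  if (a == INTEGER(A)) return A;
  return B;
}

// Evolve a batch and record, at every step after `discard`, the mean value
// of one node across the batch. Returns the series (length steps - discard
// + 1, including the state right after the discard phase).
// [[Rcpp::export]]
List engine_mean_series(IntegerMatrix S, List tables, List reg_idx,
                        List weights, IntegerVector clamp_idx,
                        IntegerVector clamp_val, int discard, int record,
                        int node) {
  Compiled c = compile(tables, reg_idx, weights, clamp_idx, clamp_val);
  const int M = S.nrow();
  const int ni = node - 1;
  IntegerMatrix A = clone(S);
  IntegerMatrix B(S.nrow(), S.ncol());
  int *a = INTEGER(A), *b = INTEGER(B);
  for (int t = 0; t < discard; ++t) {
    step_all(c, a, b, M);
    std::swap(a, b);
  }
  NumericVector out(record + 1);
  for (int t = 0; t <= record; ++t) {
    if (t > 0) { step_all(c, a, b, M); std::swap(a, b); }
    const int *col = a + (size_t)ni * M;
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += col[m];
    out[t] = s / M;
  }
  return List::create(_["series"] = out);
}

// Attractor statistics per initial condition: evolve each trajectory
// privately, record its encoding history, detect the period as the first
// return of the post-burn-in state, the transient as the first time index
// lying on the cycle, and the canonical key as the smallest encoding on
// the cycle. enc_w are the mixed-radix encoding weights (node 1 most
// significant, as doubles).
// [[Rcpp::export]]
List engine_basin(IntegerMatrix S, List tables, List reg_idx, List weights,
                  IntegerVector clamp_idx, IntegerVector clamp_val,
                  int burn_in, int max_period, NumericVector enc_w) {
  Compiled c = compile(tables, reg_idx, weights, clamp_idx, clamp_val);
  const int M = S.nrow();
  const int N = S.ncol();
  IntegerVector period(M), transient(M);
  NumericVector canon(M);
  std::vector<int> cur(N), nxt(N);
  std::vector<double> enc(burn_in + max_period + 1);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < N; ++i) cur[i] = S(m, i);
    auto encode = [&](const std::vector<int> &s) {
      double e = 0.0;
      for (int i = 0; i < N; ++i) e += s[i] * enc_w[i];
      return e;
    };
    enc[0] = encode(cur);
    for (int t = 1; t <= burn_in; ++t) {
      step_one(c, cur.data(), nxt.data());
      cur.swap(nxt);
      enc[t] = encode(cur);
    }
    const double ref = enc[burn_in];
    int p = -1;
    for (int q = 1; q <= max_period; ++q) {
      step_one(c, cur.data(), nxt.data());
      cur.swap(nxt);
      enc[burn_in + q] = encode(cur);
      if (enc[burn_in + q] == ref) { p = q; break; }
    }
    if (p < 0)
      stop("trajectory did not return within max_period steps after burn_in; "
           "increase burn_in and/or max_period");
    int tr = 0;
    while (tr < burn_in && enc[tr] != enc[tr + p]) ++tr;
    double cmin = enc[burn_in];
    for (int q = 1; q < p; ++q)
      if (enc[burn_in + q] < cmin) cmin = enc[burn_in + q];
    period[m] = p;
    transient[m] = tr;
    canon[m] = cmin;
  }
  return List::create(_["period"] = period, _["transient"] = transient,
                      _["canon"] = canon);
}
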