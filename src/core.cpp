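#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Memory layout matches R's column-major 5x2 h-matrix flattened to 10
// doubles: entry (s, a) lives at (s + 2) + 5 * ((a + 1) / 2), i.e. rows are
// percepts -2..+2 and column 0 is "turn" (a = -1), column 1 "continue".

static inline int ring_dist(int x1, int x2, int W) {
  int d = x1 - x2;
  if (d < 0) d = -d;
  return d < W - d ? d : W - d;
}

static inline int clamp2(int v) {
  return v < -2 ? -2 : (v > 2 ? 2 : v);
}

// Net-flow percept of agent i against current neighbour headings.
static int percept_of(int i, const std::vector<int>& pos,
                      const std::vector<int>& head, int W, int r) {
  int net = 0;
  const int n = (int)pos.size();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (ring_dist(pos[i], pos[j], W) <= r)
      net += (head[j] == head[i]) ? 1 : -1;
  }
  return clamp2(net);
}

// Majority-alignment reward for agent i (heading already post-action).
static int reward_of(int i, const std::vector<int>& pos,
                     const std::vector<int>& head, int W, int r,
                     bool reward_ties) {
  int same = 0, opp = 0;
  const int n = (int)pos.size();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (ring_dist(pos[i], pos[j], W) <= r) {
      if (head[j] == head[i]) ++same; else ++opp;
    }
  }
  if (same + opp == 0) return 0;
  if (same > opp) return 1;
  if (same == opp && reward_ties) return 1;
  return 0;
}

// One full asynchronous sweep; agents act in index order, consuming one
// uniform variate each. hmem has `hcols` columns (1 = shared policy,
// N = per-agent memories). Logs, when requested, receive one row per turn.
static void do_sweep(std::vector<int>& pos, std::vector<int>& head,
                     double* hmem, int hcols, int W, int r,
                     bool learning, double gamma, bool reward_ties,
                     bool move_per_turn,
                     int* log_row /* 5 ints per turn or NULL */,
                     int t) {
  const int n = (int)pos.size();
  for (int i = 0; i < n; ++i) {
    double* h = hmem + (hcols == 1 ? 0 : 10 * i);
    int s = percept_of(i, pos, head, W, r);
    int row = s + 2;
    double h_turn = h[row], h_cont = h[row + 5];
    double p_turn = h_turn / (h_turn + h_cont);
    double u = unif_rand();
    int a = (u < p_turn) ? -1 : 1;
    if (a == -1) head[i] = -head[i];
    int R = reward_of(i, pos, head, W, r, reward_ties);
    if (learning) {
      for (int k = 0; k < 10; ++k) h[k] = 1.0 + (1.0 - gamma) * (h[k] - 1.0);
      h[row + (a == -1 ? 0 : 5)] += (double)R;
    }
    if (move_per_turn) {
      pos[i] += head[i];
      if (pos[i] < 0) pos[i] += W; else if (pos[i] >= W) pos[i] -= W;
    }
    if (log_row) {
      int* rowp = log_row + 5 * i;
      rowp[0] = t; rowp[1] = i + 1; rowp[2] = s; rowp[3] = a; rowp[4] = R;
    }
  }
  if (!move_per_turn) {
    for (int i = 0; i < n; ++i) {
      pos[i] += head[i];
      if (pos[i] < 0) pos[i] += W; else if (pos[i] >= W) pos[i] -= W;
    }
  }
}

// [[Rcpp::export]]
List cpp_run_sweeps(IntegerVector position, IntegerVector heading,
                    NumericMatrix hmem, int W, int r,
                    bool learning, double gamma, int steps,
                    bool reward_ties, bool move_per_turn,
                    int snapshot_every, bool log_turns) {
  const int n = position.size();
  std::vector<int> pos(position.begin(), position.end());
  std::vector<int> head(heading.begin(), heading.end());
  NumericMatrix hm = clone(hmem);
  const int hcols = hm.ncol();

  NumericVector z(steps + 1);
  int sum0 = 0;
  for (int i = 0; i < n; ++i) sum0 += head[i];
  z[0] = (double)sum0 / n;

  int nsnap = snapshot_every > 0 ? steps / snapshot_every + 1 : 0;
  NumericVector snaps(nsnap > 0 ? (R_xlen_t)10 * hcols * nsnap : 0);
  IntegerVector snap_t(nsnap);
  if (nsnap > 0) {
    std::copy(hm.begin(), hm.end(), snaps.begin());
    snap_t[0] = 0;
  }

  IntegerMatrix logs = log_turns ? IntegerMatrix((R_xlen_t)steps * n, 5)
                                 : IntegerMatrix(0, 5);
  std::vector<int> logbuf(log_turns ? 5 * n : 0);

  int isnap = 1;
  for (int t = 1; t <= steps; ++t) {
    do_sweep(pos, head, hm.begin(), hcols, W, r, learning, gamma,
             reward_ties, move_per_turn,
             log_turns ? logbuf.data() : (int*)0, t);
    int sum = 0;
    for (int i = 0; i < n; ++i) sum += head[i];
    z[t] = (double)sum / n;
    if (log_turns) {
      R_xlen_t base = (R_xlen_t)(t - 1) * n;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 5; ++k)
          logs(base + i, k) = logbuf[5 * i + k];
    }
    if (snapshot_every > 0 && t % snapshot_every == 0) {
      std::copy(hm.begin(), hm.end(),
                snaps.begin() + (R_xlen_t)10 * hcols * isnap);
      snap_t[isnap++] = t;
    }
  }

  List out = List::create(
      _["z"] = z,
      _["position"] = IntegerVector(pos.begin(), pos.end()),
      _["heading"] = IntegerVector(head.begin(), head.end()),
      _["hmem"] = hm,
      _["snapshots"] = snaps,
      _["snapshot_t"] = snap_t,
      _["logs"] = logs);
  return out;
}

// Monte-Carlo transition kernel of the alignment parameter: for every grid
// value z = (2m - N)/N the swarm is re-sampled (uniform positions, exactly
// m agents heading +1, assignment shuffled), one sweep of the fixed policy
// is applied, and the resulting m' is histogrammed.
// [[Rcpp::export]]
IntegerMatrix cpp_estimate_kernel(int N, int W, int r, NumericVector hpol,
                                  int n_samples, bool reward_ties,
                                  bool move_per_turn) {
  IntegerMatrix counts(N + 1, N + 1);
  std::vector<int> pos(N), head(N);
  std::vector<double> h(10);
  for (int m = 0; m <= N; ++m) {
    for (int s = 0; s < n_samples; ++s) {
      for (int i = 0; i < N; ++i) {
        pos[i] = (int)(unif_rand() * W);
        if (pos[i] >= W) pos[i] = W - 1;  // guard against u == 1.0
        head[i] = i < m ? 1 : -1;
      }
      // Fisher-Yates shuffle of the heading assignment
      for (int i = N - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(head[i], head[j]);
      }
      std::copy(hpol.begin(), hpol.end(), h.begin());
      do_sweep(pos, head, h.data(), 1, W, r, false, 0.0, reward_ties,
               move_per_turn, (int*)0, 1);
      int sum = 0;
      for (int i = 0; i < N; ++i) sum += head[i];
      counts(m, (sum + N) / 2) += 1;
    }
  }
  return counts;
}
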