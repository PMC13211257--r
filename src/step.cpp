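#include <Rcpp.h>
using namespace Rcpp;

// Axial neighbor offsets (col, row) on a pointy-top hex grid. Fixed order so
// snapshots and seeded runs are portable across platforms.
static const int OFF[6][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1}, {1, -1}, {-1, 1}};

static inline int wrap(int a, int n) {
  int r = a % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
IntegerVector hex_neighbors_cpp(int site, int width, int height) {
  // site is 0-based; returns 0-based indices in fixed offset order
  int col = site % width, row = site / width;
  IntegerVector out(6);
  for (int k = 0; k < 6; ++k) {
    int c = wrap(col + OFF[k][0], width);
    int r = wrap(row + OFF[k][1], height);
    out[k] = r * width + c;
  }
  return out;
}

// One full update step: synchronous mortality, then sequential replication of
// the survivors in a uniformly random order. Newly placed cells are not in the
// survivor list, so they cannot replicate within their birth step, but they do
// occupy space immediately (later cells in the order see them as blocked).
// All randomness comes from R's RNG stream (RNGScope via Rcpp attributes).
// [[Rcpp::export]]
IntegerVector ktw_step_cpp(IntegerVector occ, int width, int height,
                           NumericVector repl_prob, double mortality) {
  IntegerVector state = clone(occ);
  const int nsites = width * height;

  if (mortality > 0) {
    for (int i = 0; i < nsites; ++i) {
      if (state[i] != 0 && unif_rand() < mortality) state[i] = 0;
    }
  }

  std::vector<int> alive;
  alive.reserve(nsites);
  for (int i = 0; i < nsites; ++i)
    if (state[i] != 0) alive.push_back(i);

  // Fisher-Yates shuffle on R's stream: the replication order is uniform
  const int n = (int)alive.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(alive[i], alive[j]);
  }

  int empties[6];
  for (int idx = 0; idx < n; ++idx) {
    const int site = alive[idx];
    const int sp = state[site];
    if (unif_rand() >= repl_prob[sp - 1]) continue;
    const int col = site % width, row = site / width;
    int ne = 0;
    for (int k = 0; k < 6; ++k) {
      int c = wrap(col + OFF[k][0], width);
      int r = wrap(row + OFF[k][1], height);
      int nb = r * width + c;
      if (state[nb] == 0) empties[ne++] = nb;
    }
    if (ne == 0) continue;  // space-limited: no empty neighbor, no offspring
    int pick = (int)(unif_rand() * ne);
    if (pick >= ne) pick = ne - 1;
    state[empties[pick]] = sp;
  }
  return state;
}
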