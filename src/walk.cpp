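#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Deterministic uniform in [0,1) from a 32-bit Mersenne Twister draw.
// std::uniform_real_distribution is not pinned down by the standard;
// this keeps walks bit-reproducible for a given seed.
static inline double unif01(std::mt19937 &rng) {
  return rng() * (1.0 / 4294967296.0);
}

// Sample j proportional to row[j] over active j != skip; -1 if total weight 0.
// row points at a gathered length-n copy of one matrix row.
static int sample_row(const std::vector<double> &row,
                      const std::vector<char> &active,
                      int n, int skip, std::mt19937 &rng) {
  double tot = 0.0;
  for (int j = 0; j < n; ++j)
    if (active[j] && j != skip) tot += row[j];
  if (tot <= 0.0) return -1;
  double r = unif01(rng) * tot, acc = 0.0;
  int last = -1;
  for (int j = 0; j < n; ++j) {
    if (!active[j] || j == skip) continue;
    acc += row[j];
    last = j;
    if (r < acc) return j;
  }
  return last; // r landed on the upper boundary within rounding
}

static int sample_uniform_active(const std::vector<char> &active, int n,
                                 int nActive, std::mt19937 &rng) {
  int k = (int)(unif01(rng) * nActive);
  if (k >= nActive) k = nActive - 1;
  for (int j = 0; j < n; ++j) {
    if (!active[j]) continue;
    if (k-- == 0) return j;
  }
  return -1; // unreachable when nActive > 0
}

// Visit-capped node-removing random walk on the weighted graph W.
// Every arrival increments the current node's visit count; a node is
// removed the moment its count reaches m, the elapsed arrivals since the
// previous removal are recorded, and the chain takes one Markov step from
// the removed node's row restricted to the remaining nodes.
// [[Rcpp::export(name = ".regulated_walk_cpp")]]
List regulated_walk_cpp(NumericMatrix W, int m, int seed) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("W must be square");
  if (m < 1) stop("visit cap m must be >= 1");

  std::mt19937 rng((uint32_t)seed);
  std::vector<char> active(n, 1);
  std::vector<int> visits(n, 0);
  std::vector<int> order, rec;
  std::vector<double> row(n);
  order.reserve(n); rec.reserve(n);

  // nodes with no positive weight to anyone never join the walk
  int nActive = 0;
  std::vector<int> isolated;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) s += W(i, j);
    if (s > 0.0) { ++nActive; } else { active[i] = 0; isolated.push_back(i + 1); }
  }
  if (nActive == 0)
    return List::create(_["removal_order"] = IntegerVector(0),
                        _["recurrence_times"] = IntegerVector(0),
                        _["isolated"] = wrap(isolated),
                        _["restarts"] = 0);

  int restarts = 0;
  int cur = sample_uniform_active(active, n, nActive, rng);
  int steps = 1;               // arrivals since the previous removal
  visits[cur] += 1;
  long guard = 0, guard_max = 10L * (long)n * (long)m + 1000L;

  while (nActive > 1 && ++guard < guard_max) {
    int from = cur;
    bool removed = false;
    if (visits[cur] == m) {
      order.push_back(cur + 1);
      rec.push_back(steps);
      active[cur] = 0; --nActive;
      steps = 0;
      removed = true;
      if (nActive == 1) break;
    }
    for (int j = 0; j < n; ++j) row[j] = W(from, j);
    int nxt = sample_row(row, active, n, from, rng);
    if (nxt < 0) {
      // stranded: no remaining positive-weight neighbor; uniform restart
      ++restarts;
      if (!removed && nActive > 1) {
        // exclude the current node so the restart actually moves
        active[cur] = 0;
        nxt = sample_uniform_active(active, n, nActive - 1, rng);
        active[cur] = 1;
      } else {
        nxt = sample_uniform_active(active, n, nActive, rng);
      }
    }
    cur = nxt;
    ++steps;
    visits[cur] += 1;
  }

  // the surviving node closes the record
  for (int j = 0; j < n; ++j)
    if (active[j]) {
      order.push_back(j + 1);
      rec.push_back(steps > 0 ? steps : 1);
      break;
    }

  return List::create(_["removal_order"] = wrap(order),
                      _["recurrence_times"] = wrap(rec),
                      _["isolated"] = wrap(isolated),
                      _["restarts"] = restarts);
}
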