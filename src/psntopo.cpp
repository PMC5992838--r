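#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Deterministic 64-bit RNG (splitmix64 seeded xorshift) so walk corpora and
// embeddings are bit-identical across platforms for a given seed.
namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    // splitmix64 scramble of the seed
    s = seed + 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    s = x;
    return x;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// sample an index proportional to the (non-negative) entries of w[0..n)
int sample_prop(const std::vector<double>& w, double total, Rng& rng) {
  double u = rng.unif() * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u < acc) return i;
  }
  for (int i = n - 1; i >= 0; --i) if (w[i] > 0) return i;
  return 0;
}

} // namespace

// Second-order biased random walks (node2vec). W is the dense symmetric
// weight matrix (zero = no edge). Returns a (n_nodes * walks_per_node) x
// walk_length integer matrix of 1-based node indices; unused tail positions
// (isolated start nodes) are 0.
// [[Rcpp::export(name = ".cpp_node2vec_walks")]]
IntegerMatrix cpp_node2vec_walks(NumericMatrix W, double p, double q,
                                 int walks_per_node, int walk_length,
                                 double seed) {
  int n = W.nrow();
  Rng rng((uint64_t)seed);
  int n_walks = n * walks_per_node;
  IntegerMatrix out(n_walks, walk_length);
  std::vector<double> deg(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) deg[i] += W(i, j);

  std::vector<double> wbuf(n);
  int row = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start, ++row) {
      out(row, 0) = start + 1;
      if (deg[start] <= 0.0) continue;  // isolated: walk of length 1
      // first step: plain weighted transition
      for (int j = 0; j < n; ++j) wbuf[j] = W(start, j);
      int cur = sample_prop(wbuf, deg[start], rng);
      int prev = start;
      out(row, 1) = cur + 1;
      for (int step = 2; step < walk_length; ++step) {
        if (deg[cur] <= 0.0) break;
        double total = 0.0;
        for (int x = 0; x < n; ++x) {
          double w = W(cur, x);
          if (w <= 0.0) { wbuf[x] = 0.0; continue; }
          double bias;
          if (x == prev) bias = 1.0 / p;           // return
          else if (W(prev, x) > 0.0) bias = 1.0;   // stay local
          else bias = 1.0 / q;                     // move outward
          wbuf[x] = w * bias;
          total += wbuf[x];
        }
        if (total <= 0.0) break;
        int nxt = sample_prop(wbuf, total, rng);
        prev = cur;
        cur = nxt;
        out(row, step) = cur + 1;
      }
    }
  }
  return out;
}

// Skip-gram with negative sampling over a walk corpus (word2vec-style),
// single-threaded and deterministic. walks: rows of 1-based node ids, 0 pads.
// Returns n_nodes x d input-embedding matrix.
// [[Rcpp::export(name = ".cpp_sgns_train")]]
NumericMatrix cpp_sgns_train(IntegerMatrix walks, int n_nodes, int d,
                             int window, int negative, int epochs,
                             double alpha, double seed) {
  Rng rng((uint64_t)seed);
  // unigram^0.75 negative-sampling distribution
  std::vector<double> counts(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int r = 0; r < walks.nrow(); ++r)
    for (int c = 0; c < walks.ncol(); ++c) {
      int v = walks(r, c);
      if (v > 0) { counts[v - 1] += 1.0; ++total_tokens; }
    }
  std::vector<double> cum(n_nodes);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) { z += std::pow(counts[i], 0.75); cum[i] = z; }

  std::vector<double> syn0((size_t)n_nodes * d), syn1((size_t)n_nodes * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (rng.unif() - 0.5) / d;

  std::vector<double> grad(d);
  long long trained = 0;
  long long budget = (long long)epochs * total_tokens;
  double min_alpha = alpha * 0.0001;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < walks.nrow(); ++r) {
      for (int c = 0; c < walks.ncol(); ++c) {
        int wv = walks(r, c);
        if (wv == 0) break;
        int center = wv - 1;
        double lr = alpha * (1.0 - (double)trained / (double)(budget + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++trained;
        int b = rng.below(window);  // word2vec-style shrunk window
        for (int o = b - window; o <= window - b; ++o) {
          if (o == 0) continue;
          int cc = c + o;
          if (cc < 0 || cc >= walks.ncol()) continue;
          int ctx = walks(r, cc);
          if (ctx == 0) continue;
          int context = ctx - 1;
          double* v_in = &syn0[(size_t)center * d];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) { target = context; label = 1.0; }
            else {
              double u = rng.unif() * z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * d];
            double dot = 0.0;
            for (int k = 0; k < d; ++k) dot += v_in[k] * v_out[k];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * lr;
            for (int k = 0; k < d; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < d; ++k) v_in[k] += grad[k];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, d);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < d; ++k) out(i, k) = syn0[(size_t)i * d + k];
  return out;
}

// Load centrality on a weighted graph with distances 1/w (Goh's algorithm):
// every node sends one unit packet to every other node along shortest paths;
// at each branching the packet splits equally among the shortest-path
// predecessors. Endpoint packets are not counted. Normalized by
// (n-1)*(n-2).
// [[Rcpp::export(name = ".cpp_load_centrality")]]
NumericVector cpp_load_centrality(NumericMatrix W) {
  int n = W.nrow();
  NumericVector load(n);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n);
  std::vector<bool> done(n);
  std::vector<double> delta(n);
  typedef std::pair<double, int> P;

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), false);
    dist[s] = 0.0;
    std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
    pq.push(P(0.0, s));
    while (!pq.empty()) {
      P top = pq.top(); pq.pop();
      int u = top.second;
      if (done[u]) continue;
      done[u] = true;
      for (int v = 0; v < n; ++v) {
        double w = W(u, v);
        if (w <= 0.0 || done[v]) continue;
        double nd = dist[u] + 1.0 / w;
        if (nd < dist[v] - 1e-12) {
          dist[v] = nd;
          pq.push(P(nd, v));
        }
      }
    }
    // process reachable nodes by decreasing distance
    std::vector<int> order;
    for (int v = 0; v < n; ++v)
      if (v != s && dist[v] < INF) order.push_back(v);
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return dist[a] > dist[b]; });
    for (int v = 0; v < n; ++v) delta[v] = (v == s || dist[v] == INF) ? 0.0 : 1.0;
    for (size_t i = 0; i < order.size(); ++i) {
      int v = order[i];
      std::vector<int> preds;
      for (int u = 0; u < n; ++u) {
        double w = W(u, v);
        if (w <= 0.0) continue;
        if (std::abs(dist[u] + 1.0 / w - dist[v]) < 1e-9) preds.push_back(u);
      }
      if (preds.empty()) continue;
      double share = delta[v] / (double)preds.size();
      for (size_t j = 0; j < preds.size(); ++j)
        if (preds[j] != s) delta[preds[j]] += share;
    }
    for (int v = 0; v < n; ++v)
      if (v != s && dist[v] < INF) load[v] += delta[v] - 1.0;  // exclude own packet
  }
  if (n > 2)
    for (int v = 0; v < n; ++v) load[v] /= (double)(n - 1) * (double)(n - 2);
  return load;
}
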