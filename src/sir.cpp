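#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time synchronous SIR on a CSR adjacency structure.
// adj: 0-based concatenated neighbour lists; ptr: length n+1 offsets.
// Each step every infected node tries to infect each susceptible
// neighbour with probability beta, then recovers with probability lambda
// (lambda = 1: infectious for exactly one step). Nodes infected in the
// current step only start transmitting in the next one. Returns the
// recovered count once no infected remain. Uses R's RNG stream.
static int outbreak(const IntegerVector& adj, const IntegerVector& ptr,
                    int seed, double beta, double lambda,
                    std::vector<int>& state,
                    std::vector<int>& frontier, std::vector<int>& nxt) {
  std::fill(state.begin(), state.end(), 0); // 0 S, 1 I, 2 R
  frontier.clear();
  frontier.push_back(seed);
  state[seed] = 1;
  int recovered = 0;
  while (!frontier.empty()) {
    nxt.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      int v = frontier[f];
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int u = adj[e];
        if (state[u] == 0 && unif_rand() < beta) {
          state[u] = 1;
          nxt.push_back(u);
        }
      }
    }
    if (lambda >= 1.0) {
      recovered += (int) frontier.size();
      for (size_t f = 0; f < frontier.size(); ++f) state[frontier[f]] = 2;
      frontier.swap(nxt);
    } else {
      std::vector<int> still;
      for (size_t f = 0; f < frontier.size(); ++f) {
        int v = frontier[f];
        if (unif_rand() < lambda) { state[v] = 2; ++recovered; }
        else still.push_back(v);
      }
      still.insert(still.end(), nxt.begin(), nxt.end());
      frontier.swap(still);
    }
  }
  return recovered;
}

// [[Rcpp::export]]
int sir_outbreak_cpp(IntegerVector adj, IntegerVector ptr, int seed,
                     double beta, double lambda) {
  int n = ptr.size() - 1;
  std::vector<int> state(n), frontier, nxt;
  return outbreak(adj, ptr, seed, beta, lambda, state, frontier, nxt);
}

// Mean recovered count per seed node over `realizations` independent runs.
// Loop order is realization-major, node-minor: each realization runs one
// outbreak from every node in index order.
// [[Rcpp::export]]
NumericVector sir_influence_cpp(IntegerVector adj, IntegerVector ptr,
                                double beta, double lambda,
                                int realizations) {
  int n = ptr.size() - 1;
  NumericVector total(n);
  std::vector<int> state(n), frontier, nxt;
  for (int r = 0; r < realizations; ++r) {
    for (int s = 0; s < n; ++s)
      total[s] += outbreak(adj, ptr, s, beta, lambda, state, frontier, nxt);
    if (r % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return total / (double) realizations;
}
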