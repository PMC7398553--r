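#include <Rcpp.h>
using namespace Rcpp;

// Event-driven jump-chain simulation of the Markovian SIR model.
// States: 0 = S, 1 = I, 2 = R.  At each step an event is drawn with
// probability beta/(beta*M_SI + N_I) per susceptible-infectious edge
// (infection) and 1/(beta*M_SI + N_I) per infectious node (recovery).
// Only the final outbreak size (number of recovered nodes) is recorded;
// waiting times never matter for it, so they are not sampled.
//
// Uses R's RNG (unif_rand) so that set.seed() in R controls the stream.

// [[Rcpp::export]]
IntegerVector gillespie_runs_cpp(int n, IntegerMatrix edges, int seed,
                                 double beta, int n_runs) {
  const int m = edges.nrow();
  IntegerVector out(n_runs);
  std::vector<int> state(n);
  std::vector<int> si_target; // susceptible endpoint per SI edge
  si_target.reserve(m);
  RNGScope scope;
  for (int run = 0; run < n_runs; ++run) {
    std::fill(state.begin(), state.end(), 0);
    state[seed - 1] = 1;
    int n_i = 1, n_r = 0;
    while (n_i > 0) {
      // collect SI edges and infectious nodes
      int m_si = 0;
      si_target.clear();
      for (int e = 0; e < m; ++e) {
        const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        if (state[a] == 0 && state[b] == 1) si_target.push_back(a);
        else if (state[a] == 1 && state[b] == 0) si_target.push_back(b);
      }
      m_si = (int)si_target.size();
      const double total = beta * m_si + n_i;
      const double u = unif_rand() * total;
      if (u < beta * m_si) {
        // infection across a uniformly chosen SI edge
        int e = (int)(u / beta);
        if (e >= m_si) e = m_si - 1;
        state[si_target[e]] = 1;
        ++n_i;
      } else {
        // recovery of a uniformly chosen infectious node
        int pick = (int)((u - beta * m_si) / 1.0);
        if (pick >= n_i) pick = n_i - 1;
        int count = 0;
        for (int v = 0; v < n; ++v) {
          if (state[v] == 1) {
            if (count == pick) { state[v] = 2; break; }
            ++count;
          }
        }
        --n_i;
        ++n_r;
      }
    }
    out[run] = n_r;
  }
  return out;
}
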