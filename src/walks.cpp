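#include <Rcpp.h>
using namespace Rcpp;

// Lazy-teleporting random walks on a directed cluster graph.
//
// Per step, with probability (1 - alpha) the walker teleports uniformly; else
// with probability (1 - x) it stays put; else it moves to a neighbour drawn
// from the row of the (forward-biased) transition matrix. Every step's end
// position counts as a visit; teleport arrivals count. Uses R's RNG so runs
// are reproducible under set.seed().
//
// cumP:   n x n row-wise cumulative transition probabilities
// rowTot: per-node total outgoing weight (0 marks a dead end)
// stop_at_terminal: end a walk on first arrival at any terminal node
// stop_when_covered: end a walk once every node has been visited
// [[Rcpp::export]]
List simulate_walks_cpp(NumericMatrix cumP, NumericVector rowTot, int root,
                        int n_walks, int max_steps, double x, double alpha,
                        IntegerVector terminals, bool stop_at_terminal,
                        bool stop_when_covered) {
  const int n = cumP.nrow();
  IntegerMatrix first_visit(n_walks, n);
  NumericMatrix visits(n_walks, n);
  IntegerVector end_state(n_walks, -1);
  std::vector<char> is_term(n, 0);
  for (int k = 0; k < terminals.size(); ++k) is_term[terminals[k]] = 1;
  std::fill(first_visit.begin(), first_visit.end(), -1);

  for (int w = 0; w < n_walks; ++w) {
    int cur = root;
    int covered = 1;
    first_visit(w, cur) = 0;
    visits(w, cur) += 1.0;
    if (stop_at_terminal && is_term[cur]) { end_state[w] = cur; continue; }
    for (int step = 1; step <= max_steps; ++step) {
      int nxt;
      if (unif_rand() > alpha) {               // teleport
        nxt = (int)(unif_rand() * n);
        if (nxt >= n) nxt = n - 1;
      } else if (unif_rand() > x) {            // lazy
        nxt = cur;
      } else {                                 // graph move
        if (rowTot[cur] <= 0.0) {
          if (x >= 1.0 && alpha >= 1.0) break; // stuck for good: walk ends
          nxt = cur;
        } else {
          double r = unif_rand();
          int j = 0;
          while (j < n - 1 && cumP(cur, j) < r) ++j;
          nxt = j;
        }
      }
      cur = nxt;
      visits(w, cur) += 1.0;
      if (first_visit(w, cur) < 0) { first_visit(w, cur) = step; ++covered; }
      if (stop_at_terminal && is_term[cur]) { end_state[w] = cur; break; }
      if (stop_when_covered && covered == n) break;
    }
  }
  return List::create(_["first_visit"] = first_visit,
                      _["visits"] = visits,
                      _["end_state"] = end_state);
}
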