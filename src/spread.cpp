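#include <Rcpp.h>
using namespace Rcpp;

// Perfect-transmission reach on a time-ordered event sequence.
//
// Events must already be sorted chronologically; simultaneous events are
// processed in stored order, so infection acquired at an event is
// transmissible at any later-processed event but never retro-propagates.
// Node and event indices are 1-based.

// First infection event per node: the index of the event at which the node
// becomes infected (NA if never reached; the seed itself stays NA).
// [[Rcpp::export]]
IntegerVector reach_first_event(IntegerVector donor, IntegerVector receiver,
                                int n_nodes, int seed, bool both) {
  int m = donor.size();
  IntegerVector first(n_nodes, NA_INTEGER);
  std::vector<char> inf(n_nodes, 0);
  if (seed < 1 || seed > n_nodes) stop("seed index out of range");
  inf[seed - 1] = 1;
  for (int e = 0; e < m; ++e) {
    int d = donor[e] - 1, r = receiver[e] - 1;
    if (inf[d]) {
      if (!inf[r]) { inf[r] = 1; first[r] = e + 1; }
    } else if (both && inf[r]) {
      inf[d] = 1;
      first[d] = e + 1;
    }
  }
  return first;
}

// Number of nodes reached (seed excluded) for each seed in `seeds`.
// [[Rcpp::export]]
IntegerVector reach_counts(IntegerVector donor, IntegerVector receiver,
                           int n_nodes, IntegerVector seeds, bool both) {
  int m = donor.size(), k = seeds.size();
  IntegerVector out(k);
  std::vector<char> inf(n_nodes);
  for (int s = 0; s < k; ++s) {
    if (seeds[s] < 1 || seeds[s] > n_nodes) stop("seed index out of range");
    std::fill(inf.begin(), inf.end(), 0);
    inf[seeds[s] - 1] = 1;
    int cnt = 0;
    for (int e = 0; e < m; ++e) {
      int d = donor[e] - 1, r = receiver[e] - 1;
      if (inf[d]) {
        if (!inf[r]) { inf[r] = 1; ++cnt; }
      } else if (both && inf[r]) {
        inf[d] = 1;
        ++cnt;
      }
    }
    out[s] = cnt;
  }
  return out;
}
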