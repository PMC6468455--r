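#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Base-pair maximization over nested structures (Watson-Crick + G:U wobble),
// with a minimum hairpin loop size. Traceback is deterministic: whenever the
// optimum is attainable by pairing position i, i is paired with the smallest
// admissible partner j; otherwise i is left unpaired.

static inline bool pairable(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default: return false;
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  if (n == 0) {
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["score"] = 0);
  }
  // F[i][j]: max pairs in seq[i..j], 0-based inclusive, stored as flat vector.
  std::vector<int> F((size_t) n * n, 0);
  auto at = [&](int i, int j) -> int& { return F[(size_t) i * n + j]; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = at(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!pairable(seq[(size_t) i], seq[(size_t) k])) continue;
        int cand = 1 + (k - i - 1 > min_loop ? at(i + 1, k - 1) : 0) +
                   (k < j ? at(k + 1, j) : 0);
        if (cand > best) best = cand;
      }
      at(i, j) = best;
    }
  }

  std::vector<int> pi, pj;
  std::stack<std::pair<int, int>> todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    while (i < j && j - i > min_loop) {
      int target = at(i, j);
      int chosen = -1;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!pairable(seq[(size_t) i], seq[(size_t) k])) continue;
        int cand = 1 + (k - i - 1 > min_loop ? at(i + 1, k - 1) : 0) +
                   (k < j ? at(k + 1, j) : 0);
        if (cand == target) { chosen = k; break; } // smallest j wins ties
      }
      if (chosen < 0) {
        ++i; // i unpaired
      } else {
        pi.push_back(i + 1); // report 1-based
        pj.push_back(chosen + 1);
        if (chosen < j) todo.push(std::make_pair(chosen + 1, j));
        j = chosen - 1;
        ++i;
      }
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["score"] = n > 1 ? at(0, n - 1) : 0);
}
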