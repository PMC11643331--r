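#include <Rcpp.h>
using namespace Rcpp;

// Randomized backtracking search for a circular type 1 index 1 serially
// balanced sequence over an alphabet of n trial-type codes: every ordered
// pair of codes, self pairs included, occurs exactly once among the n^2
// circular adjacencies.
//
// With `blocked = true` the sequence must additionally decompose into n
// consecutive blocks that are each a permutation of the alphabet.  Since a
// block then contains no repeats, the n self pairs can only sit at block
// junctions, which forces each block to open with the closing code of the
// previous block and all block-final codes to be distinct.  The search walks
// the sequence position by position (Warnsdorff ordering: codes with the
// fewest unused exits first, random tie-break), backtracking across block
// boundaries.  The search is complete: if it unwinds past the first position
// without hitting the iteration cap, no sequence exists and `exhausted` is
// set.  Uses R's RNG so results are reproducible under set.seed().
//
// Returns a 0-based integer sequence of length n^2, or an empty vector on
// failure/exhaustion.
// [[Rcpp::export]]
IntegerVector sbs_search_cpp(int n, bool blocked, double max_iter, int restarts,
                             LogicalVector exhausted) {
  exhausted[0] = false;
  if (n == 1) return IntegerVector::create(0);
  const int N = n * n;
  std::vector<int> s(N);
  std::vector<std::vector<int> > cand(N);
  std::vector<char> used(n * n), self_used(n);
  std::vector<int> outdeg(n);

  for (int r = 0; r < restarts; ++r) {
    std::fill(used.begin(), used.end(), 0);
    std::fill(self_used.begin(), self_used.end(), 0);
    std::vector<std::vector<char> > inb(n, std::vector<char>(n, 0));
    for (int i = 0; i < n; ++i) outdeg[i] = n - 1;

    int start = std::min((int)(unif_rand() * n), n - 1);
    s[0] = start;
    inb[0][start] = 1;
    int pos = 1;
    bool fresh = true;  // candidates at `pos` not yet generated
    double iter = 0;
    bool found = false;

    while (pos >= 1) {
      if (++iter > max_iter) break;
      const int b = pos / n;
      const bool boundary = (pos % n) == 0;
      std::vector<int> &cc = cand[pos];
      if (fresh) {
        cc.clear();
        const int prev = s[pos - 1];
        if (blocked && boundary) {
          // junction: forced self pair
          if (!self_used[prev]) cc.push_back(prev);
        } else {
          for (int k = 0; k < n; ++k) {
            if (blocked) {
              if (inb[b][k]) continue;
              if (used[prev * n + k]) continue;  // k != prev inside a block
            } else {
              if (k == prev) { if (self_used[k]) continue; }
              else if (used[prev * n + k]) continue;
            }
            if (pos == N - 1) {  // closing element: wrap adjacency must be free
              const int first = s[0];
              if (blocked) { if (k != first || self_used[k]) continue; }
              else if (k == first) { if (self_used[k]) continue; }
              else if (used[k * n + first]) continue;
            }
            cc.push_back(k);
          }
          if (cc.size() > 1) {
            // Warnsdorff with random tie-break; sorted worst-first so that
            // pop_back() consumes the most constrained (fewest exits) code.
            std::vector<double> key(cc.size());
            for (size_t i = 0; i < cc.size(); ++i)
              key[i] = outdeg[cc[i]] + unif_rand();
            for (size_t i = 1; i < cc.size(); ++i) {
              int ci = cc[i]; double ki = key[i]; size_t j = i;
              while (j > 0 && key[j - 1] < ki) {
                cc[j] = cc[j - 1]; key[j] = key[j - 1]; --j;
              }
              cc[j] = ci; key[j] = ki;
            }
          }
        }
        fresh = false;
      }
      if (cc.empty()) {  // backtrack: undo the move that placed s[pos-1]... s[pos]
        --pos;
        fresh = false;   // resume the candidate list already open at new pos
        if (pos >= 1) {
          const int sym = s[pos], prev = s[pos - 1];
          if (blocked) inb[pos / n][sym] = 0;
          if (sym == prev && (!blocked || (pos % n) == 0)) {
            self_used[sym] = 0;
          } else {
            used[prev * n + sym] = 0;
            ++outdeg[prev];
          }
        }
        continue;
      }
      const int nxt = cc.back();
      cc.pop_back();
      const int prev = s[pos - 1];
      s[pos] = nxt;
      if (blocked) inb[b][nxt] = 1;
      if (nxt == prev && (!blocked || boundary)) {
        self_used[nxt] = 1;
      } else {
        used[prev * n + nxt] = 1;
        --outdeg[prev];
      }
      if (pos == N - 1) { found = true; break; }
      ++pos;
      fresh = true;
    }
    if (found) return IntegerVector(s.begin(), s.end());
    if (pos < 1 && iter <= max_iter) {  // complete search space enumerated
      exhausted[0] = true;
      return IntegerVector(0);
    }
  }
  return IntegerVector(0);
}
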