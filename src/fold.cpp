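#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weights: GC=3, AU=2, GU(wobble)=1; anything else (incl. N) unpairable.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Base-pair maximization DP (Nussinov) with weighted pairs and a minimum
// hairpin loop of `min_loop` unpaired bases. Traceback is deterministic:
// at each subproblem the 5' base pairs with the smallest admissible partner
// achieving the optimum, otherwise it is left unpaired.
// [[Rcpp::export]]
List fold_nussinov_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  if (n == 0)
    return List::create(_["structure"] = "", _["score"] = 0);
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (!w) continue;
        int left = (k - i - 1 > 0) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        int s = w + left + right;
        if (s > best) best = s;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  std::vector<std::pair<int, int> > todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = M[i][j];
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (!w) continue;
      int left = (k - i - 1 > 0) ? M[i + 1][k - 1] : 0;
      int right = (k < j) ? M[k + 1][j] : 0;
      if (w + left + right == target) {
        db[i] = '(';
        db[k] = ')';
        if (k < j) todo.push_back(std::make_pair(k + 1, j));
        if (k - i - 1 > 0) todo.push_back(std::make_pair(i + 1, k - 1));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push_back(std::make_pair(i + 1, j));
  }
  return List::create(_["structure"] = db, _["score"] = M[0][n - 1]);
}

// Best ungapped identity of each read against a set of decoy sequences:
// max over decoys and all alignment offsets (partial overlaps allowed) of
// matches / read_length, forward strand.
// [[Rcpp::export]]
NumericVector best_identity_cpp(CharacterVector reads, CharacterVector decoys) {
  int nr = reads.size(), nd = decoys.size();
  NumericVector out(nr);
  std::vector<std::string> dec(nd);
  for (int d = 0; d < nd; ++d) dec[d] = as<std::string>(decoys[d]);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int m = rd.size();
    int best = 0;
    for (int d = 0; d < nd && best < m; ++d) {
      const std::string &dc = dec[d];
      int L = dc.size();
      for (int off = -(m - 1); off < L; ++off) {
        int matches = 0;
        int lo = (off < 0) ? -off : 0;
        int hi = (off + m > L) ? (L - off) : m;
        for (int i = lo; i < hi; ++i)
          if (rd[i] == dc[off + i]) ++matches;
        if (matches > best) best = matches;
        if (best == m) break;
      }
    }
    out[r] = m > 0 ? (double)best / m : 0.0;
  }
  return out;
}
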