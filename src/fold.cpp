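#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Pair energies for the built-in secondary-structure model: Watson-Crick
// GC = -3, AT = -2, wobble GT = -1 (arbitrary but fixed energy units);
// anything involving N is unpairable. Minimum hairpin loop = 3 unpaired
// bases, pseudoknot-free.
static inline double pair_energy(char a, char b) {
  if (a > b) std::swap(a, b);
  if (a == 'C' && b == 'G') return -3.0;
  if (a == 'A' && b == 'T') return -2.0;
  if (a == 'G' && b == 'T') return -1.0;
  return 1.0; // sentinel: not pairable
}

static const int MIN_LOOP = 3;

// [[Rcpp::export]]
List cpp_fold_mfe(std::string seq, bool traceback) {
  const int n = (int) seq.size();
  if (n == 0) stop("empty sequence");
  // E[i][j] = min energy of subsequence [i, j], 0-based inclusive
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i + 1][j]; // i unpaired
      // i paired with k (k - i > MIN_LOOP)
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        double w = pair_energy(seq[i], seq[k]);
        if (w > 0.0) continue;
        double inner = (k - i - 1 > MIN_LOOP) ? E[i + 1][k - 1] : 0.0;
        double rest  = (k < j) ? E[k + 1][j] : 0.0;
        double cand = w + inner + rest;
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }
  double mfe = E[0][n - 1];
  std::string db;
  if (traceback) {
    db.assign(n, '.');
    // iterative traceback over the same decomposition
    std::vector<std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (j - i < MIN_LOOP + 1) continue;
      if (E[i][j] == E[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        double w = pair_energy(seq[i], seq[k]);
        if (w > 0.0) continue;
        double inner = (k - i - 1 > MIN_LOOP) ? E[i + 1][k - 1] : 0.0;
        double rest  = (k < j) ? E[k + 1][j] : 0.0;
        if (E[i][j] == w + inner + rest) {
          db[i] = '('; db[k] = ')';
          if (k - i - 1 > MIN_LOOP) stack.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) stack.push_back(std::make_pair(k + 1, j));
          break;
        }
      }
    }
  }
  return List::create(_["mfe"] = mfe,
                      _["structure"] = traceback ? String(db) : String(NA_STRING));
}

// Fold many sequences (original + shuffles) in one call.
// [[Rcpp::export]]
NumericVector cpp_fold_mfe_many(std::vector<std::string> seqs) {
  int m = (int) seqs.size();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    List r = cpp_fold_mfe(seqs[s], false);
    out[s] = as<double>(r["mfe"]);
  }
  return out;
}
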