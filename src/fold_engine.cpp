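#include <Rcpp.h>
#include <vector>
#include <string>

// Maximum base-pairing dynamic program (Nussinov-style) with a minimum
// hairpin loop of 3 unpaired bases.  Pairs are scored 2 (G:C) or 1
// (A:U, G:U); the returned value is the negative of the best score, a
// pseudo-energy in which lower means more stable.

static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 2;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 1;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export]]
double nussinov_mfe_cpp(std::string seq) {
  const int min_loop = 3;
  int n = (int) seq.size();
  if (n == 0) return 0.0;
  for (int i = 0; i < n; ++i) {
    if (seq[i] == 'T') seq[i] = 'U';
    if (seq[i] != 'A' && seq[i] != 'C' && seq[i] != 'G' && seq[i] != 'U')
      Rcpp::stop("sequence must be over {A, C, G, T/U}");
  }
  if (n <= min_loop + 1) return 0.0;

  // M[i*n + j]: best score of seq[i..j]
  std::vector<int> M((size_t) n * n, 0);
  for (int L = min_loop + 1; L < n; ++L) {
    for (int i = 0; i + L < n; ++i) {
      int j = i + L;
      int best = M[(size_t)(i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int s = pair_score(seq[i], seq[k]);
        if (s == 0) continue;
        int inner = M[(size_t)(i + 1) * n + (k - 1)];
        int outer = (k < j) ? M[(size_t)(k + 1) * n + j] : 0;
        if (inner + outer + s > best) best = inner + outer + s;
      }
      M[(size_t) i * n + j] = best;
    }
  }
  return -(double) M[(size_t) 0 * n + (n - 1)];
}
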