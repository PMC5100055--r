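#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Symmetric DUST over sliding windows.
//
// For every window of `window` nt (step 1; the whole sequence if shorter),
// count occurrences c_t of each overlapping ACGT triplet (triplets touching
// an ambiguous base are skipped) and score the window
//   S = 10 * sum_t c_t (c_t - 1) / 2 / (m - 1)
// where m is the number of counted triplets. Every position covered by a
// window with S > level is low-complexity; intervals separated by <= linker
// positions are merged. Returns a logical mask over positions.
// [[Rcpp::export]]
LogicalVector dust_mask_core(std::string seq, int window, double level,
                             int linker) {
  const int n = (int) seq.size();
  LogicalVector mask(n);
  if (n < 3) return mask;
  const int w = std::min(window, n);

  std::vector<int> tri(n - 2, -1);
  for (int i = 0; i + 2 < n; ++i) {
    int a = base_code(seq[i]), b = base_code(seq[i + 1]),
        c = base_code(seq[i + 2]);
    if (a >= 0 && b >= 0 && c >= 0) tri[i] = (a << 4) | (b << 2) | c;
  }

  const int nwin = n - w + 1;
  std::vector<char> hot(nwin, 0);
  std::vector<int> cnt(64, 0);
  long long S = 0;
  int m = 0;
  // window at start ws covers triplet starts ws .. ws + w - 3
  for (int t = 0; t <= w - 3; ++t) {
    int v = tri[t];
    if (v >= 0) { S += cnt[v]; ++cnt[v]; ++m; }
  }
  for (int ws = 0; ws < nwin; ++ws) {
    if (m >= 2 && 10.0 * (double) S / (double) (m - 1) > level) hot[ws] = 1;
    if (ws + 1 < nwin) {
      int out = tri[ws];
      if (out >= 0) { --cnt[out]; S -= cnt[out]; --m; }
      int in = tri[ws + w - 2];  // new last triplet start = (ws+1) + w - 3
      if (in >= 0) { S += cnt[in]; ++cnt[in]; ++m; }
    }
  }

  // collect hot-window coverage intervals, merge across gaps <= linker
  int cur_s = -1, cur_e = -1;
  std::vector<std::pair<int, int> > iv;
  for (int ws = 0; ws < nwin; ++ws) {
    if (!hot[ws]) continue;
    int s = ws, e = ws + w - 1;
    if (cur_s < 0) { cur_s = s; cur_e = e; }
    else if (s <= cur_e + 1 + linker) { if (e > cur_e) cur_e = e; }
    else { iv.push_back(std::make_pair(cur_s, cur_e)); cur_s = s; cur_e = e; }
  }
  if (cur_s >= 0) iv.push_back(std::make_pair(cur_s, cur_e));
  for (size_t i = 0; i < iv.size(); ++i)
    for (int p = iv[i].first; p <= iv[i].second; ++p) mask[p] = true;
  return mask;
}
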