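// Gapless seed-and-extend local alignment over soft-masked contigs.
//
// Seeds are exact seed_k-mers that are fully uppercase ACGT in both
// sequences (soft-masked positions never seed); extension is bidirectional
// gapless x-drop and may run through masked or ambiguous positions
// (ambiguous columns score as mismatches). Per (contig pair, strand,
// diagonal) only the best-scoring alignment is reported; alignments below
// min_score are dropped.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int code_of(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline bool is_seedable(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct Aln {
  int qs, qe, ss, se;  // 0-based inclusive, subject in scan orientation
  int score, matches, len;
};

static void xdrop_extend(const std::vector<int8_t> &q,
                         const std::vector<int8_t> &s, int qp, int sp, int k,
                         int match, int mismatch, int xdrop, Aln &a) {
  const int qlen = (int) q.size(), slen = (int) s.size();
  // right of seed
  int run = 0, best = 0, bestlen = 0;
  for (int i = qp + k, j = sp + k; i < qlen && j < slen; ++i, ++j) {
    run += (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
    if (run > best) { best = run; bestlen = i - (qp + k) + 1; }
    else if (run <= best - xdrop) break;
  }
  const int rbest = best, rlen = bestlen;
  // left of seed
  run = 0; best = 0; bestlen = 0;
  for (int i = qp - 1, j = sp - 1; i >= 0 && j >= 0; --i, --j) {
    run += (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
    if (run > best) { best = run; bestlen = qp - i; }
    else if (run <= best - xdrop) break;
  }
  a.qs = qp - bestlen;
  a.qe = qp + k - 1 + rlen;
  a.ss = sp - bestlen;
  a.se = sp + k - 1 + rlen;
  a.score = k * match + best + rbest;
  a.len = a.qe - a.qs + 1;
  int m = 0;
  for (int i = a.qs, j = a.ss; i <= a.qe; ++i, ++j)
    if (q[i] < 4 && q[i] == s[j]) ++m;
  a.matches = m;
}

// [[Rcpp::export]]
DataFrame all_vs_all_core(CharacterVector seqs, IntegerVector project,
                          int seed_k, int match, int mismatch, int xdrop,
                          int min_score) {
  const int N = seqs.size();
  const uint32_t kmask =
      (seed_k >= 16) ? 0xffffffffu : ((1u << (2 * seed_k)) - 1u);

  std::vector<std::vector<int8_t> > code(N);
  std::vector<std::string> raw(N);
  for (int i = 0; i < N; ++i) {
    raw[i] = as<std::string>(seqs[i]);
    code[i].resize(raw[i].size());
    for (size_t p = 0; p < raw[i].size(); ++p)
      code[i][p] = (int8_t) code_of(raw[i][p]);
  }

  // index of seedable forward k-mers over all contigs
  typedef std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > Idx;
  Idx idx;
  for (int i = 0; i < N; ++i) {
    uint32_t key = 0;
    int run = 0;
    const std::string &s = raw[i];
    for (size_t p = 0; p < s.size(); ++p) {
      if (is_seedable(s[p])) {
        key = ((key << 2) | (uint32_t) code[i][p]) & kmask;
        if (++run >= seed_k)
          idx[key].push_back(std::make_pair(i, (int) p - seed_k + 1));
      } else {
        run = 0;
      }
    }
  }

  std::vector<int> r_qi, r_sj, r_len, r_score, r_match;
  std::vector<int> r_qs, r_qe, r_ss, r_se;
  std::vector<char> r_strand;

  std::vector<int8_t> sc;
  std::vector<char> sup;
  for (int j = 0; j < N; ++j) {
    const int slen = (int) raw[j].size();
    for (int strand = 0; strand < 2; ++strand) {
      // subject in scan orientation
      sc.resize(slen);
      sup.resize(slen);
      if (strand == 0) {
        for (int p = 0; p < slen; ++p) {
          sc[p] = code[j][p];
          sup[p] = is_seedable(raw[j][p]);
        }
      } else {
        for (int p = 0; p < slen; ++p) {
          char c0 = raw[j][slen - 1 - p];
          int v = code[j][slen - 1 - p];
          sc[p] = (int8_t) (v < 4 ? 3 - v : 4);
          sup[p] = is_seedable(c0);
        }
      }
      // gather seeds per (query contig, diagonal)
      std::unordered_map<uint64_t, std::vector<int> > seeds;
      uint32_t key = 0;
      int run = 0;
      for (int p = 0; p < slen; ++p) {
        if (sup[p]) {
          key = ((key << 2) | (uint32_t) sc[p]) & kmask;
          if (++run >= seed_k) {
            int sp = p - seed_k + 1;
            Idx::const_iterator it = idx.find(key);
            if (it == idx.end()) continue;
            const std::vector<std::pair<int, int> > &occ = it->second;
            for (size_t o = 0; o < occ.size(); ++o) {
              const int qi = occ[o].first;
              if (qi >= j || project[qi] == project[j]) continue;
              const uint64_t dk = ((uint64_t) qi << 32) |
                  (uint64_t) (uint32_t) (occ[o].second - sp + slen);
              seeds[dk].push_back(sp);
            }
          }
        } else {
          run = 0;
        }
      }
      // extend once per diagonal region, keep best per diagonal
      for (std::unordered_map<uint64_t, std::vector<int> >::iterator it =
               seeds.begin();
           it != seeds.end(); ++it) {
        const int qi = (int) (it->first >> 32);
        const int diag = (int) (uint32_t) (it->first & 0xffffffffu) - slen;
        std::vector<int> &sps = it->second;
        int covered = -1;
        Aln best;
        best.score = -1;
        for (size_t u = 0; u < sps.size(); ++u) {
          const int sp = sps[u];
          if (sp + seed_k - 1 <= covered) continue;
          Aln a;
          xdrop_extend(code[qi], sc, sp + diag, sp, seed_k, match, mismatch,
                       xdrop, a);
          if (a.se > covered) covered = a.se;
          if (a.score > best.score) best = a;
        }
        if (best.score >= min_score) {
          r_qi.push_back(qi + 1);
          r_sj.push_back(j + 1);
          r_len.push_back(best.len);
          r_score.push_back(best.score);
          r_match.push_back(best.matches);
          r_qs.push_back(best.qs + 1);
          r_qe.push_back(best.qe + 1);
          if (strand == 0) {
            r_ss.push_back(best.ss + 1);
            r_se.push_back(best.se + 1);
            r_strand.push_back('+');
          } else {
            r_ss.push_back(slen - best.se);
            r_se.push_back(slen - best.ss);
            r_strand.push_back('-');
          }
        }
      }
    }
  }

  const int M = (int) r_qi.size();
  NumericVector pid(M);
  CharacterVector str(M);
  for (int i = 0; i < M; ++i) {
    pid[i] = 100.0 * (double) r_match[i] / (double) r_len[i];
    str[i] = (r_strand[i] == '+') ? "+" : "-";
  }
  return DataFrame::create(
      _["q_idx"] = wrap(r_qi), _["s_idx"] = wrap(r_sj), _["pident"] = pid,
      _["aln_len"] = wrap(r_len), _["matches"] = wrap(r_match),
      _["score"] = wrap(r_score), _["q_start"] = wrap(r_qs),
      _["q_end"] = wrap(r_qe), _["s_start"] = wrap(r_ss),
      _["s_end"] = wrap(r_se), _["strand"] = str,
      _["stringsAsFactors"] = false);
}
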