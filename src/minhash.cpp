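#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cstdio>

using namespace Rcpp;

// FNV-1a 64-bit over the canonical (strand-min) k-mer string. Offset basis and
// prime are the standard FNV constants; no extra seed, so sketches are
// bit-stable across runs and platforms.
static inline uint64_t fnv1a64(const char *s, int n) {
  uint64_t h = 14695981039346656037ULL;
  for (int i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string hex64(uint64_t v) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
  return std::string(buf);
}

// Distinct canonical k-mer hashes of one sequence. If s > 0 only the s
// smallest are returned; s <= 0 returns the full set. Hashes come back as
// 16-digit zero-padded hex strings so lexicographic order equals uint64 order.
// K-mers containing letters outside {A,C,G,T} are skipped.
// [[Rcpp::export(name = ".cpp_kmer_hashes")]]
CharacterVector cpp_kmer_hashes(std::string seq, int k, int s) {
  int n = (int)seq.size();
  if (n < k) return CharacterVector(0);
  std::unordered_set<uint64_t> seen;
  std::string rc(k, 'N');
  for (int i = 0; i + k <= n; ++i) {
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = seq[i + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (!ok) continue;
    for (int j = 0; j < k; ++j) rc[k - 1 - j] = complement(seq[i + j]);
    // canonical = lexicographically smaller strand
    int cmp = seq.compare(i, k, rc);
    uint64_t h = (cmp <= 0) ? fnv1a64(seq.data() + i, k) : fnv1a64(rc.data(), k);
    seen.insert(h);
  }
  std::vector<uint64_t> v(seen.begin(), seen.end());
  std::sort(v.begin(), v.end());
  if (s > 0 && (int)v.size() > s) v.resize(s);
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = hex64(v[i]);
  return out;
}

// Best seed diagonal of `fragment` against `subject`: exact k-mer matches
// sampled every `step` positions vote for subject_start = subject_pos -
// fragment_pos. Returns c(best_start, votes); votes == 0 means no seed hit.
// [[Rcpp::export(name = ".cpp_seed_diagonal")]]
IntegerVector cpp_seed_diagonal(std::string fragment, std::string subject,
                                int k, int step) {
  int nf = (int)fragment.size(), ns = (int)subject.size();
  IntegerVector out(2);
  out[0] = NA_INTEGER; out[1] = 0;
  if (nf < k || ns < k) return out;
  std::unordered_map<uint64_t, std::vector<int> > idx;
  for (int i = 0; i + k <= ns; ++i) {
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = subject[i + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (ok) idx[fnv1a64(subject.data() + i, k)].push_back(i);
  }
  std::unordered_map<int, int> votes;
  for (int i = 0; i + k <= nf; i += step) {
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = fragment[i + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<int> >::iterator it =
      idx.find(fnv1a64(fragment.data() + i, k));
    if (it == idx.end()) continue;
    for (size_t m = 0; m < it->second.size(); ++m)
      votes[it->second[m] - i] += 1;
  }
  int best = NA_INTEGER, bestv = 0;
  for (std::unordered_map<int, int>::iterator it = votes.begin();
       it != votes.end(); ++it) {
    if (it->second > bestv ||
        (it->second == bestv && best != NA_INTEGER && it->first < best)) {
      bestv = it->second; best = it->first;
    }
  }
  out[0] = best; out[1] = bestv;
  return out;
}

// End-gap-free global (overlap) alignment with affine gaps, returning
// c(nmatch, columns, query_aligned, score). Terminal gap runs are free and
// excluded from the column count. Scores: match/mismatch/gap_open(+extend on
// first gap base)/gap_extend; any letter pairing involving N scores as a
// mismatch.
// [[Rcpp::export(name = ".cpp_overlap_identity")]]
IntegerVector cpp_overlap_identity(std::string a, std::string b,
                                   int match = 1, int mismatch = -1,
                                   int gap_open = -2, int gap_extend = -1) {
  int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  // DP over three states: M (diagonal), X (gap in b / consume a), Y (gap in a)
  std::vector<int> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
    Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
    tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);
  #define IDX(i, j) ((i) * (m + 1) + (j))
  M[IDX(0, 0)] = 0;
  // free end gaps: first row/col at zero cost, tracked in X/Y with flag 9
  for (int i = 1; i <= n; ++i) { X[IDX(i, 0)] = 0; tbX[IDX(i, 0)] = 9; }
  for (int j = 1; j <= m; ++j) { Y[IDX(0, j)] = 0; tbY[IDX(0, j)] = 9; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      int s = (ca == cb && ca != 'N') ? match : mismatch;
      int bm = M[IDX(i - 1, j - 1)], bx = X[IDX(i - 1, j - 1)],
        by = Y[IDX(i - 1, j - 1)];
      int best = bm; unsigned char t = 1;
      if (bx > best) { best = bx; t = 2; }
      if (by > best) { best = by; t = 3; }
      M[IDX(i, j)] = best + s; tbM[IDX(i, j)] = t;
      // X: gap in b (consume a[i-1])
      int xo = M[IDX(i - 1, j)] + gap_open + gap_extend;
      int xe = X[IDX(i - 1, j)] + gap_extend;
      if (tbX[IDX(i - 1, j)] == 9) xe = X[IDX(i - 1, j)]; // still in free lead-in? no: lead-in only at j==0
      if (xo >= xe) { X[IDX(i, j)] = xo; tbX[IDX(i, j)] = 1; }
      else { X[IDX(i, j)] = xe; tbX[IDX(i, j)] = 2; }
      // Y: gap in a (consume b[j-1])
      int yo = M[IDX(i, j - 1)] + gap_open + gap_extend;
      int ye = Y[IDX(i, j - 1)] + gap_extend;
      if (yo >= ye) { Y[IDX(i, j)] = yo; tbY[IDX(i, j)] = 1; }
      else { Y[IDX(i, j)] = ye; tbY[IDX(i, j)] = 3; }
    }
  }
  // free terminal gaps: best over last row and last column
  int bi = n, bj = m, bscore = NEG; char bstate = 'M';
  for (int j = 0; j <= m; ++j) {
    int v = std::max(M[IDX(n, j)], std::max(X[IDX(n, j)], Y[IDX(n, j)]));
    if (v > bscore) {
      bscore = v; bi = n; bj = j;
      bstate = (v == M[IDX(n, j)]) ? 'M' : ((v == X[IDX(n, j)]) ? 'X' : 'Y');
    }
  }
  for (int i = 0; i <= n; ++i) {
    int v = std::max(M[IDX(i, m)], std::max(X[IDX(i, m)], Y[IDX(i, m)]));
    if (v > bscore) {
      bscore = v; bi = i; bj = m;
      bstate = (v == M[IDX(i, m)]) ? 'M' : ((v == X[IDX(i, m)]) ? 'X' : 'Y');
    }
  }
  // traceback from (bi, bj) to the free lead-in / origin
  int i = bi, j = bj, nmatchc = 0, cols = 0, qa = 0;
  char st = bstate;
  while (i > 0 || j > 0) {
    if (st == 'M') {
      if (i == 0 || j == 0) break;
      unsigned char t = tbM[IDX(i, j)];
      cols += 1; qa += 1;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') nmatchc += 1;
      --i; --j;
      st = (t == 1) ? 'M' : ((t == 2) ? 'X' : 'Y');
    } else if (st == 'X') {
      unsigned char t = tbX[IDX(i, j)];
      if (t == 9) break; // free leading gap in b
      cols += 1; qa += 1;
      --i;
      st = (t == 1) ? 'M' : 'X';
    } else {
      unsigned char t = tbY[IDX(i, j)];
      if (t == 9) break; // free leading gap in a
      cols += 1;
      --j;
      st = (t == 1) ? 'M' : 'Y';
    }
  }
  #undef IDX
  IntegerVector out(4);
  out[0] = nmatchc; out[1] = cols; out[2] = qa; out[3] = bscore;
  return out;
}

// Seed every fragment against every subject contig (both strands), reusing
// one k-mer index per contig. Returns an integer matrix with one row per
// fragment: contig (1-based, NA if no hit), start (0-based diagonal),
// strand (0 fwd / 1 rc), votes.
// [[Rcpp::export(name = ".cpp_seed_fragments")]]
IntegerMatrix cpp_seed_fragments(CharacterVector fragments,
                                 CharacterVector contigs, int k, int step) {
  int nf = fragments.size(), nc = contigs.size();
  IntegerMatrix out(nf, 4);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int f = 0; f < nf; ++f) out(f, 3) = 0;
  for (int c = 0; c < nc; ++c) {
    std::string subject = as<std::string>(contigs[c]);
    int ns = (int)subject.size();
    if (ns < k) continue;
    std::unordered_map<uint64_t, std::vector<int> > idx;
    for (int i = 0; i + k <= ns; ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char ch = subject[i + j];
        if (ch != 'A' && ch != 'C' && ch != 'G' && ch != 'T') { ok = false; break; }
      }
      if (ok) idx[fnv1a64(subject.data() + i, k)].push_back(i);
    }
    for (int f = 0; f < nf; ++f) {
      std::string frag = as<std::string>(fragments[f]);
      int nfr = (int)frag.size();
      for (int strand = 0; strand < 2; ++strand) {
        std::string fr = frag;
        if (strand == 1) {
          fr.assign(nfr, 'N');
          for (int i = 0; i < nfr; ++i) fr[nfr - 1 - i] = complement(frag[i]);
        }
        std::unordered_map<int, int> votes;
        for (int i = 0; i + k <= nfr; i += step) {
          bool ok = true;
          for (int j = 0; j < k; ++j) {
            char ch = fr[i + j];
            if (ch != 'A' && ch != 'C' && ch != 'G' && ch != 'T') { ok = false; break; }
          }
          if (!ok) continue;
          std::unordered_map<uint64_t, std::vector<int> >::iterator it =
            idx.find(fnv1a64(fr.data() + i, k));
          if (it == idx.end()) continue;
          for (size_t m2 = 0; m2 < it->second.size(); ++m2)
            votes[it->second[m2] - i] += 1;
        }
        for (std::unordered_map<int, int>::iterator it = votes.begin();
             it != votes.end(); ++it) {
          if (it->second > out(f, 3)) {
            out(f, 0) = c + 1; out(f, 1) = it->first;
            out(f, 2) = strand; out(f, 3) = it->second;
          }
        }
      }
    }
  }
  return out;
}
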