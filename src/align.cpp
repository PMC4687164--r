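#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Fit ("glocal") alignment of a read against a candidate reference window
// under unit edit costs: the read is aligned end to end, the window provides
// free leading/trailing sequence. The window is expected to be only slightly
// wider than the read (the seeding stage bounds the diagonal drift), so a
// full dynamic program over the window is the banded alignment in practice.
//
// Returns the minimum edit distance, the 0-based start of the alignment in
// the window, and a CIGAR over {M,I,D} (M covers match and mismatch; I
// consumes read, D consumes window). Ties prefer the leftmost window end and
// a diagonal-first traceback so placement is deterministic.
//
// If allow_suffix_clip is true and the full-read alignment exceeds
// max_edit, the best read prefix whose edit distance stays within
// clip_frac * prefix_length is aligned instead and the remainder reported as
// a trailing S op (min_anchor bases must remain aligned).
// [[Rcpp::export]]
List fit_align_cpp(std::string window, std::string read,
                   int max_edit = -1, bool allow_suffix_clip = false,
                   double clip_frac = 0.1, int min_anchor = 30) {
  const int m = (int) read.size(), n = (int) window.size();
  if (m == 0 || n == 0) stop("fit_align_cpp: empty sequence");
  std::vector<int> D((m + 1) * (n + 1));
  const int W = n + 1;
  for (int j = 0; j <= n; ++j) D[j] = 0;          // free window prefix
  for (int i = 1; i <= m; ++i) D[i * W] = i;
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    int *prev = &D[(i - 1) * W], *cur = &D[i * W];
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (rc == window[j - 1] ? 0 : 1);
      int up = prev[j] + 1;       // I: read base vs gap
      int left = cur[j - 1] + 1;  // D: window base vs gap
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
  }
  // choose read span end: full read, or best prefix if clipping is allowed
  int end_i = m, lead_clip = 0;
  int best_j = 0, best_cost = D[m * W];
  for (int j = 1; j <= n; ++j)
    if (D[m * W + j] < best_cost) { best_cost = D[m * W + j]; best_j = j; }
  if (allow_suffix_clip && max_edit >= 0 && best_cost > max_edit) {
    // choose the aligned prefix maximizing (length - 4 * edit cost), a
    // local-alignment-style rule that anchors the clip at the junction
    // instead of extending raggedly into foreign sequence
    double best_sc = -1; int sc_i = -1, sc_j = 0, sc_cost = 0;
    for (int i = min_anchor; i <= m; ++i) {
      int rb = 0, rc2 = D[i * W];
      for (int j = 1; j <= n; ++j)
        if (D[i * W + j] < rc2) { rc2 = D[i * W + j]; rb = j; }
      double sc = i - 4.0 * rc2;
      if (sc >= best_sc) { best_sc = sc; sc_i = i; sc_j = rb; sc_cost = rc2; }
    }
    if (sc_i < m && sc_i >= min_anchor &&
        sc_cost <= (int) std::ceil(clip_frac * sc_i)) {
      end_i = sc_i; best_cost = sc_cost; best_j = sc_j;
    } else {
      return List::create(_["edit"] = best_cost, _["start"] = best_j,
                          _["cigar"] = CharacterVector::create(NA_STRING),
                          _["clipped"] = 0);
    }
  }
  // traceback (diagonal, then I, then D)
  std::vector<std::pair<char, int> > ops;
  int i = end_i, j = best_j;
  while (i > 0) {
    if (j > 0 && D[i * W + j] == D[(i - 1) * W + j - 1] +
        (read[i - 1] == window[j - 1] ? 0 : 1)) {
      if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
      else ops.push_back(std::make_pair('M', 1));
      --i; --j;
    } else if (D[i * W + j] == D[(i - 1) * W + j] + 1) {
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
      --i;
    } else {
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back(std::make_pair('D', 1));
      --j;
    }
  }
  lead_clip = 0; // read always fully consumed on the left here
  std::string cig;
  for (int t = (int) ops.size() - 1; t >= 0; --t)
    cig += std::to_string(ops[t].second) + ops[t].first;
  int clipped = m - end_i;
  if (clipped > 0) cig += std::to_string(clipped) + "S";
  return List::create(_["edit"] = best_cost, _["start"] = j,
                      _["cigar"] = cig, _["clipped"] = clipped);
}

static int base_row(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return 4;
  }
}

// Pileup accumulator. Walks every alignment's CIGAR once and fills
//  - counts: 5 x L matrix of base observations (rows A,C,G,T,N),
//  - del:    reads spanning a column with a deleted base,
//  - clip:   soft-clip events anchored at the adjacent aligned column,
//  - insertions keyed by (anchor column, inserted string); anchors are the
//    0-based reference column the insertion follows.
// Positions wrap modulo L on circular references; on linear references an
// alignment running past the end is a contract error.
// [[Rcpp::export]]
List pileup_cpp(int ref_len, IntegerVector ref_start, CharacterVector cigar,
                CharacterVector seq, bool circular = false) {
  const int L = ref_len;
  IntegerMatrix counts(5, L);
  IntegerVector del(L), clip(L);
  std::map<std::pair<int, std::string>, int> ins;
  const int n = ref_start.size();
  for (int r = 0; r < n; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    long refpos = ref_start[r];
    size_t readpos = 0, p = 0;
    bool at_start = true;
    while (p < cg.size()) {
      size_t q = p;
      int len = 0;
      while (q < cg.size() && cg[q] >= '0' && cg[q] <= '9') {
        len = len * 10 + (cg[q] - '0');
        ++q;
      }
      if (q == p || q >= cg.size()) stop("malformed CIGAR: %s", cg);
      char op = cg[q];
      p = q + 1;
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          long pos = refpos + t;
          if (circular) pos %= L;
          else if (pos >= L) stop("alignment overruns linear reference end");
          if (readpos + t >= sq.size()) stop("CIGAR consumes more read than present");
          counts(base_row(sq[readpos + t]), (int) pos)++;
        }
        refpos += len; readpos += len; at_start = false;
      } else if (op == 'I') {
        long anchor = refpos - 1;
        if (circular && anchor < 0) anchor += L;
        if (anchor >= 0) {
          std::string allele = sq.substr(readpos, len);
          ins[std::make_pair((int) anchor, allele)]++;
        }
        readpos += len; at_start = false;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          long pos = refpos + t;
          if (circular) pos %= L;
          else if (pos >= L) stop("alignment overruns linear reference end");
          del[(int) pos]++;
        }
        refpos += len; at_start = false;
      } else if (op == 'S') {
        long anchor = at_start ? refpos : refpos - 1;
        if (circular) anchor = ((anchor % L) + L) % L;
        if (anchor >= 0 && anchor < L) clip[(int) anchor]++;
        readpos += len;
      } else {
        stop("unsupported CIGAR op '%c'", op);
      }
    }
  }
  const size_t k = ins.size();
  IntegerVector ipos(k), icount(k);
  CharacterVector iallele(k);
  size_t t = 0;
  for (std::map<std::pair<int, std::string>, int>::iterator it = ins.begin();
       it != ins.end(); ++it, ++t) {
    ipos[t] = it->first.first;
    iallele[t] = it->first.second;
    icount[t] = it->second;
  }
  return List::create(_["counts"] = counts, _["del"] = del, _["clip"] = clip,
                      _["ins_pos"] = ipos, _["ins_allele"] = iallele,
                      _["ins_count"] = icount);
}
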