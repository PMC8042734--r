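// Alignment core: k-mer seeded glocal read aligner, exhaustive DP oracle,
// local aligner for assembly annotation, and a pileup engine.
//
// Scoring (shared by aligner and oracle): match +1, mismatch -1, affine gaps
// costing GAP_OPEN + GAP_EXT * (len - 1), and a flat LONG_DEL cost for long
// reference gaps so reads spanning large internal TE deletions still align
// contiguously (the flat cost only wins for deletions longer than
// LONG_DEL - GAP_OPEN + 1 bases).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP_OPEN = 4;   // total cost of a length-1 gap
static const int GAP_EXT = 1;
static const int LONG_DEL = 25;  // flat cost of an arbitrarily long deletion
static const int NEG = -1000000000;

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// Apply planted substitutions: at each 1-based position, replace the base by
// the one `offset` steps away in the cycle A->C->G->T (offset in 1..3), so a
// substitution never reproduces the original base.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, List positions, List offsets) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    IntegerVector pos = positions[i];
    IntegerVector off = offsets[i];
    for (int j = 0; j < pos.size(); ++j) {
      int p = pos[j] - 1;
      if (p < 0 || p >= (int)s.size()) stop("substitution position out of range");
      int b;
      switch (s[p]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = 0;
      }
      s[p] = BASES[(b + off[j]) % 4];
    }
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Glocal alignment of a read against a reference column window [lo, hi).
// The full read must be consumed; reference start/end are free.  Returns the
// best score, co-optimal end columns, and (optionally) a traceback.

struct GlocalResult {
  int score = NEG;
  int start = -1, end = -1;          // 0-based half-open on the reference
  std::string cigar;                 // ops over {=, X, I, D}
  int nX = 0, nI = 0, nD = 0;
  std::vector<int> co_end;           // absolute end columns achieving `score`
  bool valid = false;
};

static void append_op(std::string& cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

static GlocalResult glocal_window(const std::string& rd, const std::string& ref,
                                  int lo, int hi, bool allow_gaps, bool traceback) {
  GlocalResult res;
  const int R = rd.size();
  const int W = hi - lo;
  if (R == 0 || W <= 0) return res;

  if (!allow_gaps) {
    // Ungapped: slide the read over every start in the window.
    int best = NEG;
    std::vector<int> ends;
    int best_start = -1;
    for (int s = lo; s + R <= hi; ++s) {
      int mm = 0;
      for (int i = 0; i < R; ++i) if (rd[i] != ref[s + i]) ++mm;
      int sc = (R - mm) * MATCH + mm * MISMATCH;
      if (sc > best) { best = sc; ends.clear(); ends.push_back(s + R); best_start = s; }
      else if (sc == best) ends.push_back(s + R);
    }
    if (best == NEG) return res;
    res.score = best; res.co_end = ends; res.valid = true;
    res.start = best_start; res.end = best_start + R;
    if (traceback) {
      std::string cig;
      int run = 0; char cur = 0;
      for (int i = 0; i < R; ++i) {
        char op = (rd[i] == ref[best_start + i]) ? '=' : 'X';
        if (op == 'X') ++res.nX;
        if (op == cur) ++run; else { append_op(cig, cur, run); cur = op; run = 1; }
      }
      append_op(cig, cur, run);
      res.cigar = cig;
    }
    return res;
  }

  const int ncol = W + 1;
  std::vector<int> Hprev(ncol), Hcur(ncol), Ecur(ncol), Fprev(ncol), Fcur(ncol);
  // traceback matrices (only allocated when needed)
  std::vector<uint8_t> tbH, tbE, tbF;
  std::vector<int> jcol;
  if (traceback) {
    tbH.assign((size_t)(R + 1) * ncol, 0);
    tbE.assign((size_t)(R + 1) * ncol, 0);
    tbF.assign((size_t)(R + 1) * ncol, 0);
    jcol.assign((size_t)(R + 1) * ncol, 0);
  }
  auto IDX = [ncol](int i, int j) { return (size_t)i * ncol + j; };

  for (int j = 0; j < ncol; ++j) { Hprev[j] = 0; Fprev[j] = NEG; }

  for (int i = 1; i <= R; ++i) {
    // column 0: read prefix consumed with no reference -> leading insertion
    Fcur[0] = std::max(Hprev[0] - GAP_OPEN, Fprev[0] - GAP_EXT);
    if (traceback) tbF[IDX(i, 0)] = (Fprev[0] - GAP_EXT >= Hprev[0] - GAP_OPEN) ? 1 : 0;
    Hcur[0] = Fcur[0];
    if (traceback) tbH[IDX(i, 0)] = 2;
    Ecur[0] = NEG;
    int rowmax = Hcur[0], rowargmax = 0;
    char rb = rd[i - 1];
    for (int j = 1; j < ncol; ++j) {
      int diag = Hprev[j - 1] + ((rb == ref[lo + j - 1]) ? MATCH : MISMATCH);
      int e_open = Hcur[j - 1] - GAP_OPEN;
      int e_ext = Ecur[j - 1] - GAP_EXT;
      int e = std::max(e_open, e_ext);
      int f_open = Hprev[j] - GAP_OPEN;
      int f_ext = Fprev[j] - GAP_EXT;
      int f = std::max(f_open, f_ext);
      int jump = rowmax - LONG_DEL;
      int h = diag; uint8_t tb = 0;
      if (e > h) { h = e; tb = 1; }
      if (f > h) { h = f; tb = 2; }
      if (jump > h) { h = jump; tb = 3; }
      Ecur[j] = e; Fcur[j] = f; Hcur[j] = h;
      if (traceback) {
        tbH[IDX(i, j)] = tb;
        tbE[IDX(i, j)] = (e_ext > e_open) ? 1 : 0;
        tbF[IDX(i, j)] = (f_ext > f_open) ? 1 : 0;
        if (tb == 3) jcol[IDX(i, j)] = rowargmax;
      }
      if (h > rowmax) { rowmax = h; rowargmax = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  int best = NEG;
  for (int j = 0; j < ncol; ++j) if (Hprev[j] > best) best = Hprev[j];
  if (best <= NEG / 2) return res;
  for (int j = 0; j < ncol; ++j) if (Hprev[j] == best) res.co_end.push_back(lo + j);
  res.score = best;
  res.valid = true;

  if (traceback) {
    int j = res.co_end.front() - lo;
    res.end = lo + j;
    int i = R;
    std::vector<std::pair<char, int>> ops;  // reversed
    auto push = [&ops](char op, int len) {
      if (len <= 0) return;
      if (!ops.empty() && ops.back().first == op) ops.back().second += len;
      else ops.emplace_back(op, len);
    };
    while (i > 0) {
      if (j == 0) { push('I', i); res.nI += i; i = 0; break; }
      uint8_t tb = tbH[IDX(i, j)];
      if (tb == 0) {
        char op = (rd[i - 1] == ref[lo + j - 1]) ? '=' : 'X';
        if (op == 'X') ++res.nX;
        push(op, 1);
        --i; --j;
      } else if (tb == 1) {
        int len = 0;
        while (true) {
          ++len;
          bool ext = tbE[IDX(i, j)] != 0;
          --j;
          if (!ext) break;
        }
        res.nD += len; push('D', len);
      } else if (tb == 2) {
        int len = 0;
        while (true) {
          ++len;
          bool ext = tbF[IDX(i, j)] != 0;
          --i;
          if (!ext) break;
          if (i == 0) break;
        }
        res.nI += len; push('I', len);
      } else {
        int j0 = jcol[IDX(i, j)];
        int len = j - j0;
        res.nD += len; push('D', len);
        j = j0;
      }
    }
    res.start = lo + j;
    std::string cig;
    for (auto it = ops.rbegin(); it != ops.rend(); ++it) append_op(cig, it->first, it->second);
    res.cigar = cig;
  } else {
    res.end = res.co_end.front();
  }
  return res;
}

// ---------------------------------------------------------------------------
// Seeded read aligner

struct Candidate {
  int target; int strand;  // 0 = '+', 1 = '-'
  int lo, hi;
  int nseeds;
};

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector refs,
                     int k, double max_div, int mismatch_cap,
                     bool allow_gaps, int pad, int diag_join, int max_cand) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int t = 0; t < nref; ++t) R[t] = as<std::string>(refs[t]);

  // k-mer index over forward reference strands
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int t = 0; t < nref; ++t) {
    const std::string& s = R[t];
    if ((int)s.size() < k) continue;
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b;
      switch (s[p]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[h].push_back({t, p - k + 1});
    }
  }

  const R_xlen_t nreads = reads.size();
  LogicalVector mapped(nreads, false);
  IntegerVector target(nreads, NA_INTEGER), start(nreads, NA_INTEGER),
      end(nreads, NA_INTEGER), score(nreads, NA_INTEGER),
      nmm(nreads, NA_INTEGER), ambiguity(nreads, NA_INTEGER);
  CharacterVector strand(nreads, NA_STRING), cigar(nreads, NA_STRING),
      cotargets(nreads, NA_STRING);

  for (R_xlen_t r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int rl = fwd.size();
    if (rl < k) continue;
    std::string rev = revcomp(fwd);
    const std::string* oriented[2] = {&fwd, &rev};

    std::vector<Candidate> cands;
    for (int st = 0; st < 2; ++st) {
      const std::string& rd = *oriented[st];
      // per-target sorted diagonals
      std::unordered_map<int, std::vector<int>> diags;
      uint64_t h = 0; int run = 0;
      for (int p = 0; p < rl; ++p) {
        int b;
        switch (rd[p]) {
          case 'A': b = 0; break; case 'C': b = 1; break;
          case 'G': b = 2; break; case 'T': b = 3; break;
          default: b = -1;
        }
        if (b < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto it = index.find(h);
          if (it != index.end())
            for (auto& tp : it->second) diags[tp.first].push_back(tp.second - (p - k + 1));
        }
      }
      for (auto& kv : diags) {
        std::vector<int>& d = kv.second;
        std::sort(d.begin(), d.end());
        size_t i0 = 0;
        for (size_t i = 1; i <= d.size(); ++i) {
          if (i == d.size() || d[i] - d[i - 1] > diag_join) {
            int dmin = d[i0], dmax = d[i - 1];
            int reflen = R[kv.first].size();
            int lo = std::max(0, dmin - pad);
            int hi = std::min(reflen, dmax + rl + pad);
            if (hi > lo)
              cands.push_back({kv.first, st, lo, hi, (int)(i - i0)});
            i0 = i;
          }
        }
      }
    }
    if (cands.empty()) continue;

    // merge overlapping windows per (target, strand) to avoid double counting
    std::sort(cands.begin(), cands.end(), [](const Candidate& a, const Candidate& b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.target != b.target) return a.target < b.target;
      return a.lo < b.lo;
    });
    std::vector<Candidate> merged;
    for (auto& c : cands) {
      if (!merged.empty() && merged.back().strand == c.strand &&
          merged.back().target == c.target && c.lo <= merged.back().hi) {
        merged.back().hi = std::max(merged.back().hi, c.hi);
        merged.back().nseeds += c.nseeds;
      } else merged.push_back(c);
    }
    if ((int)merged.size() > max_cand) {
      std::stable_sort(merged.begin(), merged.end(),
                       [](const Candidate& a, const Candidate& b) { return a.nseeds > b.nseeds; });
      merged.resize(max_cand);
      std::sort(merged.begin(), merged.end(), [](const Candidate& a, const Candidate& b) {
        if (a.strand != b.strand) return a.strand < b.strand;
        if (a.target != b.target) return a.target < b.target;
        return a.lo < b.lo;
      });
    }

    int best = NEG;
    std::vector<GlocalResult> results(merged.size());
    for (size_t c = 0; c < merged.size(); ++c) {
      results[c] = glocal_window(*oriented[merged[c].strand], R[merged[c].target],
                                 merged[c].lo, merged[c].hi, allow_gaps, false);
      if (results[c].valid && results[c].score > best) best = results[c].score;
    }
    if (best <= NEG / 2) continue;

    int amb = 0;
    std::vector<int> cot;
    int win = -1;
    for (size_t c = 0; c < merged.size(); ++c) {
      if (!results[c].valid || results[c].score != best) continue;
      amb += (int)results[c].co_end.size();
      cot.push_back(merged[c].target);
      if (win < 0) win = (int)c;
    }
    std::sort(cot.begin(), cot.end());
    cot.erase(std::unique(cot.begin(), cot.end()), cot.end());

    GlocalResult fin = glocal_window(*oriented[merged[win].strand], R[merged[win].target],
                                     merged[win].lo, merged[win].hi, allow_gaps, true);
    int mm = fin.nX + fin.nI;
    bool ok = true;
    if (mismatch_cap >= 0 && mm > mismatch_cap) ok = false;
    if (max_div >= 0 && (double)mm / rl > max_div) ok = false;
    if (!ok) continue;

    mapped[r] = true;
    target[r] = merged[win].target + 1;
    start[r] = fin.start;
    end[r] = fin.end;
    strand[r] = (merged[win].strand == 0) ? "+" : "-";
    score[r] = fin.score;
    cigar[r] = fin.cigar;
    nmm[r] = mm;
    ambiguity[r] = amb;
    std::string cs;
    for (size_t i = 0; i < cot.size(); ++i) {
      if (i) cs += ",";
      cs += std::to_string(cot[i] + 1);
    }
    cotargets[r] = cs;
  }

  return List::create(_["mapped"] = mapped, _["target"] = target, _["start"] = start,
                      _["end"] = end, _["strand"] = strand, _["score"] = score,
                      _["cigar"] = cigar, _["nmm"] = nmm, _["ambiguity"] = ambiguity,
                      _["cotargets"] = cotargets);
}

// ---------------------------------------------------------------------------
// Exhaustive oracle: best glocal score over every target, strand and position
// (no seeding, no windows).  Written independently of the seeded path.

static int oracle_one(const std::string& rd, const std::string& ref) {
  const int R = rd.size(), W = ref.size();
  std::vector<int> Hp(W + 1), Hc(W + 1), Fp(W + 1), Fc(W + 1), E(W + 1);
  for (int j = 0; j <= W; ++j) { Hp[j] = 0; Fp[j] = NEG; }
  for (int i = 1; i <= R; ++i) {
    Fc[0] = std::max(Hp[0] - GAP_OPEN, Fp[0] - GAP_EXT);
    Hc[0] = Fc[0];
    E[0] = NEG;
    int rowmax = Hc[0];
    char rb = rd[i - 1];
    for (int j = 1; j <= W; ++j) {
      int diag = Hp[j - 1] + ((rb == ref[j - 1]) ? MATCH : MISMATCH);
      int e = std::max(Hc[j - 1] - GAP_OPEN, E[j - 1] - GAP_EXT);
      int f = std::max(Hp[j] - GAP_OPEN, Fp[j] - GAP_EXT);
      int h = std::max(std::max(diag, e), std::max(f, rowmax - LONG_DEL));
      E[j] = e; Fc[j] = f; Hc[j] = h;
      if (h > rowmax) rowmax = h;
    }
    std::swap(Hp, Hc);
    std::swap(Fp, Fc);
  }
  int best = NEG;
  for (int j = 0; j <= W; ++j) if (Hp[j] > best) best = Hp[j];
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_oracle_scores(CharacterVector reads, CharacterVector refs) {
  std::vector<std::string> R(refs.size());
  for (R_xlen_t t = 0; t < refs.size(); ++t) R[t] = as<std::string>(refs[t]);
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    int best = NEG;
    for (auto& ref : R) {
      best = std::max(best, oracle_one(fwd, ref));
      best = std::max(best, oracle_one(rev, ref));
    }
    out[r] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment with traceback, for assembly annotation.
// Affine gaps, no long-deletion jump (merging of split hits is handled by the
// caller).  Returns 0-based half-open intervals on both sequences.

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b) {
  const int A = a.size(), B = b.size();
  const int ncol = B + 1;
  std::vector<int> H((size_t)(A + 1) * ncol, 0), E((size_t)(A + 1) * ncol, NEG),
      F((size_t)(A + 1) * ncol, NEG);
  std::vector<uint8_t> tb((size_t)(A + 1) * ncol, 4);  // 4 = stop
  auto IDX = [ncol](int i, int j) { return (size_t)i * ncol + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= A; ++i) {
    for (int j = 1; j <= B; ++j) {
      int diag = H[IDX(i - 1, j - 1)] + ((a[i - 1] == b[j - 1]) ? MATCH : MISMATCH);
      int e = std::max(H[IDX(i, j - 1)] - GAP_OPEN, E[IDX(i, j - 1)] - GAP_EXT);
      int f = std::max(H[IDX(i - 1, j)] - GAP_OPEN, F[IDX(i - 1, j)] - GAP_EXT);
      int h = 0; uint8_t t = 4;
      if (diag > h) { h = diag; t = 0; }
      if (e > h) { h = e; t = 1; }
      if (f > h) { h = f; t = 2; }
      E[IDX(i, j)] = e; F[IDX(i, j)] = f; H[IDX(i, j)] = h; tb[IDX(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, mm = 0, cols = 0, matches = 0;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t t = tb[IDX(i, j)];
      if (t == 4) break;
      if (t == 0) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++matches; else ++mm;
        --i; --j;
      } else if (t == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++cols;
      bool ext = (E[IDX(i, j - 1)] - GAP_EXT) > (H[IDX(i, j - 1)] - GAP_OPEN);
      --j;
      if (!ext) state = 0;
    } else {
      ++cols;
      bool ext = (F[IDX(i - 1, j)] - GAP_EXT) > (H[IDX(i - 1, j)] - GAP_OPEN);
      --i;
      if (!ext) state = 0;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj, _["mismatches"] = mm,
                      _["matches"] = matches, _["columns"] = cols);
}

// Seed clustering for annotation: exact k-mer matches between a query and a
// contig, binned by diagonal; clusters with >= minseeds seeds become
// candidate windows (merged across adjacent bins).

// [[Rcpp::export]]
DataFrame cpp_seed_candidates(std::string contig, std::string query, int k,
                              int binwidth, int minseeds, int pad) {
  std::unordered_map<uint64_t, std::vector<int>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  {
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)contig.size(); ++p) {
      int b;
      switch (contig[p]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[h].push_back(p - k + 1);
    }
  }
  struct Seed { int diag, gp, qp; };
  std::vector<Seed> seeds;
  {
    uint64_t h = 0; int run = 0;
    for (int q = 0; q < (int)query.size(); ++q) {
      int b;
      switch (query[q]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (run + 1 >= k) {
        auto it = index.find(h);
        if (it != index.end()) {
          int qp = q - k + 1;
          for (int gp : it->second) seeds.push_back({gp - qp, gp, qp});
        }
      }
      ++run;
    }
  }
  std::vector<int> glo, ghi, qlo, qhi, nseeds;
  if (!seeds.empty()) {
    // cluster by diagonal, then split clusters on large genome-position gaps
    std::sort(seeds.begin(), seeds.end(),
              [](const Seed& a, const Seed& b) { return a.diag < b.diag; });
    size_t i0 = 0;
    std::vector<std::pair<size_t, size_t>> diag_groups;
    for (size_t i = 1; i <= seeds.size(); ++i) {
      if (i == seeds.size() || seeds[i].diag - seeds[i - 1].diag > binwidth) {
        diag_groups.push_back({i0, i});
        i0 = i;
      }
    }
    for (auto& dg : diag_groups) {
      std::vector<Seed> grp(seeds.begin() + dg.first, seeds.begin() + dg.second);
      std::sort(grp.begin(), grp.end(),
                [](const Seed& a, const Seed& b) { return a.gp < b.gp; });
      size_t j0 = 0;
      for (size_t j = 1; j <= grp.size(); ++j) {
        if (j == grp.size() || grp[j].gp - grp[j - 1].gp > 500) {
          if (j - j0 >= (size_t)minseeds) {
            int gmin = 1 << 30, gmax = -1, qmin = 1 << 30, qmax = -1;
            for (size_t x = j0; x < j; ++x) {
              gmin = std::min(gmin, grp[x].gp); gmax = std::max(gmax, grp[x].gp + k);
              qmin = std::min(qmin, grp[x].qp); qmax = std::max(qmax, grp[x].qp + k);
            }
            glo.push_back(std::max(0, gmin - pad));
            ghi.push_back(std::min((int)contig.size(), gmax + pad));
            qlo.push_back(std::max(0, qmin - pad));
            qhi.push_back(std::min((int)query.size(), qmax + pad));
            nseeds.push_back((int)(j - j0));
          }
          j0 = j;
        }
      }
    }
  }
  return DataFrame::create(_["glo"] = glo, _["ghi"] = ghi, _["qlo"] = qlo,
                           _["qhi"] = qhi, _["nseeds"] = nseeds);
}

// ---------------------------------------------------------------------------
// Pileup: per-position depths and allele counts from cigar strings.

// [[Rcpp::export]]
List cpp_pileup(IntegerVector starts, CharacterVector cigars, CharacterVector seqs,
                IntegerVector ambiguity, int reflen, int arc_min) {
  IntegerVector depth_total(reflen, 0), depth_unique(reflen, 0);
  IntegerMatrix counts(5, reflen);  // rows: A C G T del(small)
  std::vector<int> arc_aln, arc_start, arc_end;
  IntegerVector span_start(starts.size()), span_end(starts.size());

  for (R_xlen_t r = 0; r < starts.size(); ++r) {
    std::string cig = as<std::string>(cigars[r]);
    std::string sq = as<std::string>(seqs[r]);
    int tp = starts[r];   // reference cursor
    int rp = 0;           // read cursor
    bool uniq = ambiguity[r] == 1;
    span_start[r] = tp;
    size_t c = 0;
    while (c < cig.size()) {
      int len = 0;
      while (c < cig.size() && isdigit(cig[c])) { len = len * 10 + (cig[c] - '0'); ++c; }
      if (c >= cig.size()) stop("malformed operation string");
      char op = cig[c++];
      if (op == '=' || op == 'X' || op == 'M') {
        for (int x = 0; x < len; ++x) {
          if (tp >= reflen) stop("alignment beyond consensus bounds");
          ++depth_total[tp];
          if (uniq) ++depth_unique[tp];
          int b;
          switch (sq[rp]) {
            case 'A': b = 0; break; case 'C': b = 1; break;
            case 'G': b = 2; break; case 'T': b = 3; break;
            default: b = -1;
          }
          if (b >= 0) ++counts(b, tp);
          ++tp; ++rp;
        }
      } else if (op == 'I') {
        rp += len;
      } else if (op == 'D') {
        if (tp + len > reflen) stop("alignment beyond consensus bounds");
        if (len >= arc_min) {
          arc_aln.push_back((int)r + 1);
          arc_start.push_back(tp);
          arc_end.push_back(tp + len);
        } else {
          for (int x = 0; x < len; ++x) ++counts(4, tp + x);
        }
        tp += len;
      } else stop("unknown operation in alignment string");
    }
    span_end[r] = tp;
  }
  return List::create(_["depth_total"] = depth_total, _["depth_unique"] = depth_unique,
                      _["counts"] = counts,
                      _["arcs"] = DataFrame::create(_["aln"] = arc_aln,
                                                    _["start"] = arc_start,
                                                    _["end"] = arc_end),
                      _["span_start"] = span_start, _["span_end"] = span_end);
}
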