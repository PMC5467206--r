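#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local (Smith-Waterman) alignment of many reads against one
// reference. A gap of length L costs gap_open + L * gap_extend. 'N' scores 0
// against every base (masked calls must neither help nor hurt).
//
// Deterministic tie-breaking: traceback prefers diagonal > gap-in-read
// (deletion) > gap-in-reference (insertion); inside a gap run extension is
// preferred over re-opening, which left-shifts gaps on the reference. The
// traceback starts at the maximal cell with the smallest reference index,
// then the smallest read index. When both orientations are tried, ties in
// score go to the forward orientation.

namespace {

const int NEG = -1000000000;

inline int encode_base(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;  // N or anything else: masked
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

struct AlnResult {
  int score = 0;
  int ref_start = 0;
  int read_start = 0;
  std::string pattern, subject;
};

struct Aligner {
  std::vector<int> ref_code;
  std::string ref;
  int n;
  int sub[5][5];
  int gap_open, gap_extend;
  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;

  Aligner(const std::string& reference, int match, int mismatch,
          int go, int ge)
      : ref(reference), n(reference.size()), gap_open(go), gap_extend(ge) {
    ref_code.resize(n);
    for (int j = 0; j < n; ++j) ref_code[j] = encode_base(reference[j]);
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < 5; ++b)
        sub[a][b] = (a == 4 || b == 4) ? 0 : (a == b ? match : mismatch);
  }

  AlnResult align(const std::string& read) {
    AlnResult out;
    const int m = read.size();
    if (m == 0) return out;
    const size_t w = n + 1;
    const size_t sz = (size_t)(m + 1) * w;
    if (H.size() < sz) {
      H.resize(sz); E.resize(sz); F.resize(sz);
      tbH.resize(sz); tbE.resize(sz); tbF.resize(sz);
    }
    std::vector<int> read_code(m);
    for (int i = 0; i < m; ++i) read_code[i] = encode_base(read[i]);
    for (size_t j = 0; j < w; ++j) {
      H[j] = 0; E[j] = NEG; F[j] = NEG; tbH[j] = 0;
    }
    int best = 0, bi = 0, bj = 0;
    const int open_cost = gap_open + gap_extend;
    for (int i = 1; i <= m; ++i) {
      int* Hr = &H[(size_t)i * w];
      int* Er = &E[(size_t)i * w];
      int* Fr = &F[(size_t)i * w];
      const int* Hp = &H[(size_t)(i - 1) * w];
      const int* Fp = &F[(size_t)(i - 1) * w];
      unsigned char* tHr = &tbH[(size_t)i * w];
      unsigned char* tEr = &tbE[(size_t)i * w];
      unsigned char* tFr = &tbF[(size_t)i * w];
      Hr[0] = 0; Er[0] = NEG; Fr[0] = NEG; tHr[0] = 0;
      const int* srow = sub[read_code[i - 1]];
      for (int j = 1; j <= n; ++j) {
        int e_open = Hr[j - 1] - open_cost;
        int e_ext  = Er[j - 1] - gap_extend;
        int e; unsigned char te;
        if (e_ext >= e_open) { e = e_ext; te = 1; } else { e = e_open; te = 0; }
        Er[j] = e; tEr[j] = te;
        int f_open = Hp[j] - open_cost;
        int f_ext  = Fp[j] - gap_extend;
        int f; unsigned char tf;
        if (f_ext >= f_open) { f = f_ext; tf = 1; } else { f = f_open; tf = 0; }
        Fr[j] = f; tFr[j] = tf;
        int diag = Hp[j - 1] + srow[ref_code[j - 1]];
        int h = diag; unsigned char tb = 1;
        if (e > h) { h = e; tb = 2; }
        if (f > h) { h = f; tb = 3; }
        if (h <= 0) { h = 0; tb = 0; }
        Hr[j] = h; tHr[j] = tb;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    // traceback
    std::string pat, subj;
    int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (del), 2 = F (ins)
    while (i > 0 || j > 0) {
      const size_t c = (size_t)i * w + j;
      if (state == 0) {
        unsigned char tb = tbH[c];
        if (tb == 0) break;
        if (tb == 1) {
          pat.push_back(read[i - 1]); subj.push_back(ref[j - 1]);
          --i; --j;
        } else if (tb == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        pat.push_back('-'); subj.push_back(ref[j - 1]);
        unsigned char ext = tbE[c];
        --j;
        if (!ext) state = 0;
      } else {
        pat.push_back(read[i - 1]); subj.push_back('-');
        unsigned char ext = tbF[c];
        --i;
        if (!ext) state = 0;
      }
    }
    std::reverse(pat.begin(), pat.end());
    std::reverse(subj.begin(), subj.end());
    out.score = best;
    out.ref_start = j;
    out.read_start = i;
    out.pattern = pat;
    out.subject = subj;
    return out;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sw_align_batch")]]
List sw_align_batch(CharacterVector reads, std::string ref,
                    int match, int mismatch, int gap_open, int gap_extend,
                    bool try_revcomp = false) {
  const int nreads = reads.size();
  Aligner al(ref, match, mismatch, gap_open, gap_extend);

  NumericVector out_score(nreads);
  IntegerVector out_ref_start(nreads);   // 0-based start on reference
  IntegerVector out_read_start(nreads);  // 0-based start on aligned read
  CharacterVector out_pat(nreads);       // gapped read over aligned span
  CharacterVector out_sub(nreads);       // gapped reference over aligned span
  CharacterVector out_strand(nreads);

  std::string rc;
  for (int r = 0; r < nreads; ++r) {
    std::string read = as<std::string>(reads[r]);
    AlnResult res = al.align(read);
    std::string strand = "+";
    if (try_revcomp && !read.empty()) {
      rc.resize(read.size());
      for (size_t k = 0; k < read.size(); ++k)
        rc[k] = comp_base(read[read.size() - 1 - k]);
      AlnResult rev = al.align(rc);
      if (rev.score > res.score) { res = rev; strand = "-"; }
    }
    out_score[r] = res.score;
    if (read.empty()) {
      out_ref_start[r] = NA_INTEGER; out_read_start[r] = NA_INTEGER;
    } else {
      out_ref_start[r] = res.ref_start;
      out_read_start[r] = res.read_start;
    }
    out_pat[r] = res.pattern;
    out_sub[r] = res.subject;
    out_strand[r] = strand;
  }
  return List::create(_["score"] = out_score,
                      _["ref_start"] = out_ref_start,
                      _["read_start"] = out_read_start,
                      _["pattern"] = out_pat,
                      _["subject"] = out_sub,
                      _["strand"] = out_strand);
}
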