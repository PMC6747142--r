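// Banded global alignment with affine gap penalties, used to align
// amplicon reads to their reference at desk scale.  Returns a CIGAR
// string (M/I/D; I = base present in the read but not the reference)
// per read.  The band is centred on the main diagonal shifted by the
// length difference, wide enough for the indels amplicon sequencing of
// NHEJ products actually shows.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// state codes for traceback
enum { ST_M = 0, ST_IX = 1, ST_IY = 2 };  // IX: gap in ref (insertion),
                                          // IY: gap in read (deletion)

// [[Rcpp::export(name = ".nw_align_batch")]]
CharacterVector nw_align_batch(CharacterVector reads, std::string ref,
                               int match = 2, int mismatch = -4,
                               int gap_open = -10, int gap_extend = -1,
                               int band_slack = 30) {
  const int m = (int) ref.size();
  CharacterVector out(reads.size());

  for (int rix = 0; rix < reads.size(); ++rix) {
    std::string read = as<std::string>(reads[rix]);
    const int n = (int) read.size();
    if (n == 0) { out[rix] = NA_STRING; continue; }

    const int delta = m - n;  // ref minus read length
    const int lo_off = std::min(0, delta) - band_slack;
    const int hi_off = std::max(0, delta) + band_slack;
    const int bw = hi_off - lo_off + 1;  // band width in j-i offsets

    // dp[state][i][k] where k = (j - i) - lo_off
    std::vector<int> M((n + 1) * bw, NEG), IX((n + 1) * bw, NEG),
        IY((n + 1) * bw, NEG);
    std::vector<unsigned char> tbM((n + 1) * bw), tbIX((n + 1) * bw),
        tbIY((n + 1) * bw);
    auto idx = [bw](int i, int k) { return i * bw + k; };

    // initialise row 0: j = k + lo_off
    for (int k = 0; k < bw; ++k) {
      int j = k + lo_off;
      if (j < 0 || j > m) continue;
      if (j == 0) { M[idx(0, k)] = 0; }
      else {
        IY[idx(0, k)] = gap_open + gap_extend * (j - 1);
        tbIY[idx(0, k)] = (j == 1) ? ST_M : ST_IY;
      }
    }

    for (int i = 1; i <= n; ++i) {
      for (int k = 0; k < bw; ++k) {
        int j = i + k + lo_off;
        if (j < 0 || j > m) continue;
        int here = idx(i, k);
        if (j == 0) {
          // column 0: only gaps in ref (read-only prefix)
          IX[here] = gap_open + gap_extend * (i - 1);
          tbIX[here] = (i == 1) ? ST_M : ST_IX;
          continue;
        }
        // M: diagonal from (i-1, j-1) -> same k
        {
          int prev = idx(i - 1, k);
          int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
          int bm = M[prev], bx = IX[prev], by = IY[prev];
          int best = bm; unsigned char st = ST_M;
          if (bx > best) { best = bx; st = ST_IX; }
          if (by > best) { best = by; st = ST_IY; }
          if (best > NEG) { M[here] = best + s; tbM[here] = st; }
        }
        // IX: gap in ref, consume read base: from (i-1, j) -> k+1 in row i-1
        if (k + 1 < bw) {
          int prev = idx(i - 1, k + 1);
          int open_from = std::max(M[prev], IY[prev]);
          int ext = (IX[prev] > NEG) ? IX[prev] + gap_extend : NEG;
          int opn = (open_from > NEG) ? open_from + gap_open : NEG;
          if (ext >= opn && ext > NEG) { IX[here] = ext; tbIX[here] = ST_IX; }
          else if (opn > NEG) {
            IX[here] = opn;
            tbIX[here] = (M[prev] >= IY[prev]) ? ST_M : ST_IY;
          }
        }
        // IY: gap in read, consume ref base: from (i, j-1) -> k-1 same row
        if (k - 1 >= 0) {
          int prev = idx(i, k - 1);
          int open_from = std::max(M[prev], IX[prev]);
          int ext = (IY[prev] > NEG) ? IY[prev] + gap_extend : NEG;
          int opn = (open_from > NEG) ? open_from + gap_open : NEG;
          if (ext >= opn && ext > NEG) { IY[here] = ext; tbIY[here] = ST_IY; }
          else if (opn > NEG) {
            IY[here] = opn;
            tbIY[here] = (M[prev] >= IX[prev]) ? ST_M : ST_IX;
          }
        }
      }
    }

    int kend = m - n - lo_off;
    if (kend < 0 || kend >= bw) { out[rix] = NA_STRING; continue; }
    int endi = idx(n, kend);
    int best = M[endi]; int st = ST_M;
    if (IX[endi] > best) { best = IX[endi]; st = ST_IX; }
    if (IY[endi] > best) { best = IY[endi]; st = ST_IY; }
    if (best <= NEG) { out[rix] = NA_STRING; continue; }

    // traceback
    std::string ops;
    int i = n, j = m;
    while (i > 0 || j > 0) {
      int k = j - i - lo_off;
      int here = idx(i, k);
      if (st == ST_M) {
        ops.push_back('M');
        st = tbM[here]; --i; --j;
      } else if (st == ST_IX) {
        ops.push_back('I');
        st = tbIX[here]; --i;
      } else {
        ops.push_back('D');
        st = tbIY[here]; --j;
      }
    }
    // compress reversed ops into CIGAR
    std::string cig;
    int run = 0; char cur = 0;
    for (int t = (int) ops.size() - 1; t >= 0; --t) {
      if (ops[t] == cur) ++run;
      else {
        if (run > 0) cig += std::to_string(run) + cur;
        cur = ops[t]; run = 1;
      }
    }
    if (run > 0) cig += std::to_string(run) + cur;
    out[rix] = cig;
  }
  return out;
}
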