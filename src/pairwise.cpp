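#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <climits>
#include <cstdlib>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) with optional banding.
//
// States: M (a[i] aligned to b[j]), X (a[i] aligned to gap, "up"),
//         Y (gap aligned to b[j], "left").
// Gap of length L costs gapOpen + (L-1)*gapExtend (both negative).
// Tie-breaks: predecessor preference M (diagonal) > X (up) > Y (left),
// applied both when filling cells and when choosing the traceback start,
// which makes alignments deterministic.
//
// Banding restricts j to [i + min(0,d) - band, i + max(0,d) + band] with
// d = m - n. With band <= 0 the full matrix is used. Cells outside the band
// are -inf; any alignment whose gap columns fit inside the band is scored
// exactly. The band edge moves by at most one column per row, so clearing
// one guard column on each side of the writable range per row is enough to
// make unguarded reads of the previous row safe.

static const int NEG = INT_MIN / 4;

// traceback byte layout: bits 0-1 predecessor of M (0=M,1=X,2=Y,3=local start)
//                        bits 2-3 predecessor of X (0=M open, 1=X extend)
//                        bits 4-5 predecessor of Y (0=M open, 1=Y extend)

// [[Rcpp::export]]
List cpp_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
               int gapOpen, int gapExt, bool local, int band,
               bool want_ops = true) {
  const int n = a.size(), m = b.size();
  const int d = m - n;
  long long W;
  if (band <= 0) W = (long long)n + m + 1; else W = band;
  const long long lo_off = std::min(0, d) - W;  // j range at row i: [i+lo_off, i+hi_off]
  const long long hi_off = std::max(0, d) + W;
  const long long B = hi_off - lo_off + 1;
  const long long Bcap = std::min<long long>(B, (long long)m + 1);

  auto jlo = [&](long long i) { return std::max<long long>(0, i + lo_off); };
  auto jhi = [&](long long i) { return std::min<long long>(m, i + hi_off); };

  std::vector<uint8_t> tb((size_t)(n + 1) * (size_t)Bcap, 0);

  // flat substitution table indexed by a-code * nab + b-code
  const int nab = sub.nrow();
  std::vector<int> S((size_t)nab * nab);
  for (int r = 0; r < nab; ++r)
    for (int c = 0; c < nab; ++c) S[(size_t)r * nab + c] = sub(r, c);

  std::vector<int> Mp(m + 2, NEG), Xp(m + 2, NEG), Yp(m + 2, NEG);
  std::vector<int> Mc(m + 2, NEG), Xc(m + 2, NEG), Yc(m + 2, NEG);
  // index shifted by +1 so that j = -1 is addressable as 0
  int *mp = Mp.data() + 1, *xp = Xp.data() + 1, *yp = Yp.data() + 1;
  int *mc = Mc.data() + 1, *xc = Xc.data() + 1, *yc = Yc.data() + 1;

  int best = NEG;
  long long bi = 0, bj = 0; int bstate = 0;

  const int* ac = INTEGER(a);
  const int* bc = INTEGER(b);

  for (long long i = 0; i <= n; ++i) {
    const long long j0 = jlo(i), j1 = jhi(i);
    for (long long j = j0 - 1; j <= std::min<long long>(m, j1 + 1); ++j)
      mc[j] = xc[j] = yc[j] = NEG;
    uint8_t* trow = tb.data() + (size_t)i * Bcap - j0;
    if (i == 0) {
      if (!local) {
        mc[0] = 0;
        for (long long j = std::max<long long>(1, j0); j <= j1; ++j) {
          yc[j] = gapOpen + (int)(j - 1) * gapExt;
          trow[j] = (uint8_t)((j == 1 ? 0u : 1u) << 4);
        }
      } else {
        // local: row 0 stays at NEG; starts are handled per cell
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
      mp = Mp.data() + 1; xp = Xp.data() + 1; yp = Yp.data() + 1;
      mc = Mc.data() + 1; xc = Xc.data() + 1; yc = Yc.data() + 1;
      continue;
    }
    long long j = j0;
    if (j == 0) {
      if (!local) {
        xc[0] = gapOpen + (int)(i - 1) * gapExt;
        trow[0] = (uint8_t)((i == 1 ? 0u : 1u) << 2);
      }
      ++j;
    }
    const int* srow = S.data() + (size_t)ac[i - 1] * nab;
    for (; j <= j1; ++j) {
      const int s = srow[bc[j - 1]];
      // M: diagonal predecessors (reads of row i-1 are safe: guard columns
      // cleared; stale values two rows back are impossible because the band
      // moves by at most one column per row)
      int prev = mp[j - 1]; uint8_t mpred = 0;
      if (xp[j - 1] > prev) { prev = xp[j - 1]; mpred = 1; }
      if (yp[j - 1] > prev) { prev = yp[j - 1]; mpred = 2; }
      if (local && prev < 0) { prev = 0; mpred = 3; }
      // NEG is INT_MIN/4 and additive drift along any path is bounded by
      // (n + m) * |gapOpen|, so sentinel arithmetic cannot overflow
      const int Mv = prev + s;
      // X: from row i-1, same j
      int Xv; uint8_t xpred;
      {
        const int open = mp[j] + gapOpen;
        const int ext  = xp[j] + gapExt;
        if (open >= ext) { Xv = open; xpred = 0; } else { Xv = ext; xpred = 1; }
      }
      // Y: from same row, j-1
      int Yv; uint8_t ypred;
      {
        const int open = mc[j - 1] + gapOpen;
        const int ext  = yc[j - 1] + gapExt;
        if (open >= ext) { Yv = open; ypred = 0; } else { Yv = ext; ypred = 1; }
      }
      mc[j] = Mv; xc[j] = Xv; yc[j] = Yv;
      trow[j] = (uint8_t)(mpred | (xpred << 2) | (ypred << 4));
      if (local && Mv > best) { best = Mv; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    mp = Mp.data() + 1; xp = Xp.data() + 1; yp = Yp.data() + 1;
    mc = Mc.data() + 1; xc = Xc.data() + 1; yc = Yc.data() + 1;
  }

  if (!local) {
    best = mp[m]; bstate = 0; bi = n; bj = m;
    if (xp[m] > best) { best = xp[m]; bstate = 1; }
    if (yp[m] > best) { best = yp[m]; bstate = 2; }
  }
  if (local && best <= 0) {
    return List::create(_["score"] = 0, _["ops"] = IntegerVector(0),
                        _["qstart"] = 0, _["qend"] = -1, _["tstart"] = 0, _["tend"] = -1,
                        _["nident"] = 0, _["ncols"] = 0);
  }

  // traceback
  std::vector<int> ops;  // 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  long long i = bi, j = bj; int st = bstate;
  int nident = 0, ncols = 0;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    const uint8_t t = tb[(size_t)i * Bcap + (size_t)(j - jlo(i))];
    ++ncols;
    if (st == 0) {
      const uint8_t p = t & 3u;
      if (want_ops) ops.push_back(0);
      if (ac[i - 1] == bc[j - 1]) ++nident;
      --i; --j;
      if (local && p == 3) break;
      if (!local && i == 0 && j == 0) break;
      st = (p == 3) ? 0 : p;
    } else if (st == 1) {
      const uint8_t p = (t >> 2) & 3u;
      if (want_ops) ops.push_back(1);
      --i;
      st = (p == 0) ? 0 : 1;
    } else {
      const uint8_t p = (t >> 4) & 3u;
      if (want_ops) ops.push_back(2);
      --j;
      st = (p == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["qstart"] = (int)(i + 1), _["qend"] = (int)bi,
                      _["tstart"] = (int)(j + 1), _["tend"] = (int)bj,
                      _["nident"] = nident, _["ncols"] = ncols);
}

// Score-only Smith-Waterman (rolling rows, no traceback) used as a cheap
// first pass in the all-vs-all comparison; pairs whose score cannot reach
// the E-value threshold are never re-aligned with traceback.
// [[Rcpp::export]]
int cpp_align_score_local(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                          int gapOpen, int gapExt) {
  const int n = a.size(), m = b.size();
  const int nab = sub.nrow();
  std::vector<int> S((size_t)nab * nab);
  for (int r = 0; r < nab; ++r)
    for (int c = 0; c < nab; ++c) S[(size_t)r * nab + c] = sub(r, c);
  const int* ac = INTEGER(a);
  const int* bc = INTEGER(b);
  std::vector<int> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<int> Mc(m + 1, NEG), Xc(m + 1, NEG), Yc(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int* srow = S.data() + (size_t)ac[i - 1] * nab;
    int *mc = Mc.data(), *xc = Xc.data(), *yc = Yc.data();
    const int *mp = Mp.data(), *xp = Xp.data(), *yp = Yp.data();
    mc[0] = xc[0] = yc[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int prev = mp[j - 1];
      if (xp[j - 1] > prev) prev = xp[j - 1];
      if (yp[j - 1] > prev) prev = yp[j - 1];
      if (prev < 0) prev = 0;
      const int Mv = prev + srow[bc[j - 1]];
      const int xo = mp[j] + gapOpen, xe = xp[j] + gapExt;
      xc[j] = xo >= xe ? xo : xe;
      const int yo = mc[j - 1] + gapOpen, ye = yc[j - 1] + gapExt;
      yc[j] = yo >= ye ? yo : ye;
      mc[j] = Mv;
      if (Mv > best) best = Mv;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}
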