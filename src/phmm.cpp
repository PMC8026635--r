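#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Local (glocal-entry) profile-HMM alignment in log2-odds space.
//
// Model: match states 1..M with log2-odds emissions `mlo` (M x 20); insert
// states emit background (log-odds 0); delete states are silent. `tlo` is an
// (M+1) x 7 matrix of log2 transition probabilities indexed by source node
// 0..M with columns MM, MI, MD, IM, II, DM, DD (node k row holds transitions
// out of state_k into node k+1 / insert k).
//
// A scoring path enters at some match state k (free entry), ends at some
// match state l >= k (free exit); residues outside the aligned region are
// flanking and score 0. Residue code -1 (ambiguous) emits log-odds 0.
//
// Viterbi returns the best path score in bits plus the sequence region and
// match-state span; Forward returns log2 of the summed odds over all such
// paths (hence Forward >= Viterbi).

static const double NINF = -1e300;

static inline double l2add(double x, double y) {
  if (x <= NINF / 2) return y;
  if (y <= NINF / 2) return x;
  double mx = x > y ? x : y, mn = x > y ? y : x;
  return mx + std::log2(1.0 + std::exp2(mn - mx));
}

// Viterbi best score only (rolling rows, no traceback) — used as a cheap
// prefilter before the full Viterbi with region recovery.
// [[Rcpp::export]]
double cpp_phmm_score(IntegerVector seq, NumericMatrix mlo, NumericMatrix tlo) {
  const int L = seq.size(), M = mlo.nrow();
  // tlo columns (source node 0..M): MM MI MD IM II DM DD, column-major
  const double* T = REAL(tlo);
  const double *tMM = T, *tMI = T + (M + 1), *tMD = T + 2 * (M + 1),
               *tIM = T + 3 * (M + 1), *tII = T + 4 * (M + 1),
               *tDM = T + 5 * (M + 1), *tDD = T + 6 * (M + 1);
  const double* E = REAL(mlo);  // M x 20, column-major: E[x*M + (k-1)]
  std::vector<double> zeros(M, 0.0);
  std::vector<double> Vm_p(M + 1, NINF), Vi_p(M + 1, NINF), Vd_p(M + 1, NINF);
  std::vector<double> Vm_c(M + 1, NINF), Vi_c(M + 1, NINF), Vd_c(M + 1, NINF);
  double best = NINF;
  for (int j = 1; j <= L; ++j) {
    const int x = seq[j - 1];
    const double* em = (x >= 0) ? E + (size_t)x * M : zeros.data();  // em[k-1]
    double *vm = Vm_c.data(), *vi = Vi_c.data(), *vd = Vd_c.data();
    const double *pm = Vm_p.data(), *pi = Vi_p.data(), *pd = Vd_p.data();
    vm[0] = vi[0] = vd[0] = NINF;
    for (int k = 1; k <= M; ++k) {
      double cand = 0.0;
      double v = pm[k - 1] + tMM[k - 1]; if (v > cand) cand = v;
      v = pi[k - 1] + tIM[k - 1]; if (v > cand) cand = v;
      v = pd[k - 1] + tDM[k - 1]; if (v > cand) cand = v;
      const double m = em[k - 1] + cand;
      vm[k] = m;
      if (m > best) best = m;
      const double im = pm[k] + tMI[k], ii = pi[k] + tII[k];
      vi[k] = im >= ii ? im : ii;
      const double dm = vm[k - 1] + tMD[k - 1], dd = vd[k - 1] + tDD[k - 1];
      vd[k] = dm >= dd ? dm : dd;
    }
    std::swap(Vm_p, Vm_c); std::swap(Vi_p, Vi_c); std::swap(Vd_p, Vd_c);
  }
  if (best <= NINF / 2) return NA_REAL;
  return best;
}

// [[Rcpp::export]]
List cpp_phmm(IntegerVector seq, NumericMatrix mlo, NumericMatrix tlo, bool forward) {
  const int L = seq.size(), M = mlo.nrow();
  enum { MM, MI, MD, IM, II, DM, DD };

  if (!forward) {
    // full Viterbi with traceback
    std::vector<double> Vm((size_t)(L + 1) * (M + 1), NINF);
    std::vector<double> Vi((size_t)(L + 1) * (M + 1), NINF);
    std::vector<double> Vd((size_t)(L + 1) * (M + 1), NINF);
    std::vector<uint8_t> Tm((size_t)(L + 1) * (M + 1), 0);  // 0 start,1 M,2 I,3 D
    std::vector<uint8_t> Ti((size_t)(L + 1) * (M + 1), 0);  // 0 from M, 1 from I
    std::vector<uint8_t> Td((size_t)(L + 1) * (M + 1), 0);  // 0 from M, 1 from D
    auto ix = [&](int j, int k) { return (size_t)j * (M + 1) + k; };

    double best = NINF; int bj = 0, bk = 0;
    for (int j = 1; j <= L; ++j) {
      const int x = seq[j - 1];
      for (int k = 1; k <= M; ++k) {
        const double em = (x >= 0) ? mlo(k - 1, x) : 0.0;
        // M
        double cand = 0.0; uint8_t p = 0;  // fresh start
        double v = Vm[ix(j - 1, k - 1)] + tlo(k - 1, MM);
        if (v > cand) { cand = v; p = 1; }
        v = Vi[ix(j - 1, k - 1)] + tlo(k - 1, IM);
        if (v > cand) { cand = v; p = 2; }
        v = Vd[ix(j - 1, k - 1)] + tlo(k - 1, DM);
        if (v > cand) { cand = v; p = 3; }
        Vm[ix(j, k)] = em + cand; Tm[ix(j, k)] = p;
        if (Vm[ix(j, k)] > best) { best = Vm[ix(j, k)]; bj = j; bk = k; }
        // I (emits, stays at node k)
        double im = Vm[ix(j - 1, k)] + tlo(k, MI);
        double ii = Vi[ix(j - 1, k)] + tlo(k, II);
        if (im >= ii) { Vi[ix(j, k)] = im; Ti[ix(j, k)] = 0; }
        else          { Vi[ix(j, k)] = ii; Ti[ix(j, k)] = 1; }
        // D (silent, same j)
        double dm = Vm[ix(j, k - 1)] + tlo(k - 1, MD);
        double dd = Vd[ix(j, k - 1)] + tlo(k - 1, DD);
        if (dm >= dd) { Vd[ix(j, k)] = dm; Td[ix(j, k)] = 0; }
        else          { Vd[ix(j, k)] = dd; Td[ix(j, k)] = 1; }
      }
    }
    if (bj == 0) {
      return List::create(_["score"] = NA_REAL, _["jstart"] = 0, _["jend"] = -1,
                          _["kstart"] = 0, _["kend"] = -1);
    }
    // traceback from (bj, bk) in state M to the entry match state
    int j = bj, k = bk, st = 0;  // st: 0=M,1=I,2=D
    int jstart = bj, kstart = bk;
    while (true) {
      if (st == 0) {
        uint8_t p = Tm[ix(j, k)];
        jstart = j; kstart = k;
        if (p == 0) break;
        --j; --k;
        st = (p == 1) ? 0 : (p == 2 ? 1 : 2);
      } else if (st == 1) {
        uint8_t p = Ti[ix(j, k)];
        --j;
        st = (p == 0) ? 0 : 1;
      } else {
        uint8_t p = Td[ix(j, k)];
        --k;
        st = (p == 0) ? 0 : 2;
      }
    }
    return List::create(_["score"] = best, _["jstart"] = jstart, _["jend"] = bj,
                        _["kstart"] = kstart, _["kend"] = bk);
  }

  // Forward: rolling rows, log2-sum-exp
  std::vector<double> Fm_p(M + 1, NINF), Fi_p(M + 1, NINF), Fd_p(M + 1, NINF);
  std::vector<double> Fm_c(M + 1, NINF), Fi_c(M + 1, NINF), Fd_c(M + 1, NINF);
  double total = NINF;
  for (int j = 1; j <= L; ++j) {
    const int x = seq[j - 1];
    std::fill(Fm_c.begin(), Fm_c.end(), NINF);
    std::fill(Fi_c.begin(), Fi_c.end(), NINF);
    std::fill(Fd_c.begin(), Fd_c.end(), NINF);
    for (int k = 1; k <= M; ++k) {
      const double em = (x >= 0) ? mlo(k - 1, x) : 0.0;
      double acc = 0.0;  // fresh start contributes odds 2^0
      acc = l2add(acc, Fm_p[k - 1] + tlo(k - 1, MM));
      acc = l2add(acc, Fi_p[k - 1] + tlo(k - 1, IM));
      acc = l2add(acc, Fd_p[k - 1] + tlo(k - 1, DM));
      Fm_c[k] = em + acc;
      Fi_c[k] = l2add(Fm_p[k] + tlo(k, MI), Fi_p[k] + tlo(k, II));
      Fd_c[k] = l2add(Fm_c[k - 1] + tlo(k - 1, MD), Fd_c[k - 1] + tlo(k - 1, DD));
      total = l2add(total, Fm_c[k]);  // every path exits at a match state
    }
    std::swap(Fm_p, Fm_c); std::swap(Fi_p, Fi_c); std::swap(Fd_p, Fd_c);
  }
  return List::create(_["score"] = total, _["jstart"] = NA_INTEGER, _["jend"] = NA_INTEGER,
                      _["kstart"] = NA_INTEGER, _["kend"] = NA_INTEGER);
}
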