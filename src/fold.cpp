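#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy folding over pseudoknot-free structures by dynamic
// programming, under a nearest-neighbour model:
//   - helix stacking energies for adjacent base pairs (6x6 table passed
//     in from R; pair types AU, CG, GC, UA, GU, UG),
//   - flat destabilising penalties for hairpin loops, interior/bulge
//     loops and multiloops,
//   - unpaired bases free.
// Interior/bulge loops are capped at `maxloop` total unpaired bases
// (the standard folding restriction); hairpin loops span at least
// `minloop` unpaired bases.  Watson-Crick and G:U pairs admissible.
//
// Arrays (energies, minimised):
//   V(i,j)  : (i,j) paired.
//             hairpin:   Hbase + Hlog * log(size / minloop)
//             stack:     stack[p(i,j)][p(i+1,j-1)] + V(i+1,j-1)
//             interior:  Ibase + Islope * size + V(k,l), size <= maxloop
//             multiloop: Mpen + min_k WM(i+1,k-1) + M1(k,j-1)
//   M1(k,j) : best branch starting exactly at k, ending at or before j.
//   WM(i,j) : >= 1 branch within [i,j], unpaired free.
//   External region handled by a 1-D array over prefixes.

static const double BIG = 1e9;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline int pairIndex(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 1 && b == 2) return 1;  // CG
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 3 && b == 0) return 3;  // UA
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

struct FoldDP {
  int n, minloop, maxloop;
  double Hbase, Hlog, Ibase, Islope, Mpen;
  std::vector<int> b;
  double stk[6][6];
  std::vector<signed char> pmat;            // pair type or -1, n x n
  std::vector<std::vector<int> > validK;    // per j: k < j with canPair(k,j)
  std::vector<double> V, WM, M1;            // n x n row-major
  std::vector<double> W1;                   // external prefix energies

  inline double& Vat(int i, int j) { return V[(size_t) i * n + j]; }
  inline double& WMat(int i, int j) { return WM[(size_t) i * n + j]; }
  inline double& M1at(int i, int j) { return M1[(size_t) i * n + j]; }
  inline int pidx(int i, int j) const { return pmat[(size_t) i * n + j]; }
  inline bool canPair(int i, int j) const {
    return i >= 0 && j < n && j > i && pidx(i, j) >= 0;
  }

  FoldDP(const std::string& s, const NumericMatrix& st, int ml, int mxl,
         double hb, double hl, double ib, double is, double mp)
    : minloop(ml), maxloop(mxl), Hbase(hb), Hlog(hl), Ibase(ib),
      Islope(is), Mpen(mp) {
    n = (int) s.size();
    b.resize(n);
    for (int i = 0; i < n; ++i) {
      b[i] = baseCode(s[i]);
      if (b[i] < 0) stop("sequence contains a non-ACGU character after T->U mapping");
    }
    for (int a = 0; a < 6; ++a)
      for (int c = 0; c < 6; ++c) stk[a][c] = st(a, c);
    pmat.assign((size_t) n * n, -1);
    validK.assign(n, std::vector<int>());
    for (int j = 0; j < n; ++j)
      for (int i = 0; i + minloop + 1 <= j - 0; ++i) {
        if (j - i - 1 < minloop) continue;
        int p = pairIndex(b[i], b[j]);
        if (p >= 0) { pmat[(size_t) i * n + j] = (signed char) p; validK[j].push_back(i); }
      }
    V.assign((size_t) n * n, BIG);
    WM.assign((size_t) n * n, BIG);
    M1.assign((size_t) n * n, BIG);
    W1.assign(n + 1, 0.0);
    run();
  }

  void run() {
    for (int j = 0; j < n; ++j) {
      for (int i = j - minloop - 1; i >= 0; --i) {
        // V(i,j)
        if (pidx(i, j) >= 0) {
          double best = Hbase + Hlog * std::log((double)(j - i - 1) / (double) minloop);
          if (canPair(i + 1, j - 1)) {
            double c = Vat(i + 1, j - 1) + stk[(int) pidx(i, j)][(int) pidx(i + 1, j - 1)];
            if (c < best) best = c;
          }
          int kmax = i + 1 + maxloop;
          if (kmax > j - 1) kmax = j - 1;
          for (int k = i + 1; k <= kmax; ++k) {
            int lmin = j - 1 - (maxloop - (k - i - 1));
            if (lmin < k + 1) lmin = k + 1;
            const double* Vrow = &V[(size_t) k * n];
            for (int l = j - 1; l >= lmin; --l) {
              if (k == i + 1 && l == j - 1) continue;
              double c = Vrow[l] + Ibase + Islope * ((k - i - 1) + (j - l - 1));
              if (c < best) best = c;
            }
          }
          // multiloop: last branch starts at k
          if (j - i >= 2 * (minloop + 2)) {
            const double* WMrow = &WM[(size_t)(i + 1) * n];
            for (int k = i + minloop + 3; k <= j - minloop - 2; ++k) {
              double a = WMrow[k - 1];
              if (a >= BIG) continue;
              double z = M1at(k, j - 1);
              if (z >= BIG) continue;
              double c = Mpen + a + z;
              if (c < best) best = c;
            }
          }
          Vat(i, j) = best;
        }
        // M1(i,j) = min(M1(i,j-1), V(i,j))
        {
          double m = (j > i) ? M1at(i, j - 1) : BIG;
          if (Vat(i, j) < m) m = Vat(i, j);
          M1at(i, j) = m;
        }
        // WM(i,j) = min(WM(i,j-1), min_{k in validK[j], k>=i} V(k,j) + min(WM(i,k-1), 0))
        {
          double wm = (j > i) ? WMat(i, j - 1) : BIG;
          const std::vector<int>& vk = validK[j];
          for (size_t q = 0; q < vk.size(); ++q) {
            int k = vk[q];
            if (k < i) continue;
            double c = V[(size_t) k * n + j];
            if (c >= BIG) continue;
            if (k > i) {
              double left = WMat(i, k - 1);
              if (left < 0) c += left;
            }
            if (c < wm) wm = c;
          }
          WMat(i, j) = wm;
        }
      }
      // short spans: M1/WM rows for i in (j-minloop-1, j]
      for (int i = std::max(0, j - minloop - 1 + 1); i <= j; ++i) {
        M1at(i, j) = (j > i) ? M1at(i, j - 1) : BIG;
        WMat(i, j) = (j > i) ? WMat(i, j - 1) : BIG;
      }
      // external
      double w = W1[j];  // W1 is 1-based over prefix length
      {
        const std::vector<int>& vk = validK[j];
        for (size_t q = 0; q < vk.size(); ++q) {
          int k = vk[q];
          double c = V[(size_t) k * n + j] + W1[k];
          if (c < w) w = c;
        }
      }
      W1[j + 1] = w;
    }
  }

  double mfe() const { return n ? W1[n] : 0.0; }

  // --- traceback ---------------------------------------------------------
  static bool eq(double a, double b) { return std::fabs(a - b) < 1e-9; }

  void traceV(int i, int j, std::vector<int>& partner) {
    partner[i] = j; partner[j] = i;
    double v = Vat(i, j);
    if (canPair(i + 1, j - 1) &&
        eq(Vat(i + 1, j - 1) + stk[(int) pidx(i, j)][(int) pidx(i + 1, j - 1)], v)) {
      traceV(i + 1, j - 1, partner);
      return;
    }
    int kmax = std::min(i + 1 + maxloop, j - 1);
    for (int k = i + 1; k <= kmax; ++k) {
      int lmin = std::max(k + 1, j - 1 - (maxloop - (k - i - 1)));
      for (int l = j - 1; l >= lmin; --l) {
        if (k == i + 1 && l == j - 1) continue;
        if (!canPair(k, l)) continue;
        if (eq(Vat(k, l) + Ibase + Islope * ((k - i - 1) + (j - l - 1)), v)) {
          traceV(k, l, partner); return;
        }
      }
    }
    if (j - i >= 2 * (minloop + 2)) {
      for (int k = i + minloop + 3; k <= j - minloop - 2; ++k) {
        double a = WMat(i + 1, k - 1), z = M1at(k, j - 1);
        if (a < BIG && z < BIG && eq(Mpen + a + z, v)) {
          traceWM(i + 1, k - 1, partner);
          traceM1(k, j - 1, partner);
          return;
        }
      }
    }
    // hairpin loop: nothing inside
  }

  void traceM1(int i, int j, std::vector<int>& partner) {
    while (j > i && eq(M1at(i, j), M1at(i, j - 1))) --j;
    if (canPair(i, j) && eq(M1at(i, j), Vat(i, j))) traceV(i, j, partner);
  }

  void traceWM(int i, int j, std::vector<int>& partner) {
    double wm = WMat(i, j);
    if (wm >= BIG) return;
    while (j > i && eq(WMat(i, j - 1), wm)) --j;
    const std::vector<int>& vk = validK[j];
    for (size_t q = 0; q < vk.size(); ++q) {
      int k = vk[q];
      if (k < i) continue;
      double c = Vat(k, j);
      if (c >= BIG) continue;
      double left = (k > i) ? WMat(i, k - 1) : BIG;
      if (left < 0 && eq(c + left, wm)) {
        traceWM(i, k - 1, partner);
        traceV(k, j, partner);
        return;
      }
      if (eq(c, wm)) { traceV(k, j, partner); return; }
    }
  }

  void traceback(std::vector<int>& partner) {
    partner.assign(n, -1);
    int j = n - 1;
    while (j >= 0) {
      if (eq(W1[j + 1], W1[j])) { --j; continue; }
      bool done = false;
      const std::vector<int>& vk = validK[j];
      for (size_t q = 0; q < vk.size() && !done; ++q) {
        int k = vk[q];
        if (eq(Vat(k, j) + W1[k], W1[j + 1])) {
          traceV(k, j, partner);
          j = k - 1;
          done = true;
        }
      }
      if (!done) --j;
    }
  }
};

// [[Rcpp::export]]
List fold_dp_cpp(std::string seq, NumericMatrix stack, int minloop,
                 int maxloop, double hairpin_base, double hairpin_log,
                 double interior_base, double interior_slope,
                 double multiloop_penalty) {
  FoldDP dp(seq, stack, minloop, maxloop, hairpin_base, hairpin_log,
            interior_base, interior_slope, multiloop_penalty);
  std::vector<int> partner;
  dp.traceback(partner);
  int n = dp.n;
  std::string db(n, '.');
  IntegerVector part(n);
  for (int i = 0; i < n; ++i) {
    part[i] = partner[i] >= 0 ? partner[i] + 1 : NA_INTEGER;
    if (partner[i] > i) db[i] = '(';
    else if (partner[i] >= 0 && partner[i] < i) db[i] = ')';
  }
  return List::create(_["structure"] = db,
                      _["mfe"] = dp.mfe(),
                      _["partner"] = part);
}

// MFE only, vectorised over sequences (used by the shuffle test)
// [[Rcpp::export]]
NumericVector fold_mfe_batch_cpp(CharacterVector seqs, NumericMatrix stack,
                                 int minloop, int maxloop,
                                 double hairpin_base, double hairpin_log,
                                 double interior_base, double interior_slope,
                                 double multiloop_penalty) {
  int m = seqs.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    std::string s = as<std::string>(seqs[q]);
    FoldDP dp(s, stack, minloop, maxloop, hairpin_base, hairpin_log,
              interior_base, interior_slope, multiloop_penalty);
    out[q] = dp.mfe();
  }
  return out;
}

// ---------------------------------------------------------------------------
// miRNA:target duplex alignment.
//
// The miRNA (5'->3') is aligned against the reversed target window so that
// complementary antiparallel pairing becomes positionwise comparison.  The
// whole miRNA is consumed (gaps in the miRNA are scored); leading/trailing
// unaligned target bases are free.  Match/mismatch contributions at seed
// positions (miRNA positions seed_from..seed_to from the 5' end) are
// multiplied by `scaling`.
//
// Returned states per miRNA position: 0 = WC, 1 = GU, 2 = MM, 3 = GAP
// (miRNA base opposite a target gap).  `tpartner` gives the 1-based index
// (in the *original* target window orientation) paired to each miRNA
// position, NA for GAP.

// [[Rcpp::export]]
List duplex_align_cpp(std::string mirna, std::string target,
                      double match, double gu, double mm, double gap,
                      double scaling, int seed_from, int seed_to) {
  int m = (int) mirna.size(), n = (int) target.size();
  std::vector<int> a(m), t(n);
  for (int i = 0; i < m; ++i) {
    a[i] = baseCode(mirna[i]);
    if (a[i] < 0) stop("miRNA contains a non-ACGU character");
  }
  for (int j = 0; j < n; ++j) {
    t[j] = baseCode(target[n - 1 - j]);
    if (t[j] < 0) stop("target contains a non-ACGU character");
  }
  std::vector<double> dp((size_t)(m + 1) * (n + 1), 0.0);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= m; ++i) {
    dp[(size_t) i * (n + 1)] = dp[(size_t)(i - 1) * (n + 1)] + gap;
    tb[(size_t) i * (n + 1)] = 2;
  }
  for (int i = 1; i <= m; ++i) {
    double w = (i >= seed_from && i <= seed_to) ? scaling : 1.0;
    for (int j = 1; j <= n; ++j) {
      int p = pairIndex(a[i - 1], t[j - 1]);
      double sub;
      if (p >= 0 && p < 4) sub = match * w;        // Watson-Crick
      else if (p >= 4)     sub = gu;               // wobble: not scaled
      else                 sub = mm * w;
      size_t idx = (size_t) i * (n + 1) + j;
      double d = dp[(size_t)(i - 1) * (n + 1) + (j - 1)] + sub;
      double u = dp[(size_t)(i - 1) * (n + 1) + j] + gap;
      double l = dp[idx - 1] + gap;
      double best = d; unsigned char dir = 1;
      if (u > best) { best = u; dir = 2; }
      if (l > best) { best = l; dir = 3; }
      dp[idx] = best; tb[idx] = dir;
    }
  }
  // leftmost maximal cell in the final row (free trailing target gap)
  int bestj = 0; double bestscore = dp[(size_t) m * (n + 1)];
  for (int j = 1; j <= n; ++j) {
    double v = dp[(size_t) m * (n + 1) + j];
    if (v > bestscore + 1e-12) { bestscore = v; bestj = j; }
  }
  IntegerVector states(m);
  IntegerVector tpartner(m);
  int i = m, j = bestj;
  while (i > 0) {
    unsigned char dir = tb[(size_t) i * (n + 1) + j];
    if (j == 0) dir = 2;
    if (dir == 1) {
      int p = pairIndex(a[i - 1], t[j - 1]);
      states[i - 1] = (p >= 0 && p < 4) ? 0 : (p >= 4 ? 1 : 2);
      tpartner[i - 1] = n - j + 1;  // original orientation, 1-based
      --i; --j;
    } else if (dir == 2) {
      states[i - 1] = 3;
      tpartner[i - 1] = NA_INTEGER;
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["score"] = bestscore,
                      _["states"] = states,
                      _["tpartner"] = tpartner);
}
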