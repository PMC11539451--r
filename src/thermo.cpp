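// Nearest-neighbor secondary-structure dynamic programming for one or two
// RNA strands (two strands are passed as the concatenation with a nick
// index). Computes the minimum-free-energy structure with traceback and the
// McCaskill-style partition function over all valid structures.
//
// Energy model (matches the R-side structure_energy()):
//   * each base pair closes one loop; hairpin/bulge/internal penalties are
//     size-only lookups, stacks come from a 6x6 pair-type table;
//   * multibranch and exterior loops contribute zero;
//   * a loop that contains the nick between two strands scores zero and is
//     exempt from the minimum-hairpin-size rule (it acts as an exterior
//     loop);
//   * the bimolecular initiation penalty is added on the R side.
//
// Pairing: A-U, G-C, G-U (plus the reverse orientations). An optional mask
// can forbid specific (i, j) pairs, which is used for conditional ensembles
// such as "terminator stem displaced".

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e18;

// pair type index: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5, none=-1
static inline int pair_type_int(int a, int b) {
  // bases: A=0, C=1, G=2, U=3
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Engine {
  int N;
  int nick; // index of first base of strand 2, or -1
  std::vector<int> s;
  std::vector<double> stack;           // 6x6, row-major
  std::vector<double> hp, bu, in_;     // 1-indexed by loop size
  double RT;
  std::vector<char> allowed;           // N*N mask
  std::vector<double> V, W, M1, M2;        // MFE arrays
  std::vector<double> QV, QW, QM1, QM2;    // partition arrays
  std::vector<std::pair<int,int> > tb_pairs;

  inline int idx(int i, int j) const { return i * N + j; }

  inline bool nick_inside(int i, int j) const {
    return nick > i && nick <= j;
  }

  inline bool can_pair(int i, int j) const {
    if (pair_type_int(s[i], s[j]) < 0) return false;
    if (!allowed[idx(i, j)]) return false;
    if (j - i - 1 < 3 && !nick_inside(i, j)) return false;
    return true;
  }

  inline double stackE(int i, int j, int k, int l) const {
    int p1 = pair_type_int(s[i], s[j]);
    int p2 = pair_type_int(s[k], s[l]);
    return stack[p1 * 6 + p2];
  }

  // energy of the loop closed by (i,j) with single inner branch (k,l)
  inline double loopE(int i, int k, int l, int j) const {
    bool nickIn = (nick > i && nick <= k) || (nick > l && nick <= j);
    if (nickIn) return 0.0;
    int s1 = k - i - 1, s2 = j - l - 1;
    if (s1 == 0 && s2 == 0) return stackE(i, j, k, l);
    int sz = s1 + s2;
    if (s1 == 0 || s2 == 0) return (sz < (int)bu.size()) ? bu[sz] : INF;
    return (sz < (int)in_.size()) ? in_[sz] : INF;
  }

  inline double hairpinE(int i, int j) const {
    if (nick_inside(i, j)) return 0.0;
    int sz = j - i - 1;
    if (sz < 3) return INF;
    return (sz < (int)hp.size()) ? hp[sz] : INF;
  }

  void fill(bool do_mfe, bool do_pf) {
    V.assign(N * N, INF);  W.assign(N * N, 0.0);
    M1.assign(N * N, INF); M2.assign(N * N, INF);
    QV.assign(N * N, 0.0); QW.assign(N * N, 1.0);
    QM1.assign(N * N, 0.0); QM2.assign(N * N, 0.0);

    for (int span = 1; span < N; ++span) {
      for (int i = 0; i + span < N; ++i) {
        int j = i + span;
        // --- V / QV ---
        if (can_pair(i, j)) {
          double best = INF, q = 0.0;
          double hpE = hairpinE(i, j);
          if (hpE < INF / 2) {
            best = hpE;
            q += std::exp(-hpE / RT);
          }
          for (int k = i + 1; k < j; ++k) {
            for (int l = k + 1; l < j; ++l) {
              if (do_mfe && V[idx(k, l)] >= INF / 2 && QV[idx(k, l)] == 0.0)
                continue;
              bool haveV = V[idx(k, l)] < INF / 2;
              bool haveQ = QV[idx(k, l)] > 0.0;
              if (!haveV && !haveQ) continue;
              double le = loopE(i, k, l, j);
              if (le >= INF / 2) continue;
              if (haveV) {
                double cand = le + V[idx(k, l)];
                if (cand < best) best = cand;
              }
              if (haveQ) q += std::exp(-le / RT) * QV[idx(k, l)];
            }
          }
          if (j - 1 >= i + 1) {
            if (M2[idx(i + 1, j - 1)] < best) best = M2[idx(i + 1, j - 1)];
            q += QM2[idx(i + 1, j - 1)];
          }
          V[idx(i, j)] = best;
          QV[idx(i, j)] = q;
        }
        // --- W / QW (any structure; empty allowed) ---
        {
          double best = (j - 1 >= i) ? W[idx(i, j - 1)] : 0.0;
          double q = (j - 1 >= i) ? QW[idx(i, j - 1)] : 1.0;
          for (int k = i; k < j; ++k) {
            double wl = (k - 1 >= i) ? W[idx(i, k - 1)] : 0.0;
            double qwl = (k - 1 >= i) ? QW[idx(i, k - 1)] : 1.0;
            if (V[idx(k, j)] < INF / 2 && wl + V[idx(k, j)] < best)
              best = wl + V[idx(k, j)];
            if (QV[idx(k, j)] > 0.0) q += qwl * QV[idx(k, j)];
          }
          W[idx(i, j)] = best;
          QW[idx(i, j)] = q;
        }
        // --- M1 / QM1 (>= 1 branch) ---
        {
          double best = (j - 1 >= i) ? M1[idx(i, j - 1)] : INF;
          double q = (j - 1 >= i) ? QM1[idx(i, j - 1)] : 0.0;
          for (int k = i; k < j; ++k) {
            double wl = (k - 1 >= i) ? W[idx(i, k - 1)] : 0.0;
            double qwl = (k - 1 >= i) ? QW[idx(i, k - 1)] : 1.0;
            if (V[idx(k, j)] < INF / 2 && wl + V[idx(k, j)] < best)
              best = wl + V[idx(k, j)];
            if (QV[idx(k, j)] > 0.0) q += qwl * QV[idx(k, j)];
          }
          M1[idx(i, j)] = best;
          QM1[idx(i, j)] = q;
        }
        // --- M2 / QM2 (>= 2 branches) ---
        {
          double best = (j - 1 >= i) ? M2[idx(i, j - 1)] : INF;
          double q = (j - 1 >= i) ? QM2[idx(i, j - 1)] : 0.0;
          for (int k = i + 1; k < j; ++k) {
            if (!(V[idx(k, j)] < INF / 2) && QV[idx(k, j)] == 0.0) continue;
            double ml = (k - 1 >= i) ? M1[idx(i, k - 1)] : INF;
            double qml = (k - 1 >= i) ? QM1[idx(i, k - 1)] : 0.0;
            if (ml < INF / 2 && V[idx(k, j)] < INF / 2 && ml + V[idx(k, j)] < best)
              best = ml + V[idx(k, j)];
            if (qml > 0.0 && QV[idx(k, j)] > 0.0) q += qml * QV[idx(k, j)];
          }
          M2[idx(i, j)] = best;
          QM2[idx(i, j)] = q;
        }
      }
    }
  }

  static inline bool close(double a, double b) {
    return std::fabs(a - b) <= 1e-9 * (1.0 + std::fabs(a) + std::fabs(b));
  }

  void tb_W(int i, int j) {
    if (i > j) return;
    double w = W[idx(i, j)];
    if (close(w, 0.0)) return; // the empty structure realizes the optimum
    if (j - 1 >= i && close(w, W[idx(i, j - 1)])) { tb_W(i, j - 1); return; }
    for (int k = i; k < j; ++k) {
      double wl = (k - 1 >= i) ? W[idx(i, k - 1)] : 0.0;
      if (V[idx(k, j)] < INF / 2 && close(w, wl + V[idx(k, j)])) {
        if (k - 1 >= i) tb_W(i, k - 1);
        tb_V(k, j);
        return;
      }
    }
    Rcpp::stop("traceback failure in W");
  }

  void tb_V(int i, int j) {
    tb_pairs.push_back(std::make_pair(i, j));
    double v = V[idx(i, j)];
    double hpE = hairpinE(i, j);
    if (hpE < INF / 2 && close(v, hpE)) return;
    for (int k = i + 1; k < j; ++k) {
      for (int l = k + 1; l < j; ++l) {
        if (V[idx(k, l)] >= INF / 2) continue;
        double le = loopE(i, k, l, j);
        if (le >= INF / 2) continue;
        if (close(v, le + V[idx(k, l)])) { tb_V(k, l); return; }
      }
    }
    if (j - 1 >= i + 1 && M2[idx(i + 1, j - 1)] < INF / 2 &&
        close(v, M2[idx(i + 1, j - 1)])) {
      tb_M2(i + 1, j - 1);
      return;
    }
    Rcpp::stop("traceback failure in V");
  }

  void tb_M1(int i, int j) {
    double m = M1[idx(i, j)];
    if (j - 1 >= i && M1[idx(i, j - 1)] < INF / 2 && close(m, M1[idx(i, j - 1)])) {
      tb_M1(i, j - 1);
      return;
    }
    for (int k = i; k < j; ++k) {
      double wl = (k - 1 >= i) ? W[idx(i, k - 1)] : 0.0;
      if (V[idx(k, j)] < INF / 2 && close(m, wl + V[idx(k, j)])) {
        if (k - 1 >= i) tb_W(i, k - 1);
        tb_V(k, j);
        return;
      }
    }
    Rcpp::stop("traceback failure in M1");
  }

  void tb_M2(int i, int j) {
    double m = M2[idx(i, j)];
    if (j - 1 >= i && M2[idx(i, j - 1)] < INF / 2 && close(m, M2[idx(i, j - 1)])) {
      tb_M2(i, j - 1);
      return;
    }
    for (int k = i + 1; k < j; ++k) {
      if (V[idx(k, j)] >= INF / 2) continue;
      double ml = (k - 1 >= i) ? M1[idx(i, k - 1)] : INF;
      if (ml < INF / 2 && close(m, ml + V[idx(k, j)])) {
        tb_M1(i, k - 1);
        tb_V(k, j);
        return;
      }
    }
    Rcpp::stop("traceback failure in M2");
  }
};

// [[Rcpp::export]]
List thermo_dp(IntegerVector seq, int nick, NumericMatrix stack,
               NumericVector hairpin, NumericVector bulge,
               NumericVector internal, double RT,
               Nullable<LogicalMatrix> forbid = R_NilValue,
               bool traceback = true) {
  Engine e;
  e.N = seq.size();
  e.nick = nick;
  e.RT = RT;
  e.s.assign(seq.begin(), seq.end());
  e.stack.assign(36, INF);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      e.stack[a * 6 + b] = stack(a, b);
  // penalty vectors are 1-indexed by loop size
  e.hp.assign(e.N + 1, INF);
  e.bu.assign(e.N + 1, INF);
  e.in_.assign(e.N + 1, INF);
  for (int k = 1; k <= e.N; ++k) {
    if (k <= hairpin.size()) e.hp[k] = hairpin[k - 1];
    if (k <= bulge.size()) e.bu[k] = bulge[k - 1];
    if (k <= internal.size()) e.in_[k] = internal[k - 1];
  }
  e.allowed.assign(e.N * e.N, 1);
  if (forbid.isNotNull()) {
    LogicalMatrix fm(forbid);
    for (int i = 0; i < e.N; ++i)
      for (int j = 0; j < e.N; ++j)
        if (fm(i, j)) e.allowed[e.idx(i, j)] = 0;
  }
  if (e.N == 1) {
    return List::create(
      _["mfe"] = 0.0, _["pairs"] = IntegerMatrix(0, 2), _["logQ"] = 0.0,
      _["mfe_conn"] = R_PosInf, _["pairs_conn"] = IntegerMatrix(0, 2),
      _["logQ_conn"] = R_NegInf
    );
  }
  e.fill(true, true);
  double mfe = std::min(0.0, e.W[e.idx(0, e.N - 1)]);
  double logQ = std::log(e.QW[e.idx(0, e.N - 1)]);
  IntegerMatrix pairs(0, 2);
  if (traceback && mfe < -1e-12) {
    e.tb_W(0, e.N - 1);
    pairs = IntegerMatrix(e.tb_pairs.size(), 2);
    for (size_t r = 0; r < e.tb_pairs.size(); ++r) {
      pairs(r, 0) = e.tb_pairs[r].first;
      pairs(r, 1) = e.tb_pairs[r].second;
    }
  }

  // Connected two-strand ensemble: a connected structure has exactly one
  // exterior branch (k, l) spanning the nick, giving the unambiguous
  // decomposition W(0, k-1) * V(k, l) * W(l+1, N-1).
  double mfe_conn = R_PosInf, logQ_conn = R_NegInf;
  IntegerMatrix pairs_conn(0, 2);
  if (nick >= 1 && nick < e.N) {
    double best = INF, qc = 0.0;
    int bk = -1, bl = -1;
    for (int k = 0; k < nick; ++k) {
      for (int l = nick; l < e.N; ++l) {
        bool haveV = e.V[e.idx(k, l)] < INF / 2;
        bool haveQ = e.QV[e.idx(k, l)] > 0.0;
        if (!haveV && !haveQ) continue;
        double wl = (k - 1 >= 0) ? e.W[e.idx(0, k - 1)] : 0.0;
        double wr = (l + 1 <= e.N - 1) ? e.W[e.idx(l + 1, e.N - 1)] : 0.0;
        double qwl = (k - 1 >= 0) ? e.QW[e.idx(0, k - 1)] : 1.0;
        double qwr = (l + 1 <= e.N - 1) ? e.QW[e.idx(l + 1, e.N - 1)] : 1.0;
        if (haveV && wl + e.V[e.idx(k, l)] + wr < best) {
          best = wl + e.V[e.idx(k, l)] + wr;
          bk = k; bl = l;
        }
        if (haveQ) qc += qwl * e.QV[e.idx(k, l)] * qwr;
      }
    }
    if (bk >= 0 && traceback) {
      e.tb_pairs.clear();
      if (bk - 1 >= 0) e.tb_W(0, bk - 1);
      e.tb_V(bk, bl);
      if (bl + 1 <= e.N - 1) e.tb_W(bl + 1, e.N - 1);
      pairs_conn = IntegerMatrix(e.tb_pairs.size(), 2);
      for (size_t r = 0; r < e.tb_pairs.size(); ++r) {
        pairs_conn(r, 0) = e.tb_pairs[r].first;
        pairs_conn(r, 1) = e.tb_pairs[r].second;
      }
    }
    if (best < INF / 2) mfe_conn = best;
    if (qc > 0.0) logQ_conn = std::log(qc);
  }

  return List::create(
    _["mfe"] = mfe, _["pairs"] = pairs, _["logQ"] = logQ,
    _["mfe_conn"] = mfe_conn, _["pairs_conn"] = pairs_conn,
    _["logQ_conn"] = logQ_conn
  );
}
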