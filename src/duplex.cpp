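// Intermolecular RNA-RNA hybrid minimum-free-energy search.
//
// Co-linear (non-crossing) antiparallel hybrids between a target window
// (5'->3') and a miRNA (5'->3'): pairs (t1,m1), (t2,m2) with t1 < t2 imply
// m1 > m2. The energy of a hybrid is a duplex-initiation penalty plus
// nearest-neighbor stacking over adjacent pair steps plus affine penalties
// for bulges and interior loops between helices (no stacking across a
// loop). Two extension tables are computed:
//   L[i][j] = best total step cost of a chain whose rightmost pair is (i,j)
//   R[i][j] = best total step cost of a chain whose leftmost  pair is (i,j)
// (both exclude the initiation term and default to 0 = no extension).
// The unconstrained MFE is init + min L[i][j]; a seed-constrained optimum
// anchors an uninterrupted helix of >= 6 pairs within miRNA positions 1..8
// and adds optimal extensions from both helix ends.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  default: return -1;
  }
}

// Pair-type index in the stack-matrix order CG GC GU UG AU UA for the
// ordered pair (first base, second base); -1 if not pairable (G-U allowed).
static inline int pair_type_idx(int a, int b) {
  if (a == 1 && b == 2) return 0; // CG
  if (a == 2 && b == 1) return 1; // GC
  if (a == 2 && b == 3) return 2; // GU
  if (a == 3 && b == 2) return 3; // UG
  if (a == 0 && b == 3) return 4; // AU
  if (a == 3 && b == 0) return 5; // UA
  return -1;
}

struct Model {
  double stack[6][6];
  double init, loop_open, loop_ext, bulge_open, bulge_ext;
  int max_unpaired;
};

static Model read_model(const List& par) {
  Model md;
  NumericMatrix st = par["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) md.stack[i][j] = st(i, j);
  md.init = as<double>(par["init_penalty"]);
  md.loop_open = as<double>(par["loop_open"]);
  md.loop_ext = as<double>(par["loop_extend_per_nt"]);
  md.bulge_open = as<double>(par["bulge_open"]);
  md.bulge_ext = as<double>(par["bulge_extend_per_nt"]);
  md.max_unpaired = as<int>(par["max_internal_unpaired"]);
  return md;
}

// Cost of joining outer-left pair (p,q) to inner-right pair (i,j),
// p < i, q > j (0-based indices into target t and miRNA m).
static inline double step_cost(const std::vector<int>& t,
                               const std::vector<int>& m,
                               int p, int q, int i, int j, const Model& md) {
  int gt = i - p - 1, gm = q - j - 1;
  if (gt > md.max_unpaired || gm > md.max_unpaired) return INF;
  if (gt == 0 && gm == 0) {
    int a = pair_type_idx(t[p], m[q]);
    int b = pair_type_idx(m[j], t[i]);
    return md.stack[a][b];
  }
  if (gt == 0 || gm == 0)
    return md.bulge_open + (gt + gm) * md.bulge_ext;
  return md.loop_open + (gt + gm) * md.loop_ext;
}

struct Tables {
  int n, m;
  std::vector<double> L, R;
  std::vector<int> predL, predR; // encoded p * m + q, or -1
  std::vector<bool> ok;          // pairable (wobble included)
  double& Lv(int i, int j) { return L[i * m + j]; }
  double& Rv(int i, int j) { return R[i * m + j]; }
};

static void fill_tables(const std::vector<int>& t, const std::vector<int>& m,
                        const Model& md, Tables& tb) {
  int n = (int)t.size(), mm = (int)m.size();
  tb.n = n; tb.m = mm;
  tb.L.assign(n * mm, 0.0);
  tb.R.assign(n * mm, 0.0);
  tb.predL.assign(n * mm, -1);
  tb.predR.assign(n * mm, -1);
  tb.ok.assign(n * mm, false);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < mm; ++j)
      tb.ok[i * mm + j] = pair_type_idx(t[i], m[j]) >= 0;

  const double eps = 1e-9;
  // L: rightmost pair (i,j); predecessors have p < i, q > j.
  for (int i = 0; i < n; ++i)
    for (int j = mm - 1; j >= 0; --j) {
      if (!tb.ok[i * mm + j]) continue;
      double best = 0.0; int pred = -1;
      int pmin = std::max(0, i - md.max_unpaired - 1);
      int qmax = std::min(mm - 1, j + md.max_unpaired + 1);
      for (int p = pmin; p < i; ++p)
        for (int q = j + 1; q <= qmax; ++q) {
          if (!tb.ok[p * mm + q]) continue;
          double c = step_cost(t, m, p, q, i, j, md);
          if (c == INF) continue;
          double v = tb.L[p * mm + q] + c;
          if (v < best - eps) { best = v; pred = p * mm + q; }
        }
      tb.L[i * mm + j] = best;
      tb.predL[i * mm + j] = pred;
    }
  // R: leftmost pair (i,j); successors have p > i, q < j.
  for (int i = n - 1; i >= 0; --i)
    for (int j = 0; j < mm; ++j) {
      if (!tb.ok[i * mm + j]) continue;
      double best = 0.0; int pred = -1;
      int pmax = std::min(n - 1, i + md.max_unpaired + 1);
      int qmin = std::max(0, j - md.max_unpaired - 1);
      for (int p = i + 1; p <= pmax; ++p)
        for (int q = qmin; q < j; ++q) {
          if (!tb.ok[p * mm + q]) continue;
          double c = step_cost(t, m, i, j, p, q, md);
          if (c == INF) continue;
          double v = c + tb.R[p * mm + q];
          if (v < best - eps) { best = v; pred = p * mm + q; }
        }
      tb.R[i * mm + j] = best;
      tb.predR[i * mm + j] = pred;
    }
}

// Assemble the ordered pair list (ascending target) for a chain through
// (i,j): left extension via predL, then helix pairs, then right extension
// via predR. helix_t/helix_m hold the helix pairs (ascending target) or the
// single anchor pair.
static IntegerMatrix chain_pairs(const Tables& tb,
                                 const std::vector<int>& helix_t,
                                 const std::vector<int>& helix_m) {
  std::vector<int> ts, ms;
  // left extension from the leftmost helix pair
  {
    std::vector<int> lt, lm;
    int cur = tb.predL[helix_t.front() * tb.m + helix_m.front()];
    while (cur >= 0) {
      lt.push_back(cur / tb.m);
      lm.push_back(cur % tb.m);
      cur = tb.predL[cur];
    }
    for (int k = (int)lt.size() - 1; k >= 0; --k) {
      ts.push_back(lt[k]); ms.push_back(lm[k]);
    }
  }
  for (size_t k = 0; k < helix_t.size(); ++k) {
    ts.push_back(helix_t[k]); ms.push_back(helix_m[k]);
  }
  {
    int cur = tb.predR[helix_t.back() * tb.m + helix_m.back()];
    while (cur >= 0) {
      ts.push_back(cur / tb.m);
      ms.push_back(cur % tb.m);
      cur = tb.predR[cur];
    }
  }
  IntegerMatrix out((int)ts.size(), 2);
  for (size_t k = 0; k < ts.size(); ++k) {
    out(k, 0) = ts[k] + 1; // 1-based for R
    out(k, 1) = ms[k] + 1;
  }
  return out;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    v[i] = base_code(s[i]);
    if (v[i] < 0) stop("invalid RNA base '%s'", std::string(1, s[i]).c_str());
  }
  return v;
}

// [[Rcpp::export]]
List cpp_duplex_mfe(std::string target, std::string mirna, List par,
                    bool require_seed) {
  Model md = read_model(par);
  std::vector<int> t = encode(target), m = encode(mirna);
  int n = (int)t.size(), mm = (int)m.size();
  if (n == 0 || mm == 0) return List::create(_["found"] = false);
  Tables tb;
  fill_tables(t, m, md, tb);
  const double eps = 1e-9;

  double best = INF;
  std::vector<int> bh_t, bh_m; // helix pairs of the best solution

  if (!require_seed) {
    // best chain = init + min L[i][j]; anchor is the rightmost pair.
    for (int i = 0; i < n; ++i)
      for (int j = mm - 1; j >= 0; --j) {
        if (!tb.ok[i * mm + j]) continue;
        double v = md.init + tb.L[i * mm + j];
        if (v < best - eps) {
          best = v;
          bh_t.assign(1, i); bh_m.assign(1, j);
        }
      }
  } else {
    // enumerate seed helices: miRNA run s..s+len-1 (1-based) within [1,8],
    // len >= 6; anchor pairs target p (rightmost) down to p-len+1.
    for (int p = 0; p < n; ++p)
      for (int s = 1; s <= 3; ++s)
        for (int len = 8; len >= 6; --len) {
          if (s + len - 1 > 8) continue;
          if (p - len + 1 < 0 || s + len - 2 > mm - 1) continue;
          bool feas = true;
          double helixE = 0.0;
          // pairs: miRNA (s-1)+k pairs target p-k, k = 0..len-1
          for (int k = 0; k < len && feas; ++k)
            if (!tb.ok[(p - k) * mm + (s - 1 + k)]) feas = false;
          if (!feas) continue;
          for (int k = 0; k + 1 < len; ++k) {
            // step between pair (p-k-1, s+k) [left] and (p-k, s-1+k) [right]
            helixE += step_cost(t, m, p - k - 1, s + k, p - k, s - 1 + k, md);
          }
          int lt = p - len + 1, lmj = s + len - 2; // leftmost pair
          double v = md.init + helixE + tb.L[lt * mm + lmj] +
                     tb.R[p * mm + (s - 1)];
          if (v < best - eps) {
            best = v;
            bh_t.clear(); bh_m.clear();
            for (int k = len - 1; k >= 0; --k) {
              bh_t.push_back(p - k);
              bh_m.push_back(s - 1 + k);
            }
          }
        }
  }

  if (!std::isfinite(best)) return List::create(_["found"] = false);
  IntegerMatrix pairs = chain_pairs(tb, bh_t, bh_m);
  return List::create(_["found"] = true, _["energy"] = best,
                      _["pairs"] = pairs);
}

// Re-score a fixed seed helix (target th_start..th_end pairs miRNA
// mh_start..mh_end antiparallel, all 1-based) and extend the miRNA 3'
// portion optimally to the left of the helix on the target.
// [[Rcpp::export]]
List cpp_rescore_helix(std::string target, std::string mirna, List par,
                       int th_start, int th_end, int mh_start, int mh_end) {
  Model md = read_model(par);
  std::vector<int> t = encode(target), m = encode(mirna);
  int n = (int)t.size(), mm = (int)m.size();
  int len = th_end - th_start + 1;
  if (len != mh_end - mh_start + 1 || len < 1)
    stop("helix intervals have unequal lengths");
  if (th_start < 1 || th_end > n || mh_start < 1 || mh_end > mm)
    stop("helix interval out of range");
  Tables tb;
  fill_tables(t, m, md, tb);

  std::vector<int> h_t, h_m;
  double helixE = 0.0;
  // miRNA mh_start pairs target th_end; run extends leftward on target
  for (int k = len - 1; k >= 0; --k) {
    int ti = th_end - 1 - k, mj = mh_start - 1 + k;
    if (!tb.ok[ti * mm + mj])
      stop("helix contains a non-pairable position");
    h_t.push_back(ti); h_m.push_back(mj);
  }
  for (size_t k = 0; k + 1 < h_t.size(); ++k)
    helixE += step_cost(t, m, h_t[k], h_m[k], h_t[k + 1], h_m[k + 1], md);

  // left extension only (miRNA 3' portion); suppress right extension by
  // walking predL from the leftmost helix pair and not using predR.
  double energy = md.init + helixE + tb.L[h_t.front() * mm + h_m.front()];
  std::vector<int> ts, ms;
  {
    std::vector<int> lt, lm;
    int cur = tb.predL[h_t.front() * mm + h_m.front()];
    while (cur >= 0) {
      lt.push_back(cur / mm);
      lm.push_back(cur % mm);
      cur = tb.predL[cur];
    }
    for (int k = (int)lt.size() - 1; k >= 0; --k) {
      ts.push_back(lt[k]); ms.push_back(lm[k]);
    }
  }
  for (size_t k = 0; k < h_t.size(); ++k) {
    ts.push_back(h_t[k]); ms.push_back(h_m[k]);
  }
  IntegerMatrix pairs((int)ts.size(), 2);
  for (size_t k = 0; k < ts.size(); ++k) {
    pairs(k, 0) = ts[k] + 1;
    pairs(k, 1) = ms[k] + 1;
  }
  return List::create(_["found"] = true, _["energy"] = energy,
                      _["pairs"] = pairs);
}
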