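// Simplified nearest-neighbour RNA folding engine.
//
// Model (shared with the R-level element scorer, see R/energy-params.R):
//   - canonical pairs incl. GU; minimum hairpin loop 3 nt
//   - stacked pair step: 6x6 table indexed by (outer, inner) pair type
//   - hairpin/bulge/interior penalties by total unpaired size (precomputed
//     vectors, Jacobson-Stockmayer extrapolated on the R side)
//   - 1x1 interior loops scored by a constant mismatch term
//   - multibranch loop: a + b * branches + c * unpaired (closing pair
//     contributes a, each enclosed branch b)
//   - exterior bases free; two-loops capped at `maxloop` total unpaired
//
// fold_mfe_cpp returns the minimum free energy and, among co-minimal
// structures, the lexicographically smallest dot-bracket ('(' < ')' < '.').
// partition_cpp computes the McCaskill partition function over the same
// structure space and (optionally) base-pair probabilities by an outside
// recursion.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cmath>
#include <unordered_set>
using namespace Rcpp;

static const double INF = 1e18;
static const double EPS = 1e-9;

struct Model {
  std::vector<double> stack; // 6x6, row = outer pair, col = inner pair
  std::vector<double> hp;    // hairpin penalty by size (1-based index)
  std::vector<double> bu;    // bulge penalty by size
  std::vector<double> in_;   // interior penalty by total size
  double mismatch;           // 1x1 interior loop
  double ml_a, ml_b, ml_c;
  int maxloop;
  int minh;
};

static Model readModel(const List& par) {
  Model m;
  NumericMatrix st = par["stack"];
  m.stack.assign(36, 0.0);
  for (int i = 0; i < 6; i++)
    for (int j = 0; j < 6; j++) m.stack[i * 6 + j] = st(i, j);
  NumericVector hp = par["hairpin"], bu = par["bulge"], in_ = par["interior"];
  m.hp.assign(hp.begin(), hp.end());
  m.bu.assign(bu.begin(), bu.end());
  m.in_.assign(in_.begin(), in_.end());
  m.mismatch = as<double>(par["mismatch"]);
  NumericVector ml = par["ml"];
  m.ml_a = ml[0]; m.ml_b = ml[1]; m.ml_c = ml[2];
  m.maxloop = as<int>(par["maxloop"]);
  m.minh = as<int>(par["min_hairpin"]);
  return m;
}

// pair types: 0 none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA (codes A0 C1 G2 U3)
static inline int pairType(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

static inline double hpPen(const Model& m, int n) {
  return m.hp[std::min<size_t>(n, m.hp.size()) - 1];
}
static inline double buPen(const Model& m, int n) {
  return m.bu[std::min<size_t>(n, m.bu.size()) - 1];
}
static inline double inPen(const Model& m, int n) {
  return m.in_[std::min<size_t>(n, m.in_.size()) - 1];
}

// two-loop energy: outer pair (i,j), inner pair (k,l), unpaired n1 = k-i-1,
// n2 = j-l-1
static inline double twoLoop(const Model& m, int ptOut, int ptIn, int n1, int n2) {
  if (n1 == 0 && n2 == 0) return m.stack[(ptOut - 1) * 6 + (ptIn - 1)];
  if (n1 == 0 || n2 == 0) return buPen(m, n1 + n2);
  if (n1 == 1 && n2 == 1) return m.mismatch;
  return inPen(m, n1 + n2);
}

struct MfeState {
  int n;
  std::vector<int> s;
  std::vector<int> pt; // pt[i*n+j]
  std::vector<double> V, VM1, VM;
  std::vector<double> W; // W[j+1] = prefix [0..j]; W[0] = 0
  const Model* m;
  // memoized lexicographically minimal optimal strings
  std::vector<std::string> sV, sVM1, sVM, sW;
  std::vector<char> hV, hVM1, hVM, hW; // computed flags

  inline double& v(std::vector<double>& a, int i, int j) { return a[i * n + j]; }
  inline double cv(const std::vector<double>& a, int i, int j) const { return a[i * n + j]; }
};

static void mfeFill(MfeState& st) {
  const Model& m = *st.m;
  int n = st.n;
  st.V.assign(n * n, INF);
  st.VM1.assign(n * n, INF);
  st.VM.assign(n * n, INF);
  st.pt.assign(n * n, 0);
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) st.pt[i * n + j] = pairType(st.s[i], st.s[j]);

  for (int span = m.minh + 1; span < n; span++) {
    for (int i = 0; i + span < n; i++) {
      int j = i + span;
      // V
      if (st.pt[i * n + j] > 0) {
        double best = hpPen(m, j - i - 1);
        int kmax = std::min(i + 1 + m.maxloop, j - 1);
        for (int k = i + 1; k <= kmax; k++) {
          int n1 = k - i - 1;
          for (int l = j - 1; l > k + m.minh; l--) {
            int n2 = j - l - 1;
            if (n1 + n2 > m.maxloop) break;
            if (st.pt[k * n + l] == 0) continue;
            double e = st.cv(st.V, k, l);
            if (e >= INF) continue;
            double cand = e + twoLoop(m, st.pt[i * n + j], st.pt[k * n + l], n1, n2);
            if (cand < best) best = cand;
          }
        }
        for (int k = i + 2; k <= j - 2; k++) {
          double a = st.cv(st.VM, i + 1, k - 1), b = st.cv(st.VM1, k, j - 1);
          if (a >= INF || b >= INF) continue;
          double cand = m.ml_a + a + b;
          if (cand < best) best = cand;
        }
        st.v(st.V, i, j) = best;
      }
      // VM1: branch starts exactly at i, trailing unpaired to j
      {
        double best = INF;
        for (int l = i + m.minh + 1; l <= j; l++) {
          double e = st.cv(st.V, i, l);
          if (e >= INF) continue;
          double cand = e + m.ml_b + m.ml_c * (j - l);
          if (cand < best) best = cand;
        }
        st.v(st.VM1, i, j) = best;
      }
      // VM: >= 1 branch on [i..j]; condition on start k of last branch
      {
        double best = INF;
        for (int k = i; k <= j; k++) {
          double b = st.cv(st.VM1, k, j);
          if (b >= INF) continue;
          double pre = m.ml_c * (k - i);
          if (k > i) {
            double mm = st.cv(st.VM, i, k - 1);
            if (mm + b < best) best = mm + b;
          }
          if (pre + b < best) best = pre + b;
        }
        st.v(st.VM, i, j) = best;
      }
    }
  }
  // smaller spans for VM1/VM (single short branches can't exist below the
  // minimum pair span, but zero-branch prefixes can; VM/VM1 stay INF there,
  // handled by guards above). Exterior:
  st.W.assign(n + 1, 0.0);
  for (int j = 0; j < n; j++) {
    double best = st.W[j]; // j unpaired
    for (int i = 0; i + m.minh + 1 <= j; i++) {
      double e = st.cv(st.V, i, j);
      if (e >= INF) continue;
      double cand = st.W[i] + e;
      if (cand < best) best = cand;
    }
    st.W[j + 1] = best;
  }
}

static std::string dots(int k) { return std::string(k, '.'); }

static std::string strV(MfeState& st, int i, int j);
static std::string strVM1(MfeState& st, int i, int j);
static std::string strVM(MfeState& st, int i, int j);

static void lexKeep(std::string& best, const std::string& cand) {
  if (best.empty() || cand < best) best = cand;
}

static std::string strV(MfeState& st, int i, int j) {
  int n = st.n;
  if (st.hV[i * n + j]) return st.sV[i * n + j];
  const Model& m = *st.m;
  double tgt = st.cv(st.V, i, j);
  std::string best;
  if (std::abs(hpPen(m, j - i - 1) - tgt) < EPS)
    best = "(" + dots(j - i - 1) + ")";
  int kmax = std::min(i + 1 + m.maxloop, j - 1);
  for (int k = i + 1; k <= kmax; k++) {
    int n1 = k - i - 1;
    for (int l = j - 1; l > k + m.minh; l--) {
      int n2 = j - l - 1;
      if (n1 + n2 > m.maxloop) break;
      if (st.pt[k * n + l] == 0) continue;
      double e = st.cv(st.V, k, l);
      if (e >= INF) continue;
      if (std::abs(e + twoLoop(m, st.pt[i * n + j], st.pt[k * n + l], n1, n2) - tgt) < EPS)
        lexKeep(best, "(" + dots(n1) + strV(st, k, l) + dots(n2) + ")");
    }
  }
  for (int k = i + 2; k <= j - 2; k++) {
    double a = st.cv(st.VM, i + 1, k - 1), b = st.cv(st.VM1, k, j - 1);
    if (a >= INF || b >= INF) continue;
    if (std::abs(m.ml_a + a + b - tgt) < EPS)
      lexKeep(best, "(" + strVM(st, i + 1, k - 1) + strVM1(st, k, j - 1) + ")");
  }
  st.sV[i * n + j] = best;
  st.hV[i * n + j] = 1;
  return best;
}

static std::string strVM1(MfeState& st, int i, int j) {
  int n = st.n;
  if (st.hVM1[i * n + j]) return st.sVM1[i * n + j];
  const Model& m = *st.m;
  double tgt = st.cv(st.VM1, i, j);
  std::string best;
  for (int l = i + m.minh + 1; l <= j; l++) {
    double e = st.cv(st.V, i, l);
    if (e >= INF) continue;
    if (std::abs(e + m.ml_b + m.ml_c * (j - l) - tgt) < EPS)
      lexKeep(best, strV(st, i, l) + dots(j - l));
  }
  st.sVM1[i * n + j] = best;
  st.hVM1[i * n + j] = 1;
  return best;
}

static std::string strVM(MfeState& st, int i, int j) {
  int n = st.n;
  if (st.hVM[i * n + j]) return st.sVM[i * n + j];
  const Model& m = *st.m;
  double tgt = st.cv(st.VM, i, j);
  std::string best;
  for (int k = i; k <= j; k++) {
    double b = st.cv(st.VM1, k, j);
    if (b >= INF) continue;
    if (std::abs(m.ml_c * (k - i) + b - tgt) < EPS)
      lexKeep(best, dots(k - i) + strVM1(st, k, j));
    if (k > i) {
      double mm = st.cv(st.VM, i, k - 1);
      if (mm < INF && std::abs(mm + b - tgt) < EPS)
        lexKeep(best, strVM(st, i, k - 1) + strVM1(st, k, j));
    }
  }
  st.sVM[i * n + j] = best;
  st.hVM[i * n + j] = 1;
  return best;
}

static std::string strW(MfeState& st, int j) {
  // lex-min optimal string for prefix [0..j]; j = -1 -> ""
  if (j < 0) return "";
  if (st.hW[j]) return st.sW[j];
  const Model& m = *st.m;
  double tgt = st.W[j + 1];
  std::string best;
  for (int i = 0; i + m.minh + 1 <= j; i++) {
    double e = st.cv(st.V, i, j);
    if (e >= INF) continue;
    if (std::abs(st.W[i] + e - tgt) < EPS)
      lexKeep(best, strW(st, i - 1) + strV(st, i, j));
  }
  if (std::abs(st.W[j] - tgt) < EPS)
    lexKeep(best, strW(st, j - 1) + ".");
  st.sW[j] = best;
  st.hW[j] = 1;
  return best;
}

static void mfeRun(const std::vector<int>& seq, const Model& m, double& dG,
                   std::string& db) {
  MfeState st;
  st.n = (int)seq.size();
  st.s = seq;
  st.m = &m;
  mfeFill(st);
  dG = st.W[st.n];
  st.sV.assign(st.n * st.n, "");
  st.sVM1.assign(st.n * st.n, "");
  st.sVM.assign(st.n * st.n, "");
  st.sW.assign(st.n, "");
  st.hV.assign(st.n * st.n, 0);
  st.hVM1.assign(st.n * st.n, 0);
  st.hVM.assign(st.n * st.n, 0);
  st.hW.assign(st.n, 0);
  db = strW(st, st.n - 1);
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, List par) {
  Model m = readModel(par);
  std::vector<int> s(seq.begin(), seq.end());
  double dG;
  std::string db;
  mfeRun(s, m, dG, db);
  return List::create(_["structure"] = db, _["dG"] = dG);
}

// [[Rcpp::export]]
List partition_cpp(IntegerVector seq, List par, double rt, bool bpp) {
  Model m = readModel(par);
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> pt(n * n, 0);
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) pt[i * n + j] = pairType(s[i], s[j]);

  std::vector<double> Zb(n * n, 0.0), ZM1(n * n, 0.0), ZM(n * n, 0.0);
  auto B = [&](std::vector<double>& a, int i, int j) -> double& { return a[i * n + j]; };

  for (int span = m.minh + 1; span < n; span++) {
    for (int i = 0; i + span < n; i++) {
      int j = i + span;
      if (pt[i * n + j] > 0) {
        double z = std::exp(-hpPen(m, j - i - 1) / rt);
        int kmax = std::min(i + 1 + m.maxloop, j - 1);
        for (int k = i + 1; k <= kmax; k++) {
          int n1 = k - i - 1;
          for (int l = j - 1; l > k + m.minh; l--) {
            int n2 = j - l - 1;
            if (n1 + n2 > m.maxloop) break;
            if (pt[k * n + l] == 0) continue;
            double zi = B(Zb, k, l);
            if (zi <= 0) continue;
            z += zi * std::exp(-twoLoop(m, pt[i * n + j], pt[k * n + l], n1, n2) / rt);
          }
        }
        double zml = 0.0;
        for (int k = i + 2; k <= j - 2; k++)
          zml += B(ZM, i + 1, k - 1) * B(ZM1, k, j - 1);
        z += std::exp(-m.ml_a / rt) * zml;
        B(Zb, i, j) = z;
      }
      {
        double z = 0.0;
        for (int l = i + m.minh + 1; l <= j; l++) {
          double zi = B(Zb, i, l);
          if (zi <= 0) continue;
          z += zi * std::exp(-(m.ml_b + m.ml_c * (j - l)) / rt);
        }
        B(ZM1, i, j) = z;
      }
      {
        double z = 0.0;
        for (int k = i; k <= j; k++) {
          double b = B(ZM1, k, j);
          if (b <= 0) continue;
          z += std::exp(-m.ml_c * (k - i) / rt) * b;
          if (k > i) z += B(ZM, i, k - 1) * b;
        }
        B(ZM, i, j) = z;
      }
    }
  }

  // exterior, prefix and suffix
  std::vector<double> Ze(n + 1, 1.0), ZeS(n + 2, 1.0);
  for (int j = 0; j < n; j++) {
    double z = Ze[j];
    for (int i = 0; i + m.minh + 1 <= j; i++)
      if (B(Zb, i, j) > 0) z += Ze[i] * B(Zb, i, j);
    Ze[j + 1] = z;
  }
  for (int i = n - 1; i >= 0; i--) {
    double z = ZeS[i + 1];
    for (int j = i + m.minh + 1; j < n; j++)
      if (B(Zb, i, j) > 0) z += B(Zb, i, j) * ZeS[j + 1];
    ZeS[i] = z;
  }
  double Z = Ze[n];

  NumericMatrix P(bpp ? n : 0, bpp ? n : 0);
  if (bpp && n > 0) {
    std::vector<double> Qh(n * n, 0.0);
    double wa = std::exp(-(m.ml_a + m.ml_b) / rt);
    auto U = [&](int len) { return std::exp(-m.ml_c * len / rt); };
    auto MU = [&](int a, int b) { // segment [a..b]; empty if a > b
      int len = b - a + 1;
      if (len <= 0) return 1.0;
      return U(len) + ZM[a * n + b];
    };
    auto Useg = [&](int a, int b) {
      int len = b - a + 1;
      return len <= 0 ? 1.0 : U(len);
    };
    for (int span = n - 1; span >= m.minh + 1; span--) {
      for (int i = 0; i + span < n; i++) {
        int j = i + span;
        if (pt[i * n + j] == 0 || B(Zb, i, j) <= 0) continue;
        double q = Ze[i] * ZeS[j + 1];
        // enclosed by (h,l) as a two-loop
        int hmin = std::max(0, i - 1 - m.maxloop);
        for (int h = hmin; h < i; h++) {
          int n1 = i - h - 1;
          for (int l = j + 1; l < n; l++) {
            int n2 = l - j - 1;
            if (n1 + n2 > m.maxloop) break;
            if (pt[h * n + l] == 0) continue;
            double qo = Qh[h * n + l];
            if (qo <= 0) continue;
            q += qo * std::exp(-twoLoop(m, pt[h * n + l], pt[i * n + j], n1, n2) / rt);
          }
        }
        // branch of a multiloop closed by (h,l); needs >= 1 further branch
        for (int h = 0; h < i; h++) {
          for (int l = j + 1; l < n; l++) {
            if (pt[h * n + l] == 0) continue;
            double qo = Qh[h * n + l];
            if (qo <= 0) continue;
            double X = MU(h + 1, i - 1) * MU(j + 1, l - 1) -
                       Useg(h + 1, i - 1) * Useg(j + 1, l - 1);
            if (X > 0) q += qo * wa * X;
          }
        }
        Qh[i * n + j] = q;
      }
    }
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++)
        if (B(Zb, i, j) > 0 && Qh[i * n + j] > 0)
          P(i, j) = Qh[i * n + j] * B(Zb, i, j) / Z;
  }

  return List::create(_["Z"] = Z, _["bpp"] = P);
}

// Uniform sampling of sequences compatible with a structure: each pair drawn
// from the 6 canonical pair types, unpaired positions uniform over ACGU.
// Uses the R RNG so set.seed() controls reproducibility.
// [[Rcpp::export]]
List neutral_sample_cpp(std::string target, List par, int n_samples) {
  Model m = readModel(par);
  int L = target.size();
  std::vector<int> left, right, unp;
  std::vector<int> stk;
  for (int i = 0; i < L; i++) {
    char c = target[i];
    if (c == '(') stk.push_back(i);
    else if (c == ')') { left.push_back(stk.back()); right.push_back(i); stk.pop_back(); }
    else unp.push_back(i);
  }
  static const int PA[6] = {1, 2, 2, 3, 0, 3};
  static const int PB[6] = {2, 1, 3, 2, 3, 0};
  int hits = 0;
  std::vector<int> s(L, 0);
  for (int it = 0; it < n_samples; it++) {
    for (size_t p = 0; p < left.size(); p++) {
      int t = (int)std::floor(unif_rand() * 6.0);
      if (t > 5) t = 5;
      s[left[p]] = PA[t];
      s[right[p]] = PB[t];
    }
    for (size_t u = 0; u < unp.size(); u++) {
      int b = (int)std::floor(unif_rand() * 4.0);
      if (b > 3) b = 3;
      s[unp[u]] = b;
    }
    double dG;
    std::string db;
    mfeRun(s, m, dG, db);
    if (db == target) hits++;
  }
  return List::create(_["hits"] = hits, _["n"] = n_samples);
}

// Exhaustive neutral-set count over all 4^L sequences (L <= 12 guard in R).
// [[Rcpp::export]]
int neutral_exhaustive_cpp(std::string target, List par) {
  Model m = readModel(par);
  int L = target.size();
  long total = 1;
  for (int i = 0; i < L; i++) total *= 4;
  int hits = 0;
  std::vector<int> s(L, 0);
  for (long code = 0; code < total; code++) {
    long c = code;
    for (int i = 0; i < L; i++) { s[i] = c & 3; c >>= 2; }
    double dG;
    std::string db;
    mfeRun(s, m, dG, db);
    if (db == target) hits++;
  }
  return hits;
}

// Degree-preserving edge swapping for a bipartite network. m/t are 0-based
// integer endpoint indices; n_swaps selections are attempted, a swap executes
// only when neither replacement edge already exists. Uses the R RNG.
// [[Rcpp::export]]
List edge_swap_cpp(IntegerVector mir, IntegerVector tar, int n_swaps,
                   int n_target) {
  int E = mir.size();
  std::vector<int> mm(mir.begin(), mir.end()), tt(tar.begin(), tar.end());
  std::unordered_set<long long> have;
  have.reserve(E * 2);
  auto key = [&](int a, int b) { return (long long)a * n_target + b; };
  for (int e = 0; e < E; e++) have.insert(key(mm[e], tt[e]));
  int performed = 0;
  for (int it = 0; it < n_swaps; it++) {
    int e1 = (int)std::floor(unif_rand() * E);
    int e2 = (int)std::floor(unif_rand() * E);
    if (e1 >= E) e1 = E - 1;
    if (e2 >= E) e2 = E - 1;
    if (e1 == e2) continue;
    int m1 = mm[e1], t1 = tt[e1], m2 = mm[e2], t2 = tt[e2];
    if (m1 == m2 || t1 == t2) continue;
    if (have.count(key(m1, t2)) || have.count(key(m2, t1))) continue;
    have.erase(key(m1, t1));
    have.erase(key(m2, t2));
    mm[e1] = m2; // miRNAs are exchanged between the two edges
    mm[e2] = m1;
    have.insert(key(m2, t1));
    have.insert(key(m1, t2));
    performed++;
  }
  return List::create(_["mirna"] = wrap(mm), _["target"] = wrap(tt),
                      _["n_performed"] = performed);
}
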