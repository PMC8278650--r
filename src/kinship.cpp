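#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Pedigree encoding used throughout src/: animals are 1..n in an order where
// parents precede offspring; sire[i-1]/dam[i-1] hold the 1-based parent index
// or 0 for an unknown parent.

// Meuwissen & Luo (1992) recursive algorithm: F_i = sum_j L_j^2 D_j - 1 over
// the ancestors j of i, where D_j is the Mendelian-sampling variance scale
// and L accumulates path coefficients.  The -1 convention for an unknown
// parent's F makes D correct for 0/1/2 known parents.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n + 1, 0.0);
  std::vector<double> D(n + 1, 0.0);
  std::vector<char> inq(n + 1, 0);

  auto f_of = [&](int p) { return p == 0 ? -1.0 : F[p - 1]; };

  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    D[i] = 0.5 - 0.25 * (f_of(s) + f_of(d));
    if (s == 0 || d == 0) {
      F[i - 1] = 0.0;
      continue;
    }
    // ancestor sweep for a_ii
    std::priority_queue<int> q;
    std::vector<int> touched;
    double aii = 0.0;
    L[i] = 1.0;
    q.push(i);
    inq[i] = 1;
    touched.push_back(i);
    while (!q.empty()) {
      int j = q.top();
      q.pop();
      inq[j] = 0;
      double lj = L[j];
      aii += lj * lj * D[j];
      int sj = sire[j - 1], dj = dam[j - 1];
      if (sj > 0) {
        L[sj] += 0.5 * lj;
        if (!inq[sj]) { q.push(sj); inq[sj] = 1; touched.push_back(sj); }
      }
      if (dj > 0) {
        L[dj] += 0.5 * lj;
        if (!inq[dj]) { q.push(dj); inq[dj] = 1; touched.push_back(dj); }
      }
    }
    F[i - 1] = aii - 1.0;
    for (int t : touched) L[t] = 0.0;
  }
  return F;
}

// Recursive kinship with memoisation.  Relies on the topological order:
// an animal with a larger index cannot be an ancestor of one with a smaller
// index, so we always recurse through the parents of the younger member.
static double kin_rec(int a, int b, const IntegerVector& sire,
                      const IntegerVector& dam,
                      std::unordered_map<long long, double>& memo) {
  if (a == 0 || b == 0) return 0.0;
  long long key = a <= b ? ((long long)a << 32) | (unsigned int)b
                         : ((long long)b << 32) | (unsigned int)a;
  auto it = memo.find(key);
  if (it != memo.end()) return it->second;
  double v;
  if (a == b) {
    v = 0.5 * (1.0 + kin_rec(sire[a - 1], dam[a - 1], sire, dam, memo));
  } else {
    int young = a > b ? a : b;
    int old = a > b ? b : a;
    v = 0.5 * (kin_rec(sire[young - 1], old, sire, dam, memo) +
               kin_rec(dam[young - 1], old, sire, dam, memo));
  }
  memo[key] = v;
  return v;
}

// [[Rcpp::export]]
double kinship_pair_cpp(IntegerVector sire, IntegerVector dam, int a, int b) {
  std::unordered_map<long long, double> memo;
  return kin_rec(a, b, sire, dam, memo);
}

// Per-focal truncated inbreeding: BFS up from the focal animal recording
// minimum ancestor depth; ancestors first reached exactly t generations up
// have both parents set unknown, deeper ancestors drop out.  F is then the
// kinship of the focal's parents on that truncated pedigree.
// [[Rcpp::export]]
double truncated_f_cpp(IntegerVector sire, IntegerVector dam, int focal,
                       int t) {
  int n = sire.size();
  if (focal < 1 || focal > n) stop("focal index out of range");
  if (t < 1) stop("t must be >= 1");
  std::vector<int> depth(n + 1, -1);
  std::queue<int> bfs;
  depth[focal] = 0;
  bfs.push(focal);
  while (!bfs.empty()) {
    int x = bfs.front();
    bfs.pop();
    if (depth[x] >= t) continue;
    int p[2] = {sire[x - 1], dam[x - 1]};
    for (int k = 0; k < 2; ++k) {
      if (p[k] > 0 && depth[p[k]] == -1) {
        depth[p[k]] = depth[x] + 1;
        bfs.push(p[k]);
      }
    }
  }
  IntegerVector s2(clone(sire)), d2(clone(dam));
  for (int x = 1; x <= n; ++x) {
    if (depth[x] == -1 || depth[x] >= t) {
      s2[x - 1] = 0;
      d2[x - 1] = 0;
    } else {
      // drop links to parents outside the truncated vertex set
      int sp = sire[x - 1], dp = dam[x - 1];
      if (sp > 0 && (depth[sp] == -1 || depth[sp] > t)) s2[x - 1] = 0;
      if (dp > 0 && (depth[dp] == -1 || depth[dp] > t)) d2[x - 1] = 0;
    }
  }
  std::unordered_map<long long, double> memo;
  return kin_rec(s2[focal - 1], d2[focal - 1], s2, d2, memo);
}

// Longest ancestor chain per animal (MaxGen).
// [[Rcpp::export]]
IntegerVector max_gen_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  IntegerVector mg(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    int ms = s > 0 ? mg[s - 1] + 1 : 0;
    int md = d > 0 ? mg[d - 1] + 1 : 0;
    mg[i] = ms > md ? ms : md;
  }
  return mg;
}

// Equivalent complete generations: ecg(i) = 0.5*(1+ecg(s)) + 0.5*(1+ecg(d))
// over the known parents, ecg = 0 for founders.
// [[Rcpp::export]]
NumericVector ecg_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    double v = 0.0;
    if (sire[i] > 0) v += 0.5 * (1.0 + e[sire[i] - 1]);
    if (dam[i] > 0) v += 0.5 * (1.0 + e[dam[i] - 1]);
    e[i] = v;
  }
  return e;
}
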