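#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Maximal-run ROH scan for one sample x chromosome.
//
// calls: 0 = homozygous, 1 = heterozygous, 2 = missing; pos strictly
// increasing bp.  A run [i, j] is feasible when it holds at most max_het
// heterozygous and max_missing missing calls and no adjacent gap inside it
// exceeds max_gap_bp.  Feasibility is monotone under shrinking, so a
// two-pointer sweep finds, for each start, the largest feasible end; a run
// is maximal when it cannot be extended on either side.  Maximal runs are
// then filtered (min_snps, min_length_bp, density) and reduced to a
// non-overlapping set greedily by decreasing length (ties: leftmost first).
// Returns a matrix with columns start_idx, end_idx (1-based), n_snps,
// n_het, n_missing.
// [[Rcpp::export]]
IntegerMatrix roh_scan_cpp(IntegerVector calls, NumericVector pos,
                           double min_length_bp, int min_snps, int max_het,
                           int max_missing, double max_gap_bp,
                           double min_density_bp_per_snp) {
  int n = calls.size();
  std::vector<int> cs, ce, cn, ch, cm;  // candidates after filtering

  // split at gaps > max_gap_bp, then two-pointer within each block
  int block_start = 0;
  while (block_start < n) {
    int block_end = block_start;
    while (block_end + 1 < n &&
           pos[block_end + 1] - pos[block_end] <= max_gap_bp)
      ++block_end;

    int j = block_start - 1;  // last feasible end for current start
    int het = 0, mis = 0;
    int prev_j = -2;  // j of the previous start, for maximality
    for (int i = block_start; i <= block_end; ++i) {
      if (j < i - 1) {  // window emptied: reset counters at i-1
        j = i - 1;
        het = 0;
        mis = 0;
      }
      while (j + 1 <= block_end) {
        int c = calls[j + 1];
        int nh = het + (c == 1), nm = mis + (c == 2);
        if (nh > max_het || nm > max_missing) break;
        het = nh;
        mis = nm;
        ++j;
      }
      if (j >= i && (i == block_start || j > prev_j)) {
        // maximal run [i, j]
        int nsnp = j - i + 1;
        double len = pos[j] - pos[i];
        if (nsnp >= min_snps && len >= min_length_bp &&
            len / nsnp <= min_density_bp_per_snp) {
          cs.push_back(i);
          ce.push_back(j);
          cn.push_back(nsnp);
          ch.push_back(het);
          cm.push_back(mis);
        }
      }
      prev_j = j;
      // slide start out of the window
      if (j >= i) {
        if (calls[i] == 1) --het;
        if (calls[i] == 2) --mis;
      }
    }
    block_start = block_end + 1;
  }

  // greedy non-overlapping selection: longest first, leftmost on ties
  int k = cs.size();
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    double la = pos[ce[a]] - pos[cs[a]], lb = pos[ce[b]] - pos[cs[b]];
    if (la != lb) return la > lb;
    return cs[a] < cs[b];
  });
  std::vector<char> keep(k, 0);
  std::vector<std::pair<int, int> > chosen;
  for (int oi = 0; oi < k; ++oi) {
    int c = ord[oi];
    bool ok = true;
    for (auto& pr : chosen) {
      if (cs[c] <= pr.second && ce[c] >= pr.first) {
        ok = false;
        break;
      }
    }
    if (ok) {
      keep[c] = 1;
      chosen.push_back(std::make_pair(cs[c], ce[c]));
    }
  }
  int nk = 0;
  for (int i = 0; i < k; ++i) nk += keep[i];
  IntegerMatrix out(nk, 5);
  int r = 0;
  for (int i = 0; i < k; ++i) {
    if (!keep[i]) continue;
    out(r, 0) = cs[i] + 1;
    out(r, 1) = ce[i] + 1;
    out(r, 2) = cn[i];
    out(r, 3) = ch[i];
    out(r, 4) = cm[i];
    ++r;
  }
  return out;
}
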