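#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-locus gene dropping with Kalinowski exposure bookkeeping.
//
// Every replicate: founders get two globally unique allele labels; each
// non-founder draws one allele uniformly from each parent (a fresh unique
// label stands in for an unknown parent).  An individual is autozygous when
// its two labels match.  Each allele copy carries a sticky "exposed" flag
// that is switched on whenever the copy sits in an autozygous individual and
// travels with transmission; autozygosity through an already-exposed allele
// counts as ancestral (F_anc_Kal), otherwise as new (F_new_Kal).  A
// Ballou-style column records whether either inherited allele had been
// exposed in an ancestor, irrespective of current autozygosity.
//
// Uses R's RNG: seed via set.seed() in the calling R code.
// [[Rcpp::export]]
List gene_drop_cpp(IntegerVector sire, IntegerVector dam, int n_reps) {
  int n = sire.size();
  std::vector<int> a1(n), a2(n);
  std::vector<char> e1(n), e2(n);
  std::vector<double> cF(n, 0.0), cNew(n, 0.0), cAnc(n, 0.0), cBal(n, 0.0);

  for (int rep = 0; rep < n_reps; ++rep) {
    int next_label = 1;
    for (int i = 0; i < n; ++i) {
      int s = sire[i], d = dam[i];
      if (s == 0) {
        a1[i] = next_label++;
        e1[i] = 0;
      } else if (unif_rand() < 0.5) {
        a1[i] = a1[s - 1];
        e1[i] = e1[s - 1];
      } else {
        a1[i] = a2[s - 1];
        e1[i] = e2[s - 1];
      }
      if (d == 0) {
        a2[i] = next_label++;
        e2[i] = 0;
      } else if (unif_rand() < 0.5) {
        a2[i] = a1[d - 1];
        e2[i] = e1[d - 1];
      } else {
        a2[i] = a2[d - 1];
        e2[i] = e2[d - 1];
      }
      if (e1[i] || e2[i]) cBal[i] += 1.0;  // exposure inherited from ancestors
      if (a1[i] == a2[i]) {
        cF[i] += 1.0;
        if (e1[i] || e2[i])
          cAnc[i] += 1.0;
        else
          cNew[i] += 1.0;
        e1[i] = 1;
        e2[i] = 1;
      }
    }
  }
  double nr = (double)n_reps;
  NumericVector f(n), fnew(n), fanc(n), fbal(n);
  for (int i = 0; i < n; ++i) {
    f[i] = cF[i] / nr;
    fnew[i] = cNew[i] / nr;
    fanc[i] = cAnc[i] / nr;
    fbal[i] = cBal[i] / nr;
  }
  return List::create(_["f_hat"] = f, _["f_new_kal"] = fnew,
                      _["f_anc_kal"] = fanc, _["f_anc_ballou"] = fbal);
}

// Exact version: enumerate every equally likely transmission pattern.  Each
// known-parent link is one meiosis with two outcomes; the pattern index's
// bits select the transmitted allele.  Only feasible for small pedigrees.
// [[Rcpp::export]]
List exact_drop_cpp(IntegerVector sire, IntegerVector dam, int max_meioses) {
  int n = sire.size();
  int m = 0;
  for (int i = 0; i < n; ++i) {
    if (sire[i] > 0) ++m;
    if (dam[i] > 0) ++m;
  }
  if (m > max_meioses)
    stop("pedigree has %d meioses; exact enumeration limited to %d", m,
         max_meioses);
  long long npat = 1LL << m;
  std::vector<int> a1(n), a2(n);
  std::vector<char> e1(n), e2(n);
  std::vector<double> cF(n, 0.0), cNew(n, 0.0), cAnc(n, 0.0), cBal(n, 0.0);

  for (long long pat = 0; pat < npat; ++pat) {
    int bit = 0;
    int next_label = 1;
    for (int i = 0; i < n; ++i) {
      int s = sire[i], d = dam[i];
      if (s == 0) {
        a1[i] = next_label++;
        e1[i] = 0;
      } else {
        bool first = (pat >> bit++) & 1;
        a1[i] = first ? a1[s - 1] : a2[s - 1];
        e1[i] = first ? e1[s - 1] : e2[s - 1];
      }
      if (d == 0) {
        a2[i] = next_label++;
        e2[i] = 0;
      } else {
        bool first = (pat >> bit++) & 1;
        a2[i] = first ? a1[d - 1] : a2[d - 1];
        e2[i] = first ? e1[d - 1] : e2[d - 1];
      }
      if (e1[i] || e2[i]) cBal[i] += 1.0;
      if (a1[i] == a2[i]) {
        cF[i] += 1.0;
        if (e1[i] || e2[i])
          cAnc[i] += 1.0;
        else
          cNew[i] += 1.0;
        e1[i] = 1;
        e2[i] = 1;
      }
    }
  }
  double np = (double)npat;
  NumericVector f(n), fnew(n), fanc(n), fbal(n);
  for (int i = 0; i < n; ++i) {
    f[i] = cF[i] / np;
    fnew[i] = cNew[i] / np;
    fanc[i] = cAnc[i] / np;
    fbal[i] = cBal[i] / np;
  }
  return List::create(_["f_hat"] = f, _["f_new_kal"] = fnew,
                      _["f_anc_kal"] = fanc, _["f_anc_ballou"] = fbal);
}
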