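#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>
using namespace Rcpp;

// One extension step of the greedy forward beam search.
//
// L:        n x C matrix of per-candidate LLR contributions (sample i,
//           candidate j), already on the scale where a panel's LLR is the
//           sum of its members' columns. In cross-validated scoring mode
//           the caller supplies per-fold (held-out) contributions instead.
// is_case:  length-n class indicator.
// beam:     k x B integer matrix of current panels (1-based candidate
//           indices, columns sorted ascending). k = 0 seeds the size-1 step.
// beam_llr: n x B matrix of current panel LLR sums (zeros when k = 0).
// thr:      decision threshold on the LLR (log((1-prior)/prior)).
// beam_width: number of unique extended panels to retain.
//
// Ties on score are broken lexicographically on the sorted candidate-index
// vector; the R wrapper orders candidates by analyte id so this equals
// lexicographic order on sorted analyte ids. Duplicate sets (the same
// panel reached from different parents) are kept once.
// [[Rcpp::export]]
List beam_step_cpp(NumericMatrix L, LogicalVector is_case,
                   IntegerMatrix beam, NumericMatrix beam_llr,
                   double thr, int beam_width) {
  const int n = L.nrow(), C = L.ncol();
  const int k = beam.nrow(), B = beam.ncol();
  int n1 = 0, n0 = 0;
  for (int i = 0; i < n; ++i) (is_case[i] ? n1 : n0)++;

  std::vector<int> from_b, from_j;
  std::vector<double> sc, se, sp;
  from_b.reserve((size_t)B * C);

  std::vector<char> in_panel(C + 1, 0);
  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < k; ++r) in_panel[beam(r, b)] = 1;
    const double* pl = &beam_llr(0, b);
    for (int j = 0; j < C; ++j) {
      if (in_panel[j + 1]) continue;
      const double* lj = &L(0, j);
      int tp = 0, tn = 0;
      for (int i = 0; i < n; ++i) {
        bool pos = pl[i] + lj[i] > thr;
        if (is_case[i]) tp += pos; else tn += !pos;
      }
      double sens = n1 ? (double)tp / n1 : NA_REAL;
      double spec = n0 ? (double)tn / n0 : NA_REAL;
      from_b.push_back(b); from_j.push_back(j + 1);
      se.push_back(sens); sp.push_back(spec); sc.push_back(sens + spec);
    }
    for (int r = 0; r < k; ++r) in_panel[beam(r, b)] = 0;
  }

  const size_t M = sc.size();
  std::vector<int> idx(M);
  for (size_t i = 0; i < M; ++i) idx[i] = (int)i;

  // sorted member vector of extension e
  auto members = [&](int e) {
    std::vector<int> v(k + 1);
    int b = from_b[e], j = from_j[e];
    for (int r = 0; r < k; ++r) v[r] = beam(r, b);
    v[k] = j;
    std::sort(v.begin(), v.end());
    return v;
  };

  std::sort(idx.begin(), idx.end(), [&](int a, int b2) {
    if (sc[a] != sc[b2]) return sc[a] > sc[b2];
    return members(a) < members(b2);
  });

  std::set<std::vector<int> > seen;
  std::vector<int> keep;
  keep.reserve(beam_width);
  for (size_t t = 0; t < M && (int)keep.size() < beam_width; ++t) {
    std::vector<int> mem = members(idx[t]);
    if (seen.insert(mem).second) keep.push_back(idx[t]);
  }

  const int Bp = keep.size();
  IntegerMatrix new_beam(k + 1, Bp);
  IntegerVector rb(Bp), rj(Bp);
  NumericVector rsc(Bp), rse(Bp), rsp(Bp);
  for (int c = 0; c < Bp; ++c) {
    int e = keep[c];
    std::vector<int> mem = members(e);
    for (int r = 0; r <= k; ++r) new_beam(r, c) = mem[r];
    rb[c] = from_b[e] + 1;
    rj[c] = from_j[e];
    rsc[c] = sc[e]; rse[c] = se[e]; rsp[c] = sp[e];
  }
  return List::create(_["beam"] = new_beam, _["from_b"] = rb,
                      _["from_j"] = rj, _["score"] = rsc,
                      _["sensitivity"] = rse, _["specificity"] = rsp);
}
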