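#include <Rcpp.h>
using namespace Rcpp;

// Boyer-Moore scan loop over bitmask-encoded sequences. Text masks are
// powers of two (concrete DNA); pattern masks may be any non-empty subset of
// {A=1,C=2,G=4,T=8}. A text position matches a pattern position when the
// masks intersect. Shift tables are built in R (build_tables) and passed in:
//   bc: length-4 table entry per concrete text letter (A,C,G,T order),
//       the classic last-occurrence form m-1-rightmost (rightmost taken over
//       positions 0..m-2); applied shift at mismatch position j is
//       bc[c] - (m-1-j), floored at 1.
//   gs: length-m good-suffix table indexed by 0-based mismatch position
//       (gs[0] also serves as the shift after a full match); empty when the
//       pattern is degenerate and good-suffix shifts are disabled.
// Returns 0-based match starts; when trace is true, also every alignment
// (window start) visited, for shift-sequence verification.
// [[Rcpp::export(name = ".bm_scan")]]
List bm_scan(IntegerVector tmask, IntegerVector pmask,
             IntegerVector bc, IntegerVector gs, bool trace) {
  const int n = tmask.size(), m = pmask.size();
  std::vector<int> hits, aligns;
  const bool use_gs = gs.size() > 0;
  // map mask (1,2,4,8) -> index 0..3
  int midx[9] = {0};
  midx[1] = 0; midx[2] = 1; midx[4] = 2; midx[8] = 3;
  int s = 0;
  while (s <= n - m) {
    if (trace) aligns.push_back(s);
    int j = m - 1;
    while (j >= 0 && (tmask[s + j] & pmask[j])) --j;
    if (j < 0) {
      hits.push_back(s);
      s += use_gs ? gs[0] : 1;
    } else {
      int shift_bc = bc[midx[tmask[s + j]]] - (m - 1 - j);
      int shift = shift_bc;
      if (use_gs && gs[j] > shift) shift = gs[j];
      if (shift < 1) shift = 1;
      s += shift;
    }
  }
  if (trace)
    return List::create(Named("starts") = wrap(hits),
                        Named("alignments") = wrap(aligns));
  return List::create(Named("starts") = wrap(hits));
}
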