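#include <Rcpp.h>
using namespace Rcpp;

// Alternating-extrema scan (Billauer peakdet). In classic mode (0) a maximum
// is emitted once the series has fallen >= delta below the running maximum,
// then a minimum once it has risen >= delta above the running minimum,
// alternating. The trailing running extremum at the end of the series is
// never emitted.
//
// Mode 1 applies delta to the height of the candidate extremum above the
// preceding running minimum (and symmetrically below the preceding running
// maximum); the turn itself fires on any strict reversal.
// [[Rcpp::export(name = ".peakdet_cpp")]]
List peakdet_cpp(NumericVector v, double delta, int mode) {
  int n = v.size();
  std::vector<int> maxidx, minidx;
  double mx = R_NegInf, mn = R_PosInf;
  int mxpos = -1, mnpos = -1;
  bool lookformax = true;
  for (int i = 0; i < n; ++i) {
    double x = v[i];
    if (x > mx) { mx = x; mxpos = i; }
    if (x < mn) { mn = x; mnpos = i; }
    if (lookformax) {
      bool fire = (mode == 0) ? (x < mx - delta)
                              : (x < mx && mx - mn >= delta);
      if (fire) {
        maxidx.push_back(mxpos);
        mn = x; mnpos = i;
        lookformax = false;
      }
    } else {
      bool fire = (mode == 0) ? (x > mn + delta)
                              : (x > mn && mx - mn >= delta);
      if (fire) {
        minidx.push_back(mnpos);
        mx = x; mxpos = i;
        lookformax = true;
      }
    }
  }
  return List::create(_["max_idx"] = wrap(maxidx), _["min_idx"] = wrap(minidx));
}

// Per-row peak picking over an intensity matrix (pixels x mz samples):
// peakdet maxima, threshold at >= thresh (inclusive), keep top_k by intensity
// (ties broken by lower sample index, i.e. lower m/z). Returns a list of
// integer vectors of 0-based sample indices, one per row.
// [[Rcpp::export(name = ".pick_peaks_matrix_cpp")]]
List pick_peaks_matrix_cpp(NumericMatrix m, double delta, double thresh,
                           int top_k, int mode) {
  int npx = m.nrow(), nmz = m.ncol();
  List out(npx);
  NumericVector row(nmz);
  for (int p = 0; p < npx; ++p) {
    for (int j = 0; j < nmz; ++j) row[j] = m(p, j);
    List ex = peakdet_cpp(row, delta, mode);
    IntegerVector mi = ex["max_idx"];
    std::vector<int> keep;
    for (int k = 0; k < mi.size(); ++k)
      if (row[mi[k]] >= thresh) keep.push_back(mi[k]);
    std::sort(keep.begin(), keep.end(), [&](int a, int b) {
      if (row[a] != row[b]) return row[a] > row[b];
      return a < b;
    });
    if ((int)keep.size() > top_k) keep.resize(top_k);
    out[p] = wrap(keep);
  }
  return out;
}
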