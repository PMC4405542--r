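#include <Rcpp.h>
using namespace Rcpp;

// 1-based indices of pixels whose distance from (x, y) lies in
// (rmin, rmax]; if the shell is empty, rmax grows by `expand` until it is
// not (errors only when no pixel at all lies beyond rmin). Called once per
// simulated step over ~2e5 pixels, hence C++ and a single allocation-free
// scan in the common case.
// [[Rcpp::export]]
IntegerVector annulus_candidates(NumericVector px, NumericVector py,
                                 double x, double y,
                                 double rmin, double rmax, double expand) {
  const int n = px.size();
  const double lo = rmin * rmin;
  double hi = rmax * rmax;
  std::vector<int> out;
  for (;;) {
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = px[i] - x, dy = py[i] - y;
      const double d2 = dx * dx + dy * dy;
      if (d2 > lo && d2 <= hi) out.push_back(i + 1);
      else if (d2 > dmax) dmax = d2;
    }
    if (!out.empty()) break;
    if (hi >= dmax) stop("no pixel beyond the minimum distance");
    rmax += expand;
    hi = rmax * rmax;
  }
  return wrap(out);
}
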