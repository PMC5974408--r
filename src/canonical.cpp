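// Order-invariant (canonical) reductions over the gene axis.
//
// Each reduction sorts the values it accumulates into nondecreasing order
// before summing, so the result depends only on the multiset of values --
// never on the order of the gene columns. Accumulation uses long double,
// matching R's own sum().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline double sorted_sum(std::vector<double>& buf) {
  std::sort(buf.begin(), buf.end());
  long double acc = 0.0L;
  for (double v : buf) acc += v;
  return static_cast<double>(acc);
}

// [[Rcpp::export]]
NumericVector canonical_rowsums_cpp(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = m(i, j);
    out[i] = sorted_sum(buf);
  }
  return out;
}
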