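#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>

using namespace Rcpp;

// Support counts for the Kraskov-Stoegbauer-Grassberger MI estimator
// (variant 1).  For each point: eps = max-norm distance to its k-th nearest
// neighbour, nx / ny = number of other points strictly within eps on each
// margin.  Points are processed in x-sorted order; the k-NN search expands a
// window in x and prunes once the x-gap alone exceeds the current k-th best
// distance, so the cost is near-linear for non-degenerate data.
// [[Rcpp::export]]
List ksg_counts(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (k < 1 || k >= n) stop("k out of range");

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  std::vector<double> xs(n), ys(n), ysorted(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys[i] = y[ord[i]];
    ysorted[i] = y[i];
  }
  std::sort(ysorted.begin(), ysorted.end());

  IntegerVector nx(n), ny(n);
  NumericVector eps(n);

  for (int i = 0; i < n; ++i) {
    std::priority_queue<double> best;  // max-heap holding k smallest distances
    int lo = i - 1, hi = i + 1;
    while (lo >= 0 || hi < n) {
      const double dLo = (lo >= 0) ? xs[i] - xs[lo] : R_PosInf;
      const double dHi = (hi < n) ? xs[hi] - xs[i] : R_PosInf;
      if ((int)best.size() == k && std::min(dLo, dHi) >= best.top()) break;
      const int j = (dLo <= dHi) ? lo-- : hi++;
      const double d = std::max(std::abs(xs[i] - xs[j]),
                                std::abs(ys[i] - ys[j]));
      if ((int)best.size() < k) {
        best.push(d);
      } else if (d < best.top()) {
        best.pop();
        best.push(d);
      }
    }
    const double e = best.top();
    eps[ord[i]] = e;

    // strict marginal counts, excluding the point itself
    const double xi = xs[i], yi = ys[i];
    const int cx =
        (int)(std::lower_bound(xs.begin(), xs.end(), xi + e) -
              std::upper_bound(xs.begin(), xs.end(), xi - e)) - 1;
    const int cy =
        (int)(std::lower_bound(ysorted.begin(), ysorted.end(), yi + e) -
              std::upper_bound(ysorted.begin(), ysorted.end(), yi - e)) - 1;
    nx[ord[i]] = cx;
    ny[ord[i]] = cy;
  }

  return List::create(_["nx"] = nx, _["ny"] = ny, _["eps"] = eps);
}
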