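#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive max-mean contiguous window search over a cortical profile.
//
// Samples carry a step length ds (micrometres). Admissible windows are
// contiguous index ranges whose summed ds lies in [fmin, fmax] * total_len;
// when circular is false a window must stay within one contiguity run
// (contact exclusions split the boundary into runs). Returns the window
// maximizing the length-weighted mean intensity; ties broken by longer
// window, then by smaller start index.
//
// Tie handling: all windows whose mean is within tie_tol (relative) of the
// maximal mean count as tied; among tied windows the longest wins, then the
// smallest start index. tie_tol = 0 reduces to exact ties.
//
// [[Rcpp::export]]
List best_window_cpp(NumericVector intensity, NumericVector ds,
                     IntegerVector run, double total_len,
                     double fmin, double fmax, bool circular,
                     double tie_tol) {
  int n = intensity.size();
  double lo = fmin * total_len, hi = fmax * total_len;
  int m = circular ? 2 * n : n;

  std::vector<double> I(m), D(m);
  std::vector<int> R(m);
  for (int i = 0; i < m; ++i) {
    I[i] = intensity[i % n];
    D[i] = ds[i % n];
    R[i] = circular ? 0 : run[i];
  }

  const double eps = 1e-12;
  // pass 1: maximal admissible window mean
  double max_mean = R_NegInf;
  bool any = false;
  for (int i = 0; i < n; ++i) {
    double wlen = 0.0, wsum = 0.0;
    int jmax = circular ? i + n - 1 : n - 1;
    for (int j = i; j <= jmax; ++j) {
      if (!circular && R[j] != R[i]) break;
      wlen += D[j];
      wsum += I[j] * D[j];
      if (wlen > hi + eps) break;
      if (wlen + eps < lo) continue;
      any = true;
      double mean = wsum / wlen;
      if (mean > max_mean) max_mean = mean;
    }
  }
  if (!any)
    return List::create(Named("found") = false);

  // pass 2: longest window within tolerance of the maximum
  double thresh = max_mean - tie_tol * std::abs(max_mean) - eps;
  double best_mean = R_NegInf, best_len = -1.0;
  int best_i = -1, best_j = -1;
  for (int i = 0; i < n; ++i) {
    double wlen = 0.0, wsum = 0.0;
    int jmax = circular ? i + n - 1 : n - 1;
    for (int j = i; j <= jmax; ++j) {
      if (!circular && R[j] != R[i]) break;
      wlen += D[j];
      wsum += I[j] * D[j];
      if (wlen > hi + eps) break;
      if (wlen + eps < lo) continue;
      double mean = wsum / wlen;
      if (mean < thresh) continue;
      bool better = wlen > best_len + eps;
      if (!better && std::abs(wlen - best_len) <= eps && best_i >= 0) {
        if (mean > best_mean + eps) better = true;
        else if (std::abs(mean - best_mean) <= eps && i < best_i) better = true;
      }
      if (better) {
        best_mean = mean;
        best_len = wlen;
        best_i = i;
        best_j = j;
      }
    }
  }

  if (best_i < 0)
    return List::create(Named("found") = false);
  return List::create(
    Named("found") = true,
    Named("start") = best_i + 1,
    Named("end") = (best_j % n) + 1,
    Named("wraps") = best_j >= n,
    Named("mean") = best_mean,
    Named("length_um") = best_len);
}
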