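#include <Rcpp.h>
using namespace Rcpp;

// Greedy max-min farthest point sampling.
// Maintains, for every point, the minimum squared distance to the selected
// set; each iteration updates that cache against the newly selected point
// (N distance evaluations) and picks the argmax, lowest index on ties.
// The distance-operation counter is the hardware-independent cost surrogate.
// [[Rcpp::export(name = ".fps_cpp")]]
List fps_cpp(NumericMatrix coords, int m, int start_index) {
  const int n = coords.nrow();
  if (m < 1 || m > n) stop("target count m must satisfy 1 <= m <= N");
  if (start_index < 0 || start_index >= n) stop("start index out of range");
  IntegerVector sel(m);
  std::vector<double> mind(n, R_PosInf);
  const double *px = &coords(0, 0);
  const double *py = &coords(0, 1);
  const double *pz = &coords(0, 2);
  double ops = 0.0;
  int cur = start_index;
  sel[0] = cur;
  for (int j = 1; j < m; ++j) {
    const double cx = px[cur], cy = py[cur], cz = pz[cur];
    double best = -1.0;
    int best_i = -1;
    double *md = mind.data();
    for (int i = 0; i < n; ++i) {
      const double dx = px[i] - cx;
      const double dy = py[i] - cy;
      const double dz = pz[i] - cz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > md[i]) d2 = md[i]; else md[i] = d2;
      if (d2 > best) { best = d2; best_i = i; }
    }
    ops += n;
    cur = best_i;
    sel[j] = cur;
  }
  return List::create(_["indices"] = sel + 1, _["distance_ops"] = ops);
}
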