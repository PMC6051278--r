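#include <Rcpp.h>
using namespace Rcpp;

// Maximum-energy ridge path through an energy matrix (bins x times):
// maximise sum_t E[b_t, t] - lambda * (b_t - b_{t-1})^2, with per-step
// jumps limited to +/- max_jump bins. Returns 1-based bin indices.
// [[Rcpp::export(name = ".ridge_dp_cpp")]]
IntegerVector ridge_dp_cpp(NumericMatrix e, double lambda, int max_jump) {
  const int nb = e.nrow(), nt = e.ncol();
  std::vector<double> cost(nb), next(nb);
  std::vector<double> pen(2 * max_jump + 1);
  for (int d = -max_jump; d <= max_jump; ++d)
    pen[d + max_jump] = lambda * (double)d * (double)d;
  IntegerMatrix ptr(nb, nt);
  const double *ecol = &e(0, 0);
  for (int b = 0; b < nb; ++b) cost[b] = ecol[b];
  for (int t = 1; t < nt; ++t) {
    ecol = &e(0, t);
    int *pcol = &ptr(0, t);
    for (int b = 0; b < nb; ++b) {
      double best = R_NegInf;
      int barg = b;
      int lo = b - max_jump < 0 ? 0 : b - max_jump;
      int hi = b + max_jump >= nb ? nb - 1 : b + max_jump;
      for (int s = lo; s <= hi; ++s) {
        double cand = cost[s] - pen[b - s + max_jump];
        if (cand > best) { best = cand; barg = s; }
      }
      next[b] = best + ecol[b];
      pcol[b] = barg;
    }
    cost.swap(next);
  }
  IntegerVector path(nt);
  int b = 0;
  double best = R_NegInf;
  for (int i = 0; i < nb; ++i) if (cost[i] > best) { best = cost[i]; b = i; }
  path[nt - 1] = b + 1;
  for (int t = nt - 1; t > 0; --t) {
    b = ptr(b, t);
    path[t - 1] = b + 1;
  }
  return path;
}
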