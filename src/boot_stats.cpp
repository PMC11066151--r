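#include <Rcpp.h>
using namespace Rcpp;

// Mann-Whitney AUC of "higher value => positive class", ties counted 0.5.
static double pair_auc(const double* pos, int n1, const double* neg, int n0) {
  double s = 0.0;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n0; ++j) {
      if (pos[i] > neg[j]) s += 1.0;
      else if (pos[i] == neg[j]) s += 0.5;
    }
  }
  return s / (double(n1) * double(n0));
}

// Per-gene bootstrap AUC and direction stability.
// x: genes x samples; ei / ni: b x n1 / b x n0 matrices of 1-based column
// indices (stratified bootstrap resamples of the early / no-relapse group).
// A gene is stable when the direction (sign of mean difference) is defined
// and identical across all b bootstraps.
// [[Rcpp::export(name = ".boot_gene_stats_cpp")]]
List boot_gene_stats_cpp(NumericMatrix x, IntegerMatrix ei, IntegerMatrix ni) {
  const int ng = x.nrow();
  const int b = ei.nrow();
  const int n1 = ei.ncol();
  const int n0 = ni.ncol();
  if (ni.nrow() != b) stop("bootstrap index matrices disagree on b");

  NumericVector mean_auc(ng);
  IntegerVector direction(ng);
  LogicalVector stable(ng, true);

  std::vector<double> pos(n1), neg(n0);
  for (int g = 0; g < ng; ++g) {
    double auc_sum = 0.0;
    int dir0 = 0;
    bool ok = true;
    for (int r = 0; r < b; ++r) {
      double se = 0.0, sn = 0.0;
      for (int i = 0; i < n1; ++i) {
        pos[i] = x(g, ei(r, i) - 1);
        se += pos[i];
      }
      for (int j = 0; j < n0; ++j) {
        neg[j] = x(g, ni(r, j) - 1);
        sn += neg[j];
      }
      auc_sum += pair_auc(pos.data(), n1, neg.data(), n0);
      double me = se / n1, mn = sn / n0;
      int dir = (me > mn) ? 1 : ((me < mn) ? -1 : 0);
      if (dir == 0) ok = false;
      if (r == 0) dir0 = dir;
      else if (dir != dir0) ok = false;
    }
    mean_auc[g] = auc_sum / b;
    stable[g] = ok;
    direction[g] = ok ? dir0 : NA_INTEGER;
  }
  return List::create(_["mean_auc"] = mean_auc,
                      _["direction"] = direction,
                      _["stable"] = stable);
}
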