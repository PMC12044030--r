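#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximum absolute cluster mass of one 1-D t-vector: contiguous runs of
// t > thr (positive clusters) and t < -thr (negative clusters); mass is the
// sum of t inside a run. Strict inequality at the threshold.
static double max_mass_1d(const double* t, int n, double thr) {
  double best = 0.0, run = 0.0;
  int state = 0; // 0 none, 1 positive, -1 negative
  for (int i = 0; i < n; ++i) {
    int s = (t[i] > thr) ? 1 : (t[i] < -thr ? -1 : 0);
    if (s != state) {
      if (state != 0 && std::abs(run) > best) best = std::abs(run);
      run = 0.0;
      state = s;
    }
    if (s != 0) run += t[i];
  }
  if (state != 0 && std::abs(run) > best) best = std::abs(run);
  return best;
}

// [[Rcpp::export]]
NumericVector perm_max_mass_1d(NumericMatrix tmat, double thr) {
  int nperm = tmat.nrow(), n = tmat.ncol();
  NumericVector out(nperm);
  std::vector<double> row(n);
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < n; ++j) row[j] = tmat(p, j);
    out[p] = max_mass_1d(row.data(), n, thr);
  }
  return out;
}

// 4-neighbourhood connected-component labelling of a signed supra-threshold
// map (values +1 / -1 / 0); components never join across sign. Returns
// integer labels starting at 1, 0 for sub-threshold cells. Grid is
// column-major nrow x ncol (R array layout).
// [[Rcpp::export]]
IntegerVector label_components_2d(IntegerVector sign_map, int nrow, int ncol) {
  IntegerVector labels(sign_map.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < sign_map.size(); ++idx) {
    if (sign_map[idx] == 0 || labels[idx] != 0) continue;
    int s = sign_map[idx];
    ++next;
    stack.clear();
    stack.push_back(idx);
    labels[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int r = cur % nrow, c = cur / nrow;
      const int nb[4] = {
        (r > 0) ? cur - 1 : -1,
        (r < nrow - 1) ? cur + 1 : -1,
        (c > 0) ? cur - nrow : -1,
        (c < ncol - 1) ? cur + nrow : -1
      };
      for (int k = 0; k < 4; ++k) {
        int j = nb[k];
        if (j >= 0 && labels[j] == 0 && sign_map[j] == s) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_labels") = next;
  return labels;
}

// Maximum absolute 2-D cluster mass per permutation. Each row of tmat is a
// flattened (column-major, nrow x ncol) t-map.
// [[Rcpp::export]]
NumericVector perm_max_mass_2d(NumericMatrix tmat, int nrow, int ncol,
                               double thr) {
  int nperm = tmat.nrow(), n = tmat.ncol();
  if (n != nrow * ncol) stop("grid dimensions do not match map length");
  NumericVector out(nperm);
  std::vector<int> labels(n), stack;
  for (int p = 0; p < nperm; ++p) {
    std::fill(labels.begin(), labels.end(), 0);
    double best = 0.0;
    int next = 0;
    for (int idx = 0; idx < n; ++idx) {
      double v = tmat(p, idx);
      int s = (v > thr) ? 1 : (v < -thr ? -1 : 0);
      if (s == 0 || labels[idx] != 0) continue;
      ++next;
      double mass = 0.0;
      stack.clear();
      stack.push_back(idx);
      labels[idx] = next;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        mass += tmat(p, cur);
        int r = cur % nrow, c = cur / nrow;
        const int nb[4] = {
          (r > 0) ? cur - 1 : -1,
          (r < nrow - 1) ? cur + 1 : -1,
          (c > 0) ? cur - nrow : -1,
          (c < ncol - 1) ? cur + nrow : -1
        };
        for (int k = 0; k < 4; ++k) {
          int j = nb[k];
          if (j < 0 || labels[j] != 0) continue;
          double w = tmat(p, j);
          int sj = (w > thr) ? 1 : (w < -thr ? -1 : 0);
          if (sj == s) {
            labels[j] = next;
            stack.push_back(j);
          }
        }
      }
      if (std::abs(mass) > best) best = std::abs(mass);
    }
    out[p] = best;
  }
  return out;
}
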