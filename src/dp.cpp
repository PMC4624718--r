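#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with zero gap penalty over a positive score matrix.
// Returns the order-preserving set of matched (i, j) pairs (1-based)
// maximizing the summed cell scores. Ties resolved toward the diagonal
// so repeated runs are deterministic.
// [[Rcpp::export(name = ".nw_gapless")]]
IntegerMatrix nw_gapless(NumericMatrix S) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = D(i - 1, j - 1) + S(i - 1, j - 1);
      double up = D(i - 1, j);
      double left = D(i, j - 1);
      double best = diag;
      int ptr = 1;
      if (up > best) { best = up; ptr = 2; }
      if (left > best) { best = left; ptr = 3; }
      D(i, j) = best;
      P(i, j) = ptr;
    }
  }
  std::vector<int> qi, tj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    int ptr = P(i, j);
    if (ptr == 1) {
      qi.push_back(i);
      tj.push_back(j);
      --i; --j;
    } else if (ptr == 2) {
      --i;
    } else {
      --j;
    }
  }
  int k = qi.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = qi[k - 1 - r];
    out(r, 1) = tj[k - 1 - r];
  }
  return out;
}

// Shrake-Rupley accessible-point counting. For each atom, counts how many
// of the supplied unit-sphere points (scaled to radius_i + probe) fall
// outside every neighbouring sphere (radius_j + probe).
// [[Rcpp::export(name = ".sr_accessible")]]
NumericVector sr_accessible(NumericMatrix xyz, NumericVector radii,
                            double probe, NumericMatrix pts) {
  int n = xyz.nrow(), np = pts.nrow();
  NumericVector frac(n);
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    // neighbour prefilter
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double lim = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      double px = xyz(i, 0) + ri * pts(p, 0);
      double py = xyz(i, 1) + ri * pts(p, 1);
      double pz = xyz(i, 2) + ri * pts(p, 2);
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double rj = radii[j] + probe;
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    frac[i] = (double)acc / np;
  }
  return frac;
}
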