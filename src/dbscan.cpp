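#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classic DBSCAN on 2-D points (gene, anchor) with Euclidean metric.
// A point's eps-neighborhood includes the point itself; a core point has
// >= min_samples neighbors. Border points are attached to the cluster of
// their nearest core neighbor (deterministic under sample permutation,
// ties broken toward the lower cluster label). Noise is labeled -1,
// clusters 0, 1, ...
static std::vector<int> dbscan_labels(const double* x, const double* y, int n,
                                      double eps, int min_samples) {
  const double eps2 = eps * eps;
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= eps2) nbr[i].push_back(j);
    }
  }
  std::vector<bool> core(n);
  for (int i = 0; i < n; ++i) core[i] = (int)nbr[i].size() >= min_samples;

  std::vector<int> lab(n, -1);
  int c = -1;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || lab[i] != -1) continue;
    lab[i] = ++c;
    stack.assign(1, i);
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      for (int q : nbr[p]) {
        if (core[q] && lab[q] == -1) {
          lab[q] = c;
          stack.push_back(q);
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (core[i]) continue;
    double best = R_PosInf;
    int bl = -1;
    for (int q : nbr[i]) {
      if (!core[q]) continue;
      const double dx = x[i] - x[q], dy = y[i] - y[q];
      const double d = dx * dx + dy * dy;
      if (d < best || (d == best && (bl == -1 || lab[q] < bl))) {
        best = d;
        bl = lab[q];
      }
    }
    lab[i] = bl;
  }
  return lab;
}

// [[Rcpp::export(name = ".dbscan_pair_cpp")]]
IntegerVector dbscan_pair_cpp(NumericVector gene_vec, NumericVector anchor_vec,
                              double eps, int min_samples) {
  const int n = gene_vec.size();
  std::vector<int> lab =
      dbscan_labels(gene_vec.begin(), anchor_vec.begin(), n, eps, min_samples);
  return IntegerVector(lab.begin(), lab.end());
}

// Scan the whole eps grid for one gene and report the best accepting
// (eps, cluster pair) under the configured thresholds. Cluster sizes are
// counted over `count_mask` (all samples in cell-line mode, basal samples
// in tumor mode); centroids and separation use all member points.
// [[Rcpp::export(name = ".evaluate_gene_cpp")]]
List evaluate_gene_cpp(NumericVector gene_vec, NumericVector anchor_vec,
                       NumericVector eps_grid, int min_samples,
                       double min_cluster_size, bool strict_size,
                       double min_centroid_dist, double min_separation,
                       bool use_separation, LogicalVector count_mask) {
  const int n = gene_vec.size();
  bool accepted = false;
  double best_eps = NA_REAL, best_cd = -1.0, best_sep = NA_REAL;
  int best_s1 = NA_INTEGER, best_s2 = NA_INTEGER;

  for (int e = 0; e < eps_grid.size(); ++e) {
    const double eps = eps_grid[e];
    std::vector<int> lab =
        dbscan_labels(gene_vec.begin(), anchor_vec.begin(), n, eps, min_samples);
    int nc = -1;
    for (int i = 0; i < n; ++i) nc = std::max(nc, lab[i]);
    ++nc;
    if (nc < 2) continue;

    std::vector<double> cx(nc, 0.0), cy(nc, 0.0);
    std::vector<int> csz(nc, 0), cmasked(nc, 0);
    for (int i = 0; i < n; ++i) {
      const int l = lab[i];
      if (l < 0) continue;
      cx[l] += gene_vec[i];
      cy[l] += anchor_vec[i];
      ++csz[l];
      if (count_mask[i]) ++cmasked[l];
    }
    for (int l = 0; l < nc; ++l) {
      cx[l] /= csz[l];
      cy[l] /= csz[l];
    }
    for (int a = 0; a < nc; ++a) {
      for (int b = a + 1; b < nc; ++b) {
        const bool size_ok = strict_size
            ? (cmasked[a] > min_cluster_size && cmasked[b] > min_cluster_size)
            : (cmasked[a] >= min_cluster_size && cmasked[b] >= min_cluster_size);
        if (!size_ok) continue;
        const double dx = cx[a] - cx[b], dy = cy[a] - cy[b];
        const double cd = std::sqrt(dx * dx + dy * dy);
        if (!(cd > min_centroid_dist)) continue;
        // single-linkage gap between the two clusters
        double gap2 = R_PosInf;
        for (int i = 0; i < n; ++i) {
          if (lab[i] != a) continue;
          for (int j = 0; j < n; ++j) {
            if (lab[j] != b) continue;
            const double ddx = gene_vec[i] - gene_vec[j];
            const double ddy = anchor_vec[i] - anchor_vec[j];
            const double d2 = ddx * ddx + ddy * ddy;
            if (d2 < gap2) gap2 = d2;
          }
        }
        const double sep = std::sqrt(gap2);
        if (use_separation && !(sep > min_separation)) continue;
        accepted = true;
        if (cd > best_cd) {
          best_cd = cd;
          best_eps = eps;
          best_sep = sep;
          best_s1 = std::min(cmasked[a], cmasked[b]);
          best_s2 = std::max(cmasked[a], cmasked[b]);
        }
      }
    }
  }
  return List::create(
      _["accepted"] = accepted, _["best_eps"] = best_eps,
      _["centroid_dist"] = accepted ? best_cd : NA_REAL,
      _["size_small"] = best_s1, _["size_large"] = best_s2,
      _["separation"] = best_sep);
}
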