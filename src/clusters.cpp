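#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spatiotemporal clustering of a channels x time t-map. Two supra-threshold
// points are linked when they share an electrode at consecutive timepoints or
// are neighboring electrodes at the same timepoint; clusters are
// sign-homogeneous. Cluster mass is sum over members of (|t| - thresh)^weight.
//
// adj: list (length = n channels) of 1-based neighbor index vectors.
// Returns labels (0 = sub-threshold), per-cluster mass and sign.
// [[Rcpp::export]]
List label_clusters_cpp(NumericMatrix t_map, List adj, double thresh,
                        double weight) {
  const int nc = t_map.nrow(), nt = t_map.ncol();
  if (adj.size() != nc) stop("adjacency list length must equal channel count");
  std::vector<std::vector<int> > nb(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector v = adj[c];
    nb[c].reserve(v.size());
    for (int i = 0; i < v.size(); ++i) nb[c].push_back(v[i] - 1);
  }
  IntegerMatrix labels(nc, nt);
  std::vector<double> masses;
  std::vector<int> signs;
  std::vector<int> stack;
  stack.reserve(nc * 4);
  int next_label = 0;
  for (int t = 0; t < nt; ++t) {
    for (int c = 0; c < nc; ++c) {
      const double v = t_map(c, t);
      if (labels(c, t) != 0 || std::fabs(v) <= thresh) continue;
      const int sgn = v > 0 ? 1 : -1;
      ++next_label;
      double mass = 0.0;
      stack.clear();
      stack.push_back(c + nc * t);
      labels(c, t) = next_label;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cc = idx % nc, tt = idx / nc;
        mass += std::pow(std::fabs(t_map(cc, tt)) - thresh, weight);
        // temporal neighbors, same electrode
        for (int dt = -1; dt <= 1; dt += 2) {
          const int t2 = tt + dt;
          if (t2 < 0 || t2 >= nt) continue;
          const double w = t_map(cc, t2);
          if (labels(cc, t2) == 0 && std::fabs(w) > thresh &&
              ((w > 0) ? 1 : -1) == sgn) {
            labels(cc, t2) = next_label;
            stack.push_back(cc + nc * t2);
          }
        }
        // spatial neighbors, same timepoint
        for (size_t k = 0; k < nb[cc].size(); ++k) {
          const int c2 = nb[cc][k];
          const double w = t_map(c2, tt);
          if (labels(c2, tt) == 0 && std::fabs(w) > thresh &&
              ((w > 0) ? 1 : -1) == sgn) {
            labels(c2, tt) = next_label;
            stack.push_back(c2 + nc * tt);
          }
        }
      }
      masses.push_back(mass);
      signs.push_back(sgn);
    }
  }
  return List::create(_["labels"] = labels, _["mass"] = wrap(masses),
                      _["sign"] = wrap(signs));
}

// Maximum cluster mass per sign for one permutation t-map, given as a flat
// vector (channel-fastest). Returns c(max positive mass, max negative mass),
// 0 when no cluster of that sign exists.
// [[Rcpp::export]]
NumericVector max_cluster_mass_cpp(NumericVector t_flat, int nc, int nt,
                                   List adj, double thresh, double weight) {
  if ((int)t_flat.size() != nc * nt) stop("t vector length mismatch");
  std::vector<std::vector<int> > nb(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector v = adj[c];
    nb[c].reserve(v.size());
    for (int i = 0; i < v.size(); ++i) nb[c].push_back(v[i] - 1);
  }
  std::vector<char> seen(nc * nt, 0);
  std::vector<int> stack;
  double max_pos = 0.0, max_neg = 0.0;
  for (int idx0 = 0; idx0 < nc * nt; ++idx0) {
    const double v = t_flat[idx0];
    if (seen[idx0] || std::fabs(v) <= thresh) continue;
    const int sgn = v > 0 ? 1 : -1;
    double mass = 0.0;
    stack.clear();
    stack.push_back(idx0);
    seen[idx0] = 1;
    while (!stack.empty()) {
      const int idx = stack.back();
      stack.pop_back();
      const int cc = idx % nc, tt = idx / nc;
      mass += std::pow(std::fabs(t_flat[idx]) - thresh, weight);
      for (int dt = -1; dt <= 1; dt += 2) {
        const int t2 = tt + dt;
        if (t2 < 0 || t2 >= nt) continue;
        const int j = cc + nc * t2;
        const double w = t_flat[j];
        if (!seen[j] && std::fabs(w) > thresh && ((w > 0) ? 1 : -1) == sgn) {
          seen[j] = 1;
          stack.push_back(j);
        }
      }
      for (size_t k = 0; k < nb[cc].size(); ++k) {
        const int j = nb[cc][k] + nc * tt;
        const double w = t_flat[j];
        if (!seen[j] && std::fabs(w) > thresh && ((w > 0) ? 1 : -1) == sgn) {
          seen[j] = 1;
          stack.push_back(j);
        }
      }
    }
    if (sgn > 0) {
      if (mass > max_pos) max_pos = mass;
    } else {
      if (mass > max_neg) max_neg = mass;
    }
  }
  return NumericVector::create(max_pos, max_neg);
}
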