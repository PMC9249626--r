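#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Claim pixels for labelled segments by exact Euclidean distance.
//
// For every allowed pixel, find the nearest boundary pixel of any labelled
// segment whose per-label maximum claim distance covers it. Ties are broken
// to the smaller distance, then to the lower label id. Distances are exact
// (squared integer offsets compared in double, which is lossless here).
//
// seeds:    integer matrix of segment labels, 0 = none
// allowed:  logical matrix marking pixels that may be claimed
// max_dist: per-label claim radius in pixels, indexed by label id
//           (<= 0 means the label never claims)
//
// Candidate seed pixels are restricted to label boundaries (a nearest seed
// pixel of a label, seen from outside it, is always on its boundary) and
// bucketed on a grid of the maximum radius so each query scans only the
// 3x3 neighbouring buckets.
// [[Rcpp::export]]
IntegerMatrix assign_nearest_label_cpp(IntegerMatrix seeds,
                                       LogicalMatrix allowed,
                                       NumericVector max_dist) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  if (allowed.nrow() != nr || allowed.ncol() != nc)
    stop("'seeds' and 'allowed' must have identical dimensions");

  int max_label = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > max_label) max_label = seeds(i, j);
  if (max_label > max_dist.size())
    stop("'max_dist' must supply a radius for every label");

  std::vector<double> md2(max_label + 1, -1.0);
  double rmax = 1.0;
  for (int l = 1; l <= max_label; ++l) {
    double r = max_dist[l - 1];
    if (R_finite(r) && r > 0) {
      md2[l] = r * r;
      if (r > rmax) rmax = r;
    }
  }

  const int bin = (int)std::ceil(rmax);
  const int gr = nr / bin + 1, gc = nc / bin + 1;
  std::vector< std::vector<int> > bucket((size_t)gr * gc);

  // boundary seed pixels: any 4-neighbour differs (or image edge)
  std::vector<int> brow, bcol, blab;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int l = seeds(i, j);
      if (l <= 0 || md2[l] < 0) continue;
      bool edge = (i == 0 || i == nr - 1 || j == 0 || j == nc - 1);
      if (!edge &&
          seeds(i - 1, j) == l && seeds(i + 1, j) == l &&
          seeds(i, j - 1) == l && seeds(i, j + 1) == l)
        continue;
      int idx = (int)brow.size();
      brow.push_back(i); bcol.push_back(j); blab.push_back(l);
      bucket[(size_t)(i / bin) * gc + (j / bin)].push_back(idx);
    }
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!allowed(i, j) || seeds(i, j) != 0) continue;
      const int bi = i / bin, bj = j / bin;
      double best = R_PosInf;
      int best_lab = 0;
      for (int di = -1; di <= 1; ++di) {
        const int gi = bi + di;
        if (gi < 0 || gi >= gr) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int gj = bj + dj;
          if (gj < 0 || gj >= gc) continue;
          const std::vector<int> &cand = bucket[(size_t)gi * gc + gj];
          for (size_t k = 0; k < cand.size(); ++k) {
            const int c = cand[k];
            const double dr = (double)(i - brow[c]);
            const double dc = (double)(j - bcol[c]);
            const double d2 = dr * dr + dc * dc;
            const int l = blab[c];
            if (d2 > md2[l]) continue;
            if (d2 < best || (d2 == best && l < best_lab)) {
              best = d2;
              best_lab = l;
            }
          }
        }
      }
      out(i, j) = best_lab;
    }
  }
  return out;
}
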