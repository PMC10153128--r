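#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected components of supra-threshold bins in a 2-D statistic map,
// positive (z > thresh) and negative (z < -thresh) bins labelled separately.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).

static void flood(const NumericMatrix& z, IntegerMatrix& lab, int r0, int c0,
                  int label, int sgn, double thresh, int conn) {
  const int nr = z.nrow(), nc = z.ncol();
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(r0, c0));
  lab(r0, c0) = label;
  static const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  static const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (conn == 8) ? dr8 : dr4;
  const int* dc = (conn == 8) ? dc8 : dc4;
  const int nd = (conn == 8) ? 8 : 4;
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int k = 0; k < nd; ++k) {
      const int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (lab(r, c) != 0) continue;
      const double v = z(r, c);
      if ((sgn > 0 && v > thresh) || (sgn < 0 && v < -thresh)) {
        lab(r, c) = label;
        stack.push_back(std::make_pair(r, c));
      }
    }
  }
}

// [[Rcpp::export(name = ".label_clusters")]]
List label_clusters(NumericMatrix z, double thresh, int conn) {
  const int nr = z.nrow(), nc = z.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> masses;
  std::vector<int> signs;
  int label = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) != 0) continue;
      const double v = z(r, c);
      if (!(v > thresh || v < -thresh)) continue;
      const int sgn = v > 0 ? 1 : -1;
      flood(z, lab, r, c, ++label, sgn, thresh, conn);
      signs.push_back(sgn);
      masses.push_back(0.0);
    }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) masses[lab(r, c) - 1] += z(r, c);
  return List::create(_["labels"] = lab,
                      _["mass"] = NumericVector(masses.begin(), masses.end()),
                      _["sign"] = IntegerVector(signs.begin(), signs.end()));
}

// Maximum absolute cluster mass over both signs (used for the permutation null).
// [[Rcpp::export(name = ".max_cluster_mass")]]
double max_cluster_mass(NumericMatrix z, double thresh, int conn) {
  List res = label_clusters(z, thresh, conn);
  NumericVector mass = res["mass"];
  double best = 0.0;
  for (R_xlen_t i = 0; i < mass.size(); ++i)
    best = std::max(best, std::fabs(mass[i]));
  return best;
}
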