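#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Static balanced kd-tree over 3-D reference points. Built once per query
// batch; nodes are stored implicitly (heap layout) over a permutation of
// point indices. Sufficient for the 1e3-1e5 point clouds the surface
// pipeline works with.

namespace {

struct KD {
  const double *x, *y, *z;
  std::vector<int> perm;         // point index per slot
  std::vector<int> axis;         // split axis per node (-1 = leaf span)
  std::vector<double> splitval;  // split coordinate per node (fixed at build)
  int n;

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  void build(int node, int lo, int hi) {
    if (hi - lo <= 1) return;
    // split on widest extent
    double mn[3], mx[3];
    for (int a = 0; a < 3; ++a) { mn[a] = R_PosInf; mx[a] = R_NegInf; }
    for (int k = lo; k < hi; ++k)
      for (int a = 0; a < 3; ++a) {
        double v = coord(perm[k], a);
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int ax = 0;
    double best = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > best) { best = mx[a] - mn[a]; ax = a; }
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    axis[node] = ax;
    splitval[node] = coord(perm[mid], ax);  // perm shifts below; value won't
    build(2 * node + 1, lo, mid);
    build(2 * node + 2, mid, hi);
  }

  void search(int node, int lo, int hi, double qx, double qy, double qz,
              double &bestd2, int &besti) const {
    if (hi - lo <= 8) {  // leaf scan
      for (int k = lo; k < hi; ++k) {
        int i = perm[k];
        double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < bestd2) { bestd2 = d2; besti = i; }
      }
      return;
    }
    int ax = axis[node];
    int mid = (lo + hi) / 2;
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double diff = q - splitval[node];
    if (diff < 0) {
      search(2 * node + 1, lo, mid, qx, qy, qz, bestd2, besti);
      if (diff * diff < bestd2)
        search(2 * node + 2, mid, hi, qx, qy, qz, bestd2, besti);
    } else {
      search(2 * node + 2, mid, hi, qx, qy, qz, bestd2, besti);
      if (diff * diff < bestd2)
        search(2 * node + 1, lo, mid, qx, qy, qz, bestd2, besti);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List nn_kdtree(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("reference point set is empty");
  if (query.ncol() != 3 || ref.ncol() != 3) stop("points must be m x 3");

  NumericMatrix refc = clone(ref);  // column-contiguous access
  KD kd;
  kd.n = nr;
  kd.x = &refc(0, 0);
  kd.y = &refc(0, 1);
  kd.z = &refc(0, 2);
  kd.perm.resize(nr);
  for (int i = 0; i < nr; ++i) kd.perm[i] = i;
  // implicit binary tree needs at most 4*n nodes at leaf size 8
  kd.axis.assign(std::max(4 * nr, 16), -1);
  kd.splitval.assign(kd.axis.size(), 0.0);
  kd.build(0, 0, nr);

  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double bestd2 = R_PosInf;
    int besti = 0;
    kd.search(0, 0, nr, query(i, 0), query(i, 1), query(i, 2), bestd2, besti);
    idx[i] = besti + 1;
    dist[i] = std::sqrt(bestd2);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
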