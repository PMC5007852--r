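#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-neighbour offsets
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Greyscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm): raster + anti-raster sweep, then FIFO propagation. marker must
// be <= mask everywhere; the result is the largest image <= mask whose
// regional maxima are seeded by marker.
// [[Rcpp::export]]
NumericMatrix reconstruct_dilate_cpp(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));

  // raster scan: neighbours already visited (N+ in raster order)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      if (r > 0) {
        v = std::max(v, J(r - 1, c));
        if (c > 0) v = std::max(v, J(r - 1, c - 1));
        if (c < nc - 1) v = std::max(v, J(r - 1, c + 1));
      }
      if (c > 0) v = std::max(v, J(r, c - 1));
      J(r, c) = std::min(v, mask(r, c));
    }
  }
  // anti-raster scan, queue pixels with lower propagatable neighbours
  std::queue<std::pair<int, int> > fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      if (r < nr - 1) {
        v = std::max(v, J(r + 1, c));
        if (c > 0) v = std::max(v, J(r + 1, c - 1));
        if (c < nc - 1) v = std::max(v, J(r + 1, c + 1));
      }
      if (c < nc - 1) v = std::max(v, J(r, c + 1));
      J(r, c) = std::min(v, mask(r, c));
      // enqueue if some anti-raster neighbour could still grow
      bool enq = false;
      for (int k = 0; k < 8 && !enq; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) enq = true;
      }
      if (enq) fifo.push(std::make_pair(r, c));
    }
  }
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    double v = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < v && J(rr, cc) < mask(rr, cc)) {
        J(rr, cc) = std::min(v, mask(rr, cc));
        fifo.push(std::make_pair(rr, cc));
      }
    }
  }
  return J;
}

// Label the regional-maxima plateaus of img (8-connectivity). A plateau is a
// connected set of equal-valued pixels; it is a regional maximum if no pixel
// bordering the plateau is strictly brighter. Returns an integer matrix with
// 0 for non-maximum pixels and 1..K for maxima plateaus.
// [[Rcpp::export]]
IntegerMatrix regional_maxima_cpp(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);           // 0 unvisited
  std::vector<int> stack_r, stack_c;
  int next_label = 0;
  std::vector<std::pair<int, int> > plateau;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (lab(r0, c0) != 0) continue;
      double v = img(r0, c0);
      // flood the plateau of value v containing (r0, c0)
      plateau.clear();
      bool is_max = true;
      stack_r.clear(); stack_c.clear();
      stack_r.push_back(r0); stack_c.push_back(c0);
      lab(r0, c0) = -1;                // temporary visiting mark
      while (!stack_r.empty()) {
        int r = stack_r.back(), c = stack_c.back();
        stack_r.pop_back(); stack_c.pop_back();
        plateau.push_back(std::make_pair(r, c));
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double w = img(rr, cc);
          if (w > v) { is_max = false; continue; }
          if (w == v && lab(rr, cc) == 0) {
            lab(rr, cc) = -1;
            stack_r.push_back(rr); stack_c.push_back(cc);
          }
        }
      }
      int id = is_max ? ++next_label : -2;  // -2 = definitively not a maximum
      for (size_t i = 0; i < plateau.size(); ++i)
        lab(plateau[i].first, plateau[i].second) = id;
    }
  }
  for (int i = 0; i < nr * nc; ++i)
    if (lab[i] < 0) lab[i] = 0;
  return lab;
}
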