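#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a logical/integer matrix (nonzero = fg).
// Labels are assigned in raster-scan discovery order starting at 1.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix& bin) {
  const int h = bin.nrow(), w = bin.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!bin(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
            if (bin(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.emplace_back(rr, cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

namespace {
struct FloodItem {
  double elev;   // -dmap value: lower pops first
  int row, col;
  long long order; // insertion index, breaks remaining ties
  int label;
};
struct FloodCmp {
  // priority_queue pops the *largest* under this comparator, so invert:
  // we want smallest (elev, row, col, order) first.
  bool operator()(const FloodItem& a, const FloodItem& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    if (a.row != b.row) return a.row > b.row;
    if (a.col != b.col) return a.col > b.col;
    return a.order > b.order;
  }
};
} // namespace

// Marker-controlled priority flood over elevation = -dmap, restricted to
// fill_mask. First arrival labels a pixel; the queue orders by
// (-dmap, row, col, insertion index) so results are order-independent and
// bit-reproducible. Fill pixels unreachable from any marker stay 0.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(const NumericMatrix& dmap,
                              const IntegerMatrix& markers,
                              const LogicalMatrix& fill) {
  const int h = dmap.nrow(), w = dmap.ncol();
  if (markers.nrow() != h || markers.ncol() != w ||
      fill.nrow() != h || fill.ncol() != w)
    stop("dmap, markers and fill mask must share shape");
  IntegerMatrix out(h, w);
  std::priority_queue<FloodItem, std::vector<FloodItem>, FloodCmp> pq;
  long long order = 0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (markers(i, j) > 0 && fill(i, j))
        pq.push({-dmap(i, j), i, j, order++, markers(i, j)});
  while (!pq.empty()) {
    FloodItem it = pq.top();
    pq.pop();
    if (out(it.row, it.col)) continue;
    out(it.row, it.col) = it.label;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int rr = it.row + dr, cc = it.col + dc;
        if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
        if (fill(rr, cc) && !out(rr, cc))
          pq.push({-dmap(rr, cc), rr, cc, order++, it.label});
      }
    }
  }
  return out;
}
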