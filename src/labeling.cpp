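#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 4-connected component labeling of a logical mask. Background (FALSE) gets
// label 0; components are numbered 1..k in column-major scan order of their
// first pixel (R's native matrix order), which makes labeling deterministic.
// [[Rcpp::export(name = ".cc_label_4")]]
IntegerMatrix cc_label_4(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        int cy = q.front().first, cx = q.front().second;
        q.pop();
        const int dy[4] = {-1, 1, 0, 0};
        const int dx[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int ny = cy + dy[d], nx = cx + dx[d];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            q.push(std::make_pair(ny, nx));
          }
        }
      }
    }
  }
  return lab;
}

// Label the faces of a figure partitioned by cut-line "walls". Walls sit on
// the half-open pixel lattice: vwalls rows are (x, y0, y1) blocking
// 4-adjacency between columns x-1 and x for rows y in [y0, y1); hwalls rows
// are (y, x0, x1) blocking rows y-1 / y for columns x in [x0, x1). All
// coordinates 0-based. Every pixel receives a region id 1..k.
// [[Rcpp::export(name = ".region_label_walls")]]
IntegerMatrix region_label_walls(int H, int W, const IntegerMatrix& vwalls,
                                 const IntegerMatrix& hwalls) {
  std::vector<unsigned char> blockV((size_t)H * W, 0); // left edge of (x,y)
  std::vector<unsigned char> blockH((size_t)H * W, 0); // top edge of (x,y)
  for (int r = 0; r < vwalls.nrow(); ++r) {
    int x = vwalls(r, 0), y0 = vwalls(r, 1), y1 = vwalls(r, 2);
    if (x <= 0 || x >= W) continue;
    for (int y = std::max(0, y0); y < std::min(H, y1); ++y)
      blockV[(size_t)y * W + x] = 1;
  }
  for (int r = 0; r < hwalls.nrow(); ++r) {
    int y = hwalls(r, 0), x0 = hwalls(r, 1), x1 = hwalls(r, 2);
    if (y <= 0 || y >= H) continue;
    for (int x = std::max(0, x0); x < std::min(W, x1); ++x)
      blockH[(size_t)y * W + x] = 1;
  }
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        int cy = q.front().first, cx = q.front().second;
        q.pop();
        // left
        if (cx > 0 && !blockV[(size_t)cy * W + cx] && lab(cy, cx - 1) == 0) {
          lab(cy, cx - 1) = next; q.push(std::make_pair(cy, cx - 1));
        }
        // right
        if (cx + 1 < W && !blockV[(size_t)cy * W + cx + 1] &&
            lab(cy, cx + 1) == 0) {
          lab(cy, cx + 1) = next; q.push(std::make_pair(cy, cx + 1));
        }
        // up
        if (cy > 0 && !blockH[(size_t)cy * W + cx] && lab(cy - 1, cx) == 0) {
          lab(cy - 1, cx) = next; q.push(std::make_pair(cy - 1, cx));
        }
        // down
        if (cy + 1 < H && !blockH[(size_t)(cy + 1) * W + cx] &&
            lab(cy + 1, cx) == 0) {
          lab(cy + 1, cx) = next; q.push(std::make_pair(cy + 1, cx));
        }
      }
    }
  }
  return lab;
}
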