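// Buffer delineation on planar rasters.
//
// Round buffers: all cells whose centers lie within `size` meters of the
// site coordinate (the site's own cell is always included). Catchment
// buffers: the gap-bridged connected component, grown from the site cell,
// of round-buffer cells whose elevation is at least site elevation minus
// drop_m; two qualifying cells are connected when their centers are within
// gap_m meters of each other. Non-finite drop_m makes every round cell
// qualify; non-finite gap_m drops the connectivity requirement altogether.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

struct Window {
  int r0, c0, H, W;
};

// Neighbor offsets whose center-to-center distance is <= gap_m. For
// gap_m < res this degenerates; a 4- or 8-neighborhood is used instead,
// selected by `neigh`.
std::vector<std::pair<int, int>> make_offsets(double gap_m, double res, int neigh) {
  std::vector<std::pair<int, int>> off;
  int g = (int)std::floor(gap_m / res + 1e-9);
  if (g < 1) {
    off.push_back({-1, 0}); off.push_back({1, 0});
    off.push_back({0, -1}); off.push_back({0, 1});
    if (neigh == 8) {
      off.push_back({-1, -1}); off.push_back({-1, 1});
      off.push_back({1, -1});  off.push_back({1, 1});
    }
    return off;
  }
  double g2 = (gap_m / res) * (gap_m / res) + 1e-9;
  for (int dr = -g; dr <= g; ++dr)
    for (int dc = -g; dc <= g; ++dc) {
      if (dr == 0 && dc == 0) continue;
      if ((double)dr * dr + (double)dc * dc <= g2) off.push_back({dr, dc});
    }
  return off;
}

// Fill `in` (over the window) with region membership; returns truncation flag.
bool build_region(const NumericMatrix& dem, double sx, double sy, double selev,
                  double size_m, bool catchment, double xll, double yll,
                  double res, double drop_m, double gap_m, int neigh,
                  Window& win, std::vector<unsigned char>& in) {
  const int ny = dem.nrow(), nx = dem.ncol();
  bool truncated = (sx - size_m < xll) || (sx + size_m > xll + nx * res) ||
                   (sy - size_m < yll) || (sy + size_m > yll + ny * res);

  int cs = (int)std::floor((sx - xll) / res);
  int rs = ny - 1 - (int)std::floor((sy - yll) / res);
  if (cs < 0) cs = 0; if (cs > nx - 1) cs = nx - 1;
  if (rs < 0) rs = 0; if (rs > ny - 1) rs = ny - 1;

  int c0 = (int)std::floor((sx - size_m - xll) / res - 0.5);
  int c1 = (int)std::ceil((sx + size_m - xll) / res - 0.5);
  int r0 = (int)std::floor((double)ny - 0.5 - (sy + size_m - yll) / res);
  int r1 = (int)std::ceil((double)ny - 0.5 - (sy - size_m - yll) / res);
  if (c0 > cs) c0 = cs; if (c1 < cs) c1 = cs;
  if (r0 > rs) r0 = rs; if (r1 < rs) r1 = rs;
  if (c0 < 0) c0 = 0; if (c1 > nx - 1) c1 = nx - 1;
  if (r0 < 0) r0 = 0; if (r1 > ny - 1) r1 = ny - 1;

  win.r0 = r0; win.c0 = c0;
  win.H = r1 - r0 + 1; win.W = c1 - c0 + 1;
  const int H = win.H, W = win.W;
  in.assign((size_t)H * W, 0);

  const double size2 = size_m * size_m;
  const double thr = R_finite(drop_m) ? selev - drop_m : R_NegInf;

  // membership codes: 1 = in round buffer, 2 = qualifying for catchment
  std::vector<unsigned char> qual((size_t)H * W, 0);
  for (int r = r0; r <= r1; ++r) {
    double cy = yll + ((double)ny - r - 0.5) * res;
    double dy2 = (cy - sy) * (cy - sy);
    for (int c = c0; c <= c1; ++c) {
      double cx = xll + (c + 0.5) * res;
      double d2 = (cx - sx) * (cx - sx) + dy2;
      if (d2 <= size2) {
        size_t k = (size_t)(r - r0) * W + (c - c0);
        qual[k] = 1;
        if (!catchment || dem(r, c) >= thr) qual[k] = 2;
      }
    }
  }
  size_t ks = (size_t)(rs - r0) * W + (cs - c0);
  if (!catchment) {
    for (size_t k = 0; k < qual.size(); ++k) in[k] = qual[k] >= 1;
    in[ks] = 1;  // site cell always included
    return truncated;
  }

  if (!R_finite(gap_m)) {  // connectivity waived: all qualifying cells
    for (size_t k = 0; k < qual.size(); ++k) in[k] = qual[k] == 2;
    in[ks] = 1;
    return truncated;
  }

  // Region growing in two alternating phases. Phase A: ordinary 8-connected
  // flood fill over qualifying cells (covers the bulk). Phase B: gap
  // bridging -- the full <=gap_m offset disk is applied only at boundary
  // cells (region cells with a non-region 8-neighbor); any qualifying cell
  // within gap_m of an interior cell is also within gap_m of a boundary
  // cell, so this is exact.
  std::vector<std::pair<int, int>> off = make_offsets(gap_m, res, neigh);
  const int n8r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int n8c[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::queue<std::pair<int, int>> q;
  std::vector<std::pair<int, int>> boundary;
  in[ks] = 1;
  q.push({rs - r0, cs - c0});
  bool small_gap = gap_m < res;  // plain 4/8-neighborhood connectivity
  // diagonal steps are only valid adjacency if their length fits the gap
  bool diag_ok = small_gap ? (neigh == 8)
                           : (2 * res * res <= gap_m * gap_m + 1e-9);
  while (true) {
    while (!q.empty()) {  // phase A
      std::pair<int, int> cur = q.front(); q.pop();
      bool is_boundary = false;
      for (int j = 0; j < 8; ++j) {
        int nr = cur.first + n8r[j], nc = cur.second + n8c[j];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) { is_boundary = true; continue; }
        size_t k = (size_t)nr * W + nc;
        if (qual[k] == 2) {
          bool diag = n8r[j] != 0 && n8c[j] != 0;
          if (!in[k] && (!diag || diag_ok)) {
            in[k] = 1;
            q.push({nr, nc});
          }
        } else {
          is_boundary = true;
        }
      }
      if (is_boundary && !small_gap) boundary.push_back(cur);
    }
    if (small_gap || boundary.empty()) break;
    bool grew = false;  // phase B
    for (size_t i = 0; i < boundary.size(); ++i) {
      for (size_t j = 0; j < off.size(); ++j) {
        int nr = boundary[i].first + off[j].first;
        int nc = boundary[i].second + off[j].second;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        size_t k = (size_t)nr * W + nc;
        if (!in[k] && qual[k] == 2) {
          in[k] = 1;
          q.push({nr, nc});
          grew = true;
        }
      }
    }
    boundary.clear();
    if (!grew) break;
  }
  return truncated;
}

}  // namespace

// [[Rcpp::export(name = ".region_cells_cpp")]]
List region_cells_cpp(NumericMatrix dem, double sx, double sy, double selev,
                      double size_m, bool catchment, double xll, double yll,
                      double res, double drop_m, double gap_m, int neigh) {
  Window win;
  std::vector<unsigned char> in;
  bool truncated = build_region(dem, sx, sy, selev, size_m, catchment, xll, yll,
                                res, drop_m, gap_m, neigh, win, in);
  int n = 0;
  for (size_t k = 0; k < in.size(); ++k) n += in[k];
  IntegerMatrix cells(n, 2);
  int i = 0;
  for (int r = 0; r < win.H; ++r)
    for (int c = 0; c < win.W; ++c)
      if (in[(size_t)r * win.W + c]) {
        cells(i, 0) = win.r0 + r + 1;  // 1-based
        cells(i, 1) = win.c0 + c + 1;
        ++i;
      }
  return List::create(_["cells"] = cells, _["truncated"] = truncated);
}

// Per-site land-use class counts over the buffer region, for one
// (size, type) combination across all sites at once.
// [[Rcpp::export(name = ".region_class_counts_cpp")]]
List region_class_counts_cpp(NumericMatrix dem, IntegerMatrix landuse,
                             int nclass, NumericVector sx, NumericVector sy,
                             NumericVector selev, double size_m, bool catchment,
                             double xll, double yll, double res, double drop_m,
                             double gap_m, int neigh) {
  const int nsite = sx.size();
  IntegerMatrix counts(nsite, nclass);
  IntegerVector ncells(nsite);
  LogicalVector truncated(nsite);
  Window win;
  std::vector<unsigned char> in;
  for (int i = 0; i < nsite; ++i) {
    truncated[i] = build_region(dem, sx[i], sy[i], selev[i], size_m, catchment,
                                xll, yll, res, drop_m, gap_m, neigh, win, in);
    int tot = 0;
    for (int r = 0; r < win.H; ++r)
      for (int c = 0; c < win.W; ++c)
        if (in[(size_t)r * win.W + c]) {
          int code = landuse(win.r0 + r, win.c0 + c);
          if (code >= 1 && code <= nclass) counts(i, code - 1) += 1;
          ++tot;
        }
    ncells[i] = tot;
  }
  return List::create(_["counts"] = counts, _["ncells"] = ncells,
                      _["truncated"] = truncated);
}
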