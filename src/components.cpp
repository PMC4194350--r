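#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8- (or 4-) connected component labelling of a 0/1 mask by flood fill.
// mask is indexed [x, y] (column = image row, as in EBImage arrays).
// Labels are assigned 1..n in raster order (y outer, x inner) of each
// component's first pixel, which is also the scan order here.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int connectivity) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int dy4[4] = {-1, 0, 0, 1};
  const int *dx = (connectivity == 4) ? dx4 : dx8;
  const int *dy = (connectivity == 4) ? dy4 : dy8;
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      if (mask(x, y) == 0 || lab(x, y) != 0) continue;
      ++next;
      lab(x, y) = next;
      stack.clear();
      stack.push_back(x + y * nx);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cx = idx % nx, cy = idx / nx;
        for (int k = 0; k < nn; ++k) {
          int qx = cx + dx[k], qy = cy + dy[k];
          if (qx < 0 || qy < 0 || qx >= nx || qy >= ny) continue;
          if (mask(qx, qy) != 0 && lab(qx, qy) == 0) {
            lab(qx, qy) = next;
            stack.push_back(qx + qy * nx);
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour border following with Jacob's stopping criterion.
// Returns the length of the closed polygon through the centres of the
// outer border pixels: 1 per axial step, sqrt(2) per diagonal step.
// mask must contain a single 8-connected component with a one-pixel
// zero margin on every side. Components visited by fewer than 3 distinct
// border pixels get length 0 (degenerate contour convention).
// [[Rcpp::export(name = ".trace_boundary")]]
double trace_boundary(const IntegerMatrix& mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  // clockwise Moore neighbourhood, y pointing down: W NW N NE E SE S SW
  const int dx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dy[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  int sx = -1, sy = -1;
  for (int y = 0; y < ny && sx < 0; ++y)
    for (int x = 0; x < nx; ++x)
      if (mask(x, y) != 0) { sx = x; sy = y; break; }
  if (sx < 0) return 0.0;
  long npix = 0;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      if (mask(x, y) != 0) ++npix;
  if (npix < 3) return 0.0;

  int px = sx, py = sy;
  int searchdir = 0;  // backtrack of the start pixel is its W neighbour
  double len = 0.0;
  int firstx = -1, firsty = -1, firstdir = -1;
  bool have_first = false;
  long maxit = 8 * npix + 16;
  for (long it = 0; it < maxit; ++it) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {  // start AFTER the backtrack position
      int d = (searchdir + k) % 8;
      int qx = px + dx[d], qy = py + dy[d];
      if (qx < 0 || qy < 0 || qx >= nx || qy >= ny) continue;
      if (mask(qx, qy) != 0) { found = d; break; }
    }
    if (found < 0) return 0.0;  // isolated pixel (cannot happen for npix >= 3)
    int qx = px + dx[found], qy = py + dy[found];
    if (have_first && qx == firstx && qy == firsty && found == firstdir)
      return len;  // re-entered the first boundary move identically: closed
    if (!have_first) {
      firstx = qx; firsty = qy; firstdir = found;
      have_first = true;
    }
    len += (dx[found] != 0 && dy[found] != 0) ? M_SQRT2 : 1.0;
    // new backtrack is the neighbour checked just before the hit
    int bdir = (found + 7) % 8;
    int bx = px + dx[bdir], by = py + dy[bdir];
    px = qx; py = qy;
    // direction index pointing from the new pixel to the backtrack pixel
    int rdx = bx - px, rdy = by - py;
    for (int d = 0; d < 8; ++d)
      if (dx[d] == rdx && dy[d] == rdy) { searchdir = d; break; }
  }
  return len;
}
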