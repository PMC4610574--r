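#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8- and 4-neighbourhood offsets (row, col)
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

static inline void neighbours(int connectivity, const int*& dr, const int*& dc,
                              int& n) {
  if (connectivity == 4) {
    dr = DR4; dc = DC4; n = 4;
  } else {
    dr = DR8; dc = DC8; n = 8;
  }
}

//' Label connected components of a binary mask.
//'
//' @param mask logical matrix.
//' @param connectivity 4 or 8.
//' @return integer matrix of component labels, 0 for background.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int *dr, *dc; int nn;
  neighbours(connectivity, dr, dc, nn);
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * H);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}

//' Label regional-maximum plateaus of a real-valued map inside an ROI.
//'
//' A plateau is a connected set of equal-valued ROI pixels; it is a regional
//' maximum when every ROI pixel adjacent to it (under the chosen
//' connectivity) has a strictly lower value. Pixels outside the ROI are
//' ignored entirely, so plateaus touching the ROI boundary are eligible.
//'
//' @param values numeric matrix.
//' @param roi logical matrix, same shape.
//' @param connectivity 4 or 8.
//' @return integer matrix: positive plateau label on regional-maximum
//'   pixels, 0 elsewhere.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix regional_maxima_labels(NumericMatrix values, LogicalMatrix roi,
                                     int connectivity) {
  const int H = values.nrow(), W = values.ncol();
  if (roi.nrow() != H || roi.ncol() != W)
    stop("`values` and `roi` must have identical dimensions");
  const int *dr, *dc; int nn;
  neighbours(connectivity, dr, dc, nn);

  IntegerMatrix lab(H, W);
  std::vector<char> visited((size_t)H * W, 0);
  std::vector<int> stack, plateau;
  int next = 0;

  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      size_t i0 = (size_t)r0 + (size_t)c0 * H;
      if (!roi(r0, c0) || visited[i0]) continue;
      const double v = values(r0, c0);
      bool is_max = true;
      plateau.clear();
      stack.clear();
      visited[i0] = 1;
      stack.push_back((int)i0);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int r = idx % H, c = idx / H;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (!roi(rr, cc)) continue;
          double w = values(rr, cc);
          if (w > v) {
            is_max = false;
          } else if (w == v) {
            size_t j = (size_t)rr + (size_t)cc * H;
            if (!visited[j]) {
              visited[j] = 1;
              stack.push_back((int)j);
            }
          }
        }
      }
      if (is_max) {
        ++next;
        for (size_t k = 0; k < plateau.size(); ++k) {
          int idx = plateau[k];
          lab(idx % H, idx / H) = next;
        }
      }
    }
  }
  return lab;
}

//' Grayscale morphological reconstruction by dilation.
//'
//' Hybrid raster/queue algorithm: one forward and one backward raster sweep,
//' then FIFO propagation. Used for the optional h-maxima suppression of
//' shallow peaks (marker = map - h, mask = map).
//'
//' @param marker numeric matrix, pointwise <= mask.
//' @param mask numeric matrix.
//' @param connectivity 4 or 8.
//' @return reconstructed numeric matrix.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix reconstruct_dilate(NumericMatrix marker, NumericMatrix mask,
                                 int connectivity) {
  const int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W)
    stop("`marker` and `mask` must have identical dimensions");
  NumericMatrix J(clone(marker));

  const bool eight = (connectivity != 4);
  // scanned-before neighbours for a column-major forward sweep
  // (column by column, rows top to bottom)
  std::vector<std::pair<int,int> > nplus, nminus;
  nplus.push_back(std::make_pair(-1, 0));
  nplus.push_back(std::make_pair(0, -1));
  if (eight) {
    nplus.push_back(std::make_pair(-1, -1));
    nplus.push_back(std::make_pair(1, -1));
  }
  for (size_t k = 0; k < nplus.size(); ++k)
    nminus.push_back(std::make_pair(-nplus[k].first, -nplus[k].second));

  // forward sweep
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double m = J(r, c);
      for (size_t k = 0; k < nplus.size(); ++k) {
        int rr = r + nplus[k].first, cc = c + nplus[k].second;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
    }

  // backward sweep + queue seeding
  std::queue<int> fifo;
  for (int c = W - 1; c >= 0; --c)
    for (int r = H - 1; r >= 0; --r) {
      double m = J(r, c);
      for (size_t k = 0; k < nminus.size(); ++k) {
        int rr = r + nminus[k].first, cc = c + nminus[k].second;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
      for (size_t k = 0; k < nminus.size(); ++k) {
        int rr = r + nminus[k].first, cc = c + nminus[k].second;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r + c * H);
          break;
        }
      }
    }

  const int *dr, *dc; int nn;
  neighbours(connectivity, dr, dc, nn);
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx % H, c = idx / H;
    double jp = J(r, c);
    for (int k = 0; k < nn; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (J(rr, cc) < jp && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(jp, mask(rr, cc));
        fifo.push(rr + cc * H);
      }
    }
  }
  return J;
}
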