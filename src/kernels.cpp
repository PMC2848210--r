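#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-connected component labelling of a logical mask.
// Labels are assigned in row-major scan order of each component's first
// pixel, so the output is fully deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Eroded-nucleus and cytoplasmic-ring compartments from a label image.
//
// Euclidean-distance definitions (pixels are points on the integer grid):
//  * a nucleus pixel survives erosion if its distance to the nearest pixel
//    NOT carrying the same label (anything outside the image counts as
//    background) is strictly greater than erosion_px;
//  * a background pixel belongs to the ring of the nucleus whose pixels are
//    nearest, when that distance d satisfies
//    ring_distance_px < d <= ring_distance_px + ring_width_px.
//    Equidistant claims go to the lower label id.
// Searches are local: the window radius is derived from the parameters,
// which are a few pixels in this assay.
// [[Rcpp::export(name = ".compartment_masks")]]
List compartment_masks(IntegerMatrix labels, double erosion_px,
                       double ring_distance_px, double ring_width_px) {
  const int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix nuc(nr, nc), ring(nr, nc);

  const double e2 = erosion_px * erosion_px;
  const int re = (int)std::ceil(erosion_px) + 1;
  const double rin = ring_distance_px;
  const double rout = ring_distance_px + ring_width_px;
  const double rin2 = rin * rin, rout2 = rout * rout;
  const int rr = (int)std::ceil(rout) + 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int lab = labels(i, j);
      if (lab > 0) {
        // erosion: min squared distance to a non-lab pixel
        double d2min = (double)(re + 1) * (re + 1);
        for (int dj = -re; dj <= re; ++dj) {
          for (int di = -re; di <= re; ++di) {
            if (di == 0 && dj == 0) continue;
            const double d2 = (double)di * di + (double)dj * dj;
            if (d2 >= d2min) continue;
            const int ii = i + di, jj = j + dj;
            const bool bg = (ii < 0 || ii >= nr || jj < 0 || jj >= nc) ||
                            labels(ii, jj) != lab;
            if (bg) d2min = d2;
          }
        }
        if (d2min > e2) nuc(i, j) = lab;
      } else if (ring_width_px > 0) {
        // ring: nearest nucleus pixel within the outer radius
        double d2min = rout2 + 1.0;
        int best = 0;
        for (int dj = -rr; dj <= rr; ++dj) {
          for (int di = -rr; di <= rr; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            const int l2 = labels(ii, jj);
            if (l2 == 0) continue;
            const double d2 = (double)di * di + (double)dj * dj;
            if (d2 < d2min || (d2 == d2min && l2 < best)) {
              d2min = d2;
              best = l2;
            }
          }
        }
        if (best > 0 && d2min > rin2 && d2min <= rout2) ring(i, j) = best;
      }
    }
  }
  return List::create(_["nuclear"] = nuc, _["ring"] = ring);
}

// Paint disks / annuli onto an intensity grid: for each cell k the pixels
// with inner_r[k] < dist(centre) <= outer_r[k] are set to value[k].
// Cells are painted in id order; later cells overwrite earlier ones.
// [[Rcpp::export(name = ".paint_annuli")]]
NumericMatrix paint_annuli(NumericMatrix img, NumericVector cx,
                           NumericVector cy, NumericVector inner_r,
                           NumericVector outer_r, NumericVector value) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);
  for (int k = 0; k < cx.size(); ++k) {
    const double x = cx[k], y = cy[k];
    const double ri2 = inner_r[k] > 0 ? inner_r[k] * inner_r[k] : -1.0;
    const double ro2 = outer_r[k] * outer_r[k];
    const int j0 = std::max(0, (int)std::floor(x - outer_r[k]) - 1);
    const int j1 = std::min(nc - 1, (int)std::ceil(x + outer_r[k]) + 1);
    const int i0 = std::max(0, (int)std::floor(y - outer_r[k]) - 1);
    const int i1 = std::min(nr - 1, (int)std::ceil(y + outer_r[k]) + 1);
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        const double dx = (j + 1) - x, dy = (i + 1) - y; // 1-based centres
        const double d2 = dx * dx + dy * dy;
        if (d2 > ri2 && d2 <= ro2) out(i, j) = value[k];
      }
    }
  }
  return out;
}
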