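#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Pixels are addressed by R's column-major linear index (idx = x*H + y).
// All tie-breaks use that index so results on an image crop agree with the
// same neighbourhood processed inside a larger image: comparing (x1*H+y1)
// with (x2*H+y2) gives the same order for any H > max(y).

namespace {

struct QItem {
  double h;
  int idx;
  bool operator>(const QItem& o) const {
    if (h != o.h) return h > o.h;
    return idx > o.idx;
  }
};

inline int nb4(int idx, int k, int H, int W) {
  // k in 0..3: up, down, left, right; returns -1 when outside
  int y = idx % H, x = idx / H;
  switch (k) {
    case 0: return (y > 0) ? idx - 1 : -1;
    case 1: return (y < H - 1) ? idx + 1 : -1;
    case 2: return (x > 0) ? idx - H : -1;
    default: return (x < W - 1) ? idx + H : -1;
  }
}

} // namespace

// Meyer-style flooding watershed from regional minima. Every pixel is
// assigned to a basin (1..N, full coverage, 4-connected growth); where two
// basins compete for a pixel the smaller basin id wins, which is the
// raster-scan-consistent deterministic rule. Boundary pixels are derived
// afterwards on the crack grid (see derive_regions() on the R side).
// [[Rcpp::export(name = ".ws_flood_cpp")]]
IntegerVector ws_flood_cpp(NumericVector height, int H, int W) {
  const int n = H * W;
  IntegerVector lab(n, -1); // -1 unvisited, 0 watershed line, >0 basin

  // 1) regional minima: 4-connected plateaus with no strictly lower neighbour
  std::vector<char> seen(n, 0);
  int nlab = 0;
  std::vector<int> plateau;
  for (int i = 0; i < n; ++i) {
    if (seen[i]) continue;
    // flood the equal-value plateau containing i
    plateau.clear();
    plateau.push_back(i);
    seen[i] = 1;
    bool is_min = true;
    double v = height[i];
    for (size_t q = 0; q < plateau.size(); ++q) {
      int p = plateau[q];
      for (int k = 0; k < 4; ++k) {
        int m = nb4(p, k, H, W);
        if (m < 0) continue;
        if (height[m] == v) {
          if (!seen[m]) { seen[m] = 1; plateau.push_back(m); }
        } else if (height[m] < v) {
          is_min = false;
        }
      }
    }
    if (is_min) {
      ++nlab;
      for (size_t q = 0; q < plateau.size(); ++q) lab[plateau[q]] = nlab;
    }
  }
  if (nlab == 0) { // flat pathological input: single region
    for (int i = 0; i < n; ++i) lab[i] = 1;
    return lab;
  }

  // 2) priority flood
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  std::vector<char> queued(n, 0);
  for (int i = 0; i < n; ++i) {
    if (lab[i] > 0) {
      for (int k = 0; k < 4; ++k) {
        int m = nb4(i, k, H, W);
        if (m >= 0 && lab[m] == -1 && !queued[m]) {
          queued[m] = 1;
          pq.push(QItem{height[m], m});
        }
      }
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int p = it.idx;
    if (lab[p] != -1) continue;
    int l0 = 0;
    for (int k = 0; k < 4; ++k) {
      int m = nb4(p, k, H, W);
      if (m < 0) continue;
      int lm = lab[m];
      if (lm > 0 && (l0 == 0 || lm < l0)) l0 = lm;
    }
    if (l0 == 0) continue;      // re-reached later via a labelled neighbour
    lab[p] = l0;
    for (int k = 0; k < 4; ++k) {
      int m = nb4(p, k, H, W);
      if (m >= 0 && lab[m] == -1 && !queued[m]) {
        queued[m] = 1;
        pq.push(QItem{height[m], m});
      }
    }
  }

  // leftovers (theoretical pockets): take the smallest labelled neighbour;
  // fully isolated components get fresh labels
  bool left = true;
  while (left) {
    left = false;
    for (int i = 0; i < n; ++i) {
      if (lab[i] != -1) continue;
      int l0 = 0;
      for (int k = 0; k < 4; ++k) {
        int m = nb4(i, k, H, W);
        if (m >= 0 && lab[m] > 0 && (l0 == 0 || lab[m] < l0)) l0 = lab[m];
      }
      if (l0 > 0) { lab[i] = l0; left = true; }
    }
    if (!left) {
      for (int i = 0; i < n; ++i) {
        if (lab[i] == -1) { lab[i] = ++nlab; left = true; break; }
      }
    }
  }
  return lab;
}

// Crack-boundary derivation from a full-coverage label raster. A pixel
// becomes a boundary (0) pixel iff its down or right neighbour survives
// (is non-zero in the result) with a different label. Because the rule
// only looks down/right, a single reverse raster-scan pass resolves it
// exactly; and no 2x2 all-zero block can exist (the top-left pixel of such
// a block would have both deciding neighbours zero). Two surviving pixels
// with different labels are never 4-adjacent.
// [[Rcpp::export(name = ".derive_crack_cpp")]]
IntegerVector derive_crack_cpp(IntegerVector full, int H, int W) {
  IntegerVector lab(H * W);
  for (int x = W - 1; x >= 0; --x) {
    for (int y = H - 1; y >= 0; --y) {
      int idx = x * H + y;
      int v = full[idx];
      bool zero = false;
      if (y + 1 < H) {
        int d = idx + 1;
        if (lab[d] != 0 && full[d] != v) zero = true;
      }
      if (!zero && x + 1 < W) {
        int r = idx + H;
        if (lab[r] != 0 && full[r] != v) zero = true;
      }
      lab[idx] = zero ? 0 : v;
    }
  }
  return lab;
}

// 4-connected component labelling of non-zero pixels, labels in column-major
// first-encounter order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, int H, int W) {
  const int n = H * W;
  IntegerVector lab(n, 0);
  int nlab = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++nlab;
    stack.clear();
    stack.push_back(i);
    lab[i] = nlab;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      for (int k = 0; k < 4; ++k) {
        int m = nb4(p, k, H, W);
        if (m >= 0 && mask[m] != 0 && lab[m] == 0) {
          lab[m] = nlab;
          stack.push_back(m);
        }
      }
    }
  }
  return lab;
}
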