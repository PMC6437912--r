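#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline int reflect(int i, int n) {
  // mirror boundary without edge repetition collapse (…2,1,0|0,1,2…)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

} // namespace

// Structured-forest contour voting. `channels` is an H x W x C array
// (column-major). Patch centre-window top-left corners are given as 0-based
// (cy, cx) pairs; the feature window of side d_in is centred on the d_out
// label window and read with mirrored borders. Every tree drops its leaf's
// d_out x d_out patch at the centre window; `acc`/`cnt` accumulate votes in
// the order the positions are supplied, so averaging is reproducible.
// [[Rcpp::export(name = ".forest_vote_cpp")]]
List forest_vote_cpp(NumericVector channels, int H, int W, int C,
                     int d_in, int d_out,
                     IntegerVector cy, IntegerVector cx,
                     List trees) {
  const int off = (d_in - d_out) / 2;
  const int plane = H * W;
  const int npos = cy.size();
  const int ntree = trees.size();
  NumericVector acc(plane);
  NumericVector cnt(plane);

  // unpack trees once
  std::vector<IntegerMatrix> nodes(ntree);
  std::vector<NumericVector> taus(ntree);
  std::vector<NumericMatrix> leaves(ntree);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    nodes[t] = as<IntegerMatrix>(tr["nodes"]);
    taus[t] = as<NumericVector>(tr["tau"]);
    leaves[t] = as<NumericMatrix>(tr["leaves"]);
  }

  const int dd = d_in * d_in;
  for (int i = 0; i < npos; ++i) {
    const int y0 = cy[i] - off, x0 = cx[i] - off;
    for (int t = 0; t < ntree; ++t) {
      const IntegerMatrix& nd = nodes[t];
      const NumericVector& tau = taus[t];
      int cur = 0; // root row
      while (nd(cur, 3) == 0) { // internal
        int k0 = nd(cur, 0) - 1;
        int c = k0 / dd, rem = k0 % dd;
        int xo = rem / d_in, yo = rem % d_in;
        int yy = reflect(y0 + yo, H), xx = reflect(x0 + xo, W);
        double v = channels[c * plane + xx * H + yy];
        cur = (v < tau[cur]) ? nd(cur, 1) - 1 : nd(cur, 2) - 1;
      }
      const int lrow = nd(cur, 3) - 1;
      const NumericMatrix& lv = leaves[t];
      for (int p = 0; p < d_out * d_out; ++p) {
        int yo = p % d_out, xo = p / d_out;
        int gy = cy[i] + yo, gx = cx[i] + xo;
        if (gy < 0 || gy >= H || gx < 0 || gx >= W) continue;
        acc[gx * H + gy] += lv(lrow, p);
        cnt[gx * H + gy] += 1.0;
      }
    }
  }
  return List::create(_["acc"] = acc, _["cnt"] = cnt);
}
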