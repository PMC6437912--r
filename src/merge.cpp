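#include <Rcpp.h>
#include <map>
#include <set>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find + region-adjacency merge engine shared by small-region
// cleanup, threshold merging and tree agglomeration. Merged-edge boundary
// strengths are length-weighted means. All tie-breaks use region ids
// (raster-scan order), keeping results consistent between an image crop
// and the full image.

namespace {

struct Eg { double B; double L; };

struct Engine {
  std::vector<int> parent;
  std::vector<std::map<int, Eg> > adj; // root -> neighbour root -> edge

  explicit Engine(int n) : parent(n + 1), adj(n + 1) {
    for (int i = 0; i <= n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  }
  // merge roots r, s; surviving root is min(r, s); returns it
  int unite(int r, int s) {
    int keep = std::min(r, s), drop = std::max(r, s);
    parent[drop] = keep;
    adj[keep].erase(drop);
    adj[drop].erase(keep);
    for (std::map<int, Eg>::iterator it = adj[drop].begin();
         it != adj[drop].end(); ++it) {
      int nbr = it->first;
      adj[nbr].erase(drop);
      std::map<int, Eg>::iterator ex = adj[keep].find(nbr);
      if (ex != adj[keep].end()) {
        double Lt = ex->second.L + it->second.L;
        ex->second.B = (ex->second.B * ex->second.L +
                        it->second.B * it->second.L) / Lt;
        ex->second.L = Lt;
        adj[nbr][keep] = ex->second;
      } else {
        adj[keep][nbr] = it->second;
        adj[nbr][keep] = it->second;
      }
    }
    adj[drop].clear();
    return keep;
  }
};

struct QEdge {
  double B; int a, b;
  bool operator>(const QEdge& o) const {
    if (B != o.B) return B > o.B;
    if (a != o.a) return a > o.a;
    return b > o.b;
  }
};

void load_edges(Engine& en, IntegerVector ia, IntegerVector ib,
                NumericVector B, NumericVector L) {
  for (int e = 0; e < ia.size(); ++e) {
    Eg eg; eg.B = B[e]; eg.L = L[e];
    en.adj[ia[e]][ib[e]] = eg;
    en.adj[ib[e]][ia[e]] = eg;
  }
}

} // namespace

// Greedy global merging: repeatedly merge the pair with minimum boundary
// strength while it passes the threshold test (strict: B < thr, otherwise
// B <= thr). Records the merge sequence (root ids at merge time and the
// strength) for tree construction. Returns roots plus the record.
// [[Rcpp::export(name = ".merge_greedy_cpp")]]
List merge_greedy_cpp(int n, IntegerVector ia, IntegerVector ib,
                      NumericVector B, NumericVector L,
                      double thr, bool strict) {
  Engine en(n);
  load_edges(en, ia, ib, B, L);
  std::priority_queue<QEdge, std::vector<QEdge>, std::greater<QEdge> > pq;
  for (int e = 0; e < ia.size(); ++e) {
    QEdge q; q.B = B[e]; q.a = std::min(ia[e], ib[e]);
    q.b = std::max(ia[e], ib[e]);
    pq.push(q);
  }
  std::vector<int> mr, ms;
  std::vector<double> mB;
  while (!pq.empty()) {
    QEdge q = pq.top(); pq.pop();
    if (strict ? !(q.B < thr) : !(q.B <= thr)) break; // queue min failed
    if (en.find(q.a) != q.a || en.find(q.b) != q.b) continue; // stale roots
    std::map<int, Eg>::iterator it = en.adj[q.a].find(q.b);
    if (it == en.adj[q.a].end() || it->second.B != q.B) continue; // stale B
    mr.push_back(q.a); ms.push_back(q.b); mB.push_back(q.B);
    int keep = en.unite(q.a, q.b);
    for (std::map<int, Eg>::iterator it2 = en.adj[keep].begin();
         it2 != en.adj[keep].end(); ++it2) {
      QEdge nq; nq.B = it2->second.B;
      nq.a = std::min(keep, it2->first); nq.b = std::max(keep, it2->first);
      pq.push(nq);
    }
  }
  IntegerVector roots(n);
  for (int i = 1; i <= n; ++i) roots[i - 1] = en.find(i);
  return List::create(_["roots"] = roots,
                      _["merge_r"] = wrap(mr), _["merge_s"] = wrap(ms),
                      _["merge_B"] = wrap(mB));
}

// Small-region cleanup: while a region smaller than min_area has a
// neighbour, merge the smallest such region (id tie-break) into the
// neighbour with the weakest shared boundary (neighbour id tie-break).
// [[Rcpp::export(name = ".merge_small_cpp")]]
IntegerVector merge_small_cpp(int n, IntegerVector ia, IntegerVector ib,
                              NumericVector B, NumericVector L,
                              NumericVector sizes, double min_area) {
  Engine en(n);
  load_edges(en, ia, ib, B, L);
  std::vector<double> sz(n + 1);
  for (int i = 1; i <= n; ++i) sz[i] = sizes[i - 1];
  typedef std::pair<double, int> SR;
  std::set<SR> small;
  for (int i = 1; i <= n; ++i)
    if (sz[i] < min_area) small.insert(SR(sz[i], i));
  while (!small.empty()) {
    SR cur = *small.begin();
    int s = cur.second;
    if (en.find(s) != s) { small.erase(small.begin()); continue; }
    if (en.adj[s].empty()) { small.erase(small.begin()); continue; }
    double bestB = 2.0; int bestN = -1;
    for (std::map<int, Eg>::iterator it = en.adj[s].begin();
         it != en.adj[s].end(); ++it) {
      if (it->second.B < bestB) { bestB = it->second.B; bestN = it->first; }
    }
    small.erase(small.begin());
    small.erase(SR(sz[bestN], bestN));
    int keep = en.unite(s, bestN);
    double nsz = sz[s] + sz[bestN];
    sz[keep] = nsz;
    if (nsz < min_area) small.insert(SR(nsz, keep));
  }
  IntegerVector roots(n);
  for (int i = 1; i <= n; ++i) roots[i - 1] = en.find(i);
  return roots;
}
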