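// Maximally Stable Extremal Regions via an incremental component tree.
//
// Extremal (dark) regions at level t are the 4-connected components of
// {p : I(p) <= t}. Pixels are processed level by level through a
// union-find; every maximal interval of levels over which a component's
// pixel set is constant becomes one tree node. Stability of a component
// at level t is q(t) = (a(t+delta) - a(t-delta)) / a(t), where areas
// above t follow the parent chain and areas below t follow the canonical
// child (largest area, ties broken by smallest seed pixel). A region is
// reported where q attains a local minimum along its chain (q(t) <=
// q(t-1) and q(t) < q(t+1), missing neighbours pass) subject to
// q <= max_variation and area bounds; at most one report per tree node
// (its minimal-q level, earliest on ties).
//
// Pixel linear index p = col * h + row (R column-major); x = col, y = row.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  double area, sx, sy;
  int seed, l0, l1, parent;
};

struct Forest {
  std::vector<int> parent;        // union-find parent, -1 = not added
  std::vector<double> area, sx, sy;
  std::vector<int> seed, since;
  std::vector<std::vector<int> > pend;  // node ids awaiting a parent
  std::vector<Node> nodes;

  explicit Forest(int n)
      : parent(n, -1), area(n, 0), sx(n, 0), sy(n, 0),
        seed(n, 0), since(n, 0), pend(n) {}

  int find(int p) {
    int r = p;
    while (parent[r] != r) r = parent[r];
    while (parent[p] != r) { int nx = parent[p]; parent[p] = r; p = nx; }
    return r;
  }

  void emit(int r, int t) {
    Node nd;
    nd.area = area[r]; nd.sx = sx[r]; nd.sy = sy[r];
    nd.seed = seed[r]; nd.l0 = since[r]; nd.l1 = t - 1; nd.parent = -1;
    int nid = (int)nodes.size();
    nodes.push_back(nd);
    for (size_t k = 0; k < pend[r].size(); ++k) nodes[pend[r][k]].parent = nid;
    pend[r].clear();
    pend[r].push_back(nid);
    since[r] = t;
  }

  void merge(int r1, int r2, int t) {
    if (since[r1] < t) emit(r1, t);
    if (since[r2] < t) emit(r2, t);
    int w, l;
    if (area[r1] > area[r2] || (area[r1] == area[r2] && seed[r1] < seed[r2])) {
      w = r1; l = r2;
    } else {
      w = r2; l = r1;
    }
    parent[l] = w;
    area[w] += area[l]; sx[w] += sx[l]; sy[w] += sy[l];
    if (seed[l] < seed[w]) seed[w] = seed[l];
    pend[w].insert(pend[w].end(), pend[l].begin(), pend[l].end());
    pend[l].clear();
  }
};

} // namespace

// Build the component tree and report stable regions for the "dark"
// level-set convention on the supplied intensities (callers invert the
// image for the bright polarity).
// [[Rcpp::export]]
DataFrame mser_detect_cpp(IntegerVector img, int h, int w, int delta,
                          double min_area, double max_area,
                          double max_variation) {
  const int n = h * w;
  std::vector<std::vector<int> > bucket(256);
  for (int p = 0; p < n; ++p) {
    int v = img[p];
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    bucket[v].push_back(p);
  }

  Forest f(n);
  for (int t = 0; t <= 255; ++t) {
    const std::vector<int>& bp = bucket[t];
    for (size_t k = 0; k < bp.size(); ++k) {
      int p = bp[k];
      int x = p / h, y = p % h;
      f.parent[p] = p;
      f.area[p] = 1; f.sx[p] = x; f.sy[p] = y;
      f.seed[p] = p; f.since[p] = t;
      // 4-neighbours already added
      int nb[4]; int nn = 0;
      if (y > 0) nb[nn++] = p - 1;
      if (y < h - 1) nb[nn++] = p + 1;
      if (x > 0) nb[nn++] = p - h;
      if (x < w - 1) nb[nn++] = p + h;
      for (int q = 0; q < nn; ++q) {
        if (f.parent[nb[q]] == -1) continue;
        int r1 = f.find(p), r2 = f.find(nb[q]);
        if (r1 != r2) f.merge(r1, r2, t);
      }
    }
  }
  for (int p = 0; p < n; ++p)
    if (f.parent[p] == p) f.emit(p, 256);

  std::vector<Node>& nodes = f.nodes;
  const int nn = (int)nodes.size();

  // canonical child: largest area, ties by smallest seed
  std::vector<int> canon(nn, -1);
  for (int i = 0; i < nn; ++i) {
    int pa = nodes[i].parent;
    if (pa < 0) continue;
    int c = canon[pa];
    if (c < 0 || nodes[i].area > nodes[c].area ||
        (nodes[i].area == nodes[c].area && nodes[i].seed < nodes[c].seed))
      canon[pa] = i;
  }

  // q(node, t); returns NA when t is below the chain bottom or t+delta>255
  struct Q {
    const std::vector<Node>& nodes;
    const std::vector<int>& canon;
    int delta;
    Q(const std::vector<Node>& n, const std::vector<int>& c, int d)
        : nodes(n), canon(c), delta(d) {}
    double at(int m, int t) const {
      if (t + delta > 255) return NA_REAL;
      while (t > nodes[m].l1) m = nodes[m].parent;
      while (t < nodes[m].l0) {
        if (canon[m] < 0) return NA_REAL;
        m = canon[m];
      }
      int up = m;
      while (t + delta > nodes[up].l1) up = nodes[up].parent;
      int dn = m;
      while (t - delta < nodes[dn].l0 && canon[dn] >= 0) dn = canon[dn];
      return (nodes[up].area - nodes[dn].area) / nodes[m].area;
    }
  } qf(nodes, canon, delta);

  std::vector<int> out_node, out_level;
  std::vector<double> out_q;
  for (int i = 0; i < nn; ++i) {
    double best_q = NA_REAL; int best_t = -1;
    int tmax = nodes[i].l1 < 255 - delta ? nodes[i].l1 : 255 - delta;
    for (int t = nodes[i].l0; t <= tmax; ++t) {
      double q = qf.at(i, t);
      if (ISNA(q)) continue;
      if (q > max_variation) continue;
      if (nodes[i].area < min_area || nodes[i].area > max_area) continue;
      double qm = qf.at(i, t - 1);
      double qp = qf.at(i, t + 1);
      if (!ISNA(qm) && !(q <= qm)) continue;
      if (!ISNA(qp) && !(q < qp)) continue;
      if (best_t < 0 || q < best_q) { best_q = q; best_t = t; }
    }
    if (best_t >= 0) {
      out_node.push_back(i);
      out_level.push_back(best_t);
      out_q.push_back(best_q);
    }
  }

  const int m = (int)out_node.size();
  NumericVector rx(m), ry(m), rarea(m), rq(m);
  IntegerVector rlevel(m), rseed(m);
  for (int k = 0; k < m; ++k) {
    const Node& nd = nodes[out_node[k]];
    rarea[k] = nd.area;
    rx[k] = nd.sx / nd.area;
    ry[k] = nd.sy / nd.area;
    rlevel[k] = out_level[k];
    rq[k] = out_q[k];
    rseed[k] = nd.seed;
  }
  return DataFrame::create(_["x"] = rx, _["y"] = ry, _["area"] = rarea,
                           _["level"] = rlevel, _["q"] = rq,
                           _["seed"] = rseed);
}

// Pixel set of the extremal region containing `seed` at threshold
// `level` (component of {I <= level}); returns 0-based linear indices.
// [[Rcpp::export]]
IntegerVector mser_region_pixels_cpp(IntegerVector img, int h, int w,
                                     int seed, int level) {
  const int n = h * w;
  std::vector<char> vis(n, 0);
  std::vector<int> stack, out;
  if (img[seed] > level) return IntegerVector(0);
  stack.push_back(seed);
  vis[seed] = 1;
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    out.push_back(p);
    int x = p / h, y = p % h;
    int nb[4]; int nn = 0;
    if (y > 0) nb[nn++] = p - 1;
    if (y < h - 1) nb[nn++] = p + 1;
    if (x > 0) nb[nn++] = p - h;
    if (x < w - 1) nb[nn++] = p + h;
    for (int q = 0; q < nn; ++q)
      if (!vis[nb[q]] && img[nb[q]] <= level) { vis[nb[q]] = 1; stack.push_back(nb[q]); }
  }
  return wrap(out);
}

// 4-connected labelling of a logical mask; labels 1..k in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int h, int w) {
  const int n = h * w;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || lab[p0]) continue;
    ++next;
    lab[p0] = next;
    stack.push_back(p0);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int x = p / h, y = p % h;
      int nb[4]; int nn = 0;
      if (y > 0) nb[nn++] = p - 1;
      if (y < h - 1) nb[nn++] = p + 1;
      if (x > 0) nb[nn++] = p - h;
      if (x < w - 1) nb[nn++] = p + h;
      for (int q = 0; q < nn; ++q)
        if (mask[nb[q]] && !lab[nb[q]]) { lab[nb[q]] = next; stack.push_back(nb[q]); }
    }
  }
  return lab;
}
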