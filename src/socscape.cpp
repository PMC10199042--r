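// Quantile-regression-forest core and exact Euclidean distance transform.
//
// The forest is a bagged CART ensemble whose leaves retain the in-bag
// training observations (with bootstrap multiplicity), so any prediction
// point carries a full conditional distribution via Meinshausen weights:
// each tree puts weight 1/(leaf size * n_trees) on every in-bag observation
// sharing the point's leaf.
//
// Determinism contract: all randomness comes from R's RNG (RNGScope), so a
// fixed R seed reproduces the forest exactly; split ties are broken toward
// the lowest feature index, then the lowest threshold / category subset.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;           // -1 for leaf
  std::vector<double> thr;         // continuous threshold (x <= thr -> left)
  std::vector<int> left, right;    // child node ids, -1 for leaf
  std::vector<int> nleft, nright;  // in-bag sizes of children (unseen routing)
  std::vector<std::vector<int>> catleft;   // category codes routed left
  std::vector<std::vector<int>> catright;  // codes seen in training, right
  std::vector<std::vector<int>> members;   // in-bag obs (leaves only)
};

struct Problem {
  const NumericMatrix& X;
  const NumericVector& y;
  const LogicalVector& is_cat;
  int mtry, min_node;
};

// Best split over one feature; returns criterion sum(l)^2/n_l + sum(r)^2/n_r
// (maximising this minimises child SSE). Fills the split description.
struct Split {
  bool found = false;
  double crit = -std::numeric_limits<double>::infinity();
  int feat = -1;
  double thr = 0.0;
  bool is_cat = false;
  std::vector<int> catleft;
};

void best_split_continuous(const Problem& pb, const std::vector<int>& idx,
                           int j, Split& best) {
  const int n = (int)idx.size();
  std::vector<std::pair<double, double>> vy(n);
  for (int i = 0; i < n; ++i)
    vy[i] = {pb.X(idx[i], j), pb.y[idx[i]]};
  std::sort(vy.begin(), vy.end());
  if (vy.front().first == vy.back().first) return;
  double total = 0.0;
  for (auto& p : vy) total += p.second;
  double sl = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    sl += vy[i].second;
    if (vy[i].first == vy[i + 1].first) continue;
    const int nl = i + 1, nr = n - nl;
    const double sr = total - sl;
    const double crit = sl * sl / nl + sr * sr / nr;
    if (crit > best.crit) {
      best.found = true;
      best.crit = crit;
      best.feat = j;
      best.thr = 0.5 * (vy[i].first + vy[i + 1].first);
      best.is_cat = false;
      best.catleft.clear();
    }
  }
}

void best_split_categorical(const Problem& pb, const std::vector<int>& idx,
                            int j, Split& best) {
  // per-level sums/counts among node members
  std::vector<int> levels;
  std::vector<double> lsum;
  std::vector<int> lcnt;
  for (int id : idx) {
    int code = (int)pb.X(id, j);
    size_t k = 0;
    for (; k < levels.size(); ++k)
      if (levels[k] == code) break;
    if (k == levels.size()) {
      levels.push_back(code);
      lsum.push_back(0.0);
      lcnt.push_back(0);
    }
    lsum[k] += pb.y[id];
    lcnt[k] += 1;
  }
  const int L = (int)levels.size();
  if (L < 2) return;
  double total = 0.0;
  int n = (int)idx.size();
  for (double s : lsum) total += s;

  // deterministic level order: sort by code for exhaustive search
  std::vector<int> ord(L);
  for (int k = 0; k < L; ++k) ord[k] = k;
  if (L <= 10) {
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return levels[a] < levels[b]; });
    // level ord[0] pinned to the right side to avoid complement duplicates;
    // masks enumerated ascending = lowest-subset tie-break
    const int nmask = 1 << (L - 1);
    for (int mask = 1; mask < nmask; ++mask) {
      double sl = 0.0;
      int nl = 0;
      for (int b = 0; b < L - 1; ++b)
        if (mask & (1 << b)) {
          sl += lsum[ord[b + 1]];
          nl += lcnt[ord[b + 1]];
        }
      const int nr = n - nl;
      if (nl == 0 || nr == 0) continue;
      const double sr = total - sl;
      const double crit = sl * sl / nl + sr * sr / nr;
      if (crit > best.crit) {
        best.found = true;
        best.crit = crit;
        best.feat = j;
        best.is_cat = true;
        best.catleft.clear();
        for (int b = 0; b < L - 1; ++b)
          if (mask & (1 << b)) best.catleft.push_back(levels[ord[b + 1]]);
        std::sort(best.catleft.begin(), best.catleft.end());
      }
    }
  } else {
    // many levels: order by mean response, scan as if ordered
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double ma = lsum[a] / lcnt[a], mb = lsum[b] / lcnt[b];
      if (ma != mb) return ma < mb;
      return levels[a] < levels[b];
    });
    double sl = 0.0;
    int nl = 0;
    for (int k = 0; k < L - 1; ++k) {
      sl += lsum[ord[k]];
      nl += lcnt[ord[k]];
      const int nr = n - nl;
      const double sr = total - sl;
      const double crit = sl * sl / nl + sr * sr / nr;
      if (crit > best.crit) {
        best.found = true;
        best.crit = crit;
        best.feat = j;
        best.is_cat = true;
        best.catleft.clear();
        for (int m = 0; m <= k; ++m) best.catleft.push_back(levels[ord[m]]);
        std::sort(best.catleft.begin(), best.catleft.end());
      }
    }
  }
}

int grow_node(Tree& tr, const Problem& pb, std::vector<int>& idx) {
  const int node = (int)tr.feat.size();
  tr.feat.push_back(-1);
  tr.thr.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.nleft.push_back(0);
  tr.nright.push_back(0);
  tr.catleft.emplace_back();
  tr.catright.emplace_back();
  tr.members.emplace_back();

  const int n = (int)idx.size();
  bool pure = true;
  for (int i = 1; i < n && pure; ++i) pure = (pb.y[idx[i]] == pb.y[idx[0]]);

  Split best;
  if (n > pb.min_node && !pure) {
    // parent criterion: a split must strictly beat keeping the node whole
    double tot = 0.0;
    for (int id : idx) tot += pb.y[id];
    best.crit = tot * tot / n;
    const int p = pb.X.ncol();
    // sample mtry features without replacement (R RNG), then visit them in
    // ascending index order so gain ties resolve to the lowest feature
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < pb.mtry; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }
    feats.resize(pb.mtry);
    std::sort(feats.begin(), feats.end());
    for (int j : feats) {
      if (pb.is_cat[j])
        best_split_categorical(pb, idx, j, best);
      else
        best_split_continuous(pb, idx, j, best);
    }
  }

  if (!best.found) {
    tr.members[node] = idx;
    return node;
  }

  std::vector<int> lidx, ridx;
  lidx.reserve(n);
  ridx.reserve(n);
  if (best.is_cat) {
    std::vector<int> rightcodes;
    for (int id : idx) {
      int code = (int)pb.X(id, best.feat);
      if (std::binary_search(best.catleft.begin(), best.catleft.end(), code)) {
        lidx.push_back(id);
      } else {
        ridx.push_back(id);
        rightcodes.push_back(code);
      }
    }
    std::sort(rightcodes.begin(), rightcodes.end());
    rightcodes.erase(std::unique(rightcodes.begin(), rightcodes.end()),
                     rightcodes.end());
    tr.catright[node] = rightcodes;
  } else {
    for (int id : idx)
      (pb.X(id, best.feat) <= best.thr ? lidx : ridx).push_back(id);
  }
  tr.feat[node] = best.feat;
  tr.thr[node] = best.thr;
  tr.catleft[node] = best.catleft;
  tr.nleft[node] = (int)lidx.size();
  tr.nright[node] = (int)ridx.size();
  idx.clear();
  idx.shrink_to_fit();
  const int lc = grow_node(tr, pb, lidx);
  tr.left[node] = lc;
  const int rc = grow_node(tr, pb, ridx);
  tr.right[node] = rc;
  return node;
}

List tree_to_r(const Tree& tr) {
  const int m = (int)tr.feat.size();
  List cl(m), cr(m), mem(m);
  for (int i = 0; i < m; ++i) {
    cl[i] = IntegerVector(tr.catleft[i].begin(), tr.catleft[i].end());
    cr[i] = IntegerVector(tr.catright[i].begin(), tr.catright[i].end());
    mem[i] = IntegerVector(tr.members[i].begin(), tr.members[i].end());
  }
  return List::create(_["feat"] = IntegerVector(tr.feat.begin(), tr.feat.end()),
                      _["thr"] = NumericVector(tr.thr.begin(), tr.thr.end()),
                      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
                      _["right"] = IntegerVector(tr.right.begin(),
                                                 tr.right.end()),
                      _["nleft"] = IntegerVector(tr.nleft.begin(),
                                                 tr.nleft.end()),
                      _["nright"] = IntegerVector(tr.nright.begin(),
                                                  tr.nright.end()),
                      _["catleft"] = cl, _["catright"] = cr,
                      _["members"] = mem);
}

// Cached view of one tree: everything copied into plain C++ arrays once,
// then traversed millions of times without touching the R API.
struct TreeView {
  std::vector<int> feat, left, right, nleft, nright;
  std::vector<double> thr;
  std::vector<std::vector<int>> catleft, catright, members;
  explicit TreeView(List tree) {
    IntegerVector f = tree["feat"], l = tree["left"], r = tree["right"];
    IntegerVector nl = tree["nleft"], nr = tree["nright"];
    NumericVector th = tree["thr"];
    List cl = tree["catleft"], cr = tree["catright"], mem = tree["members"];
    const int nn = f.size();
    feat.assign(f.begin(), f.end());
    left.assign(l.begin(), l.end());
    right.assign(r.begin(), r.end());
    nleft.assign(nl.begin(), nl.end());
    nright.assign(nr.begin(), nr.end());
    thr.assign(th.begin(), th.end());
    catleft.resize(nn);
    catright.resize(nn);
    members.resize(nn);
    for (int i = 0; i < nn; ++i) {
      IntegerVector a = cl[i], b = cr[i], m = mem[i];
      catleft[i].assign(a.begin(), a.end());
      catright[i].assign(b.begin(), b.end());
      members[i].assign(m.begin(), m.end());
    }
  }
};

// Leaf lookup for one query row; counts unseen-level fallbacks (routed to
// the larger child).
int find_leaf(const TreeView& tv, const NumericMatrix& X, int row,
              long& unseen) {
  int node = 0;
  while (tv.feat[node] >= 0) {
    bool go_left;
    const std::vector<int>& cl = tv.catleft[node];
    if (!cl.empty()) {
      int code = (int)X(row, tv.feat[node]);
      if (std::binary_search(cl.begin(), cl.end(), code)) {
        go_left = true;
      } else {
        const std::vector<int>& cr = tv.catright[node];
        if (std::binary_search(cr.begin(), cr.end(), code)) {
          go_left = false;
        } else {
          // level never seen at this split: route to the larger child
          go_left = tv.nleft[node] >= tv.nright[node];
          ++unseen;
        }
      }
    } else {
      go_left = X(row, tv.feat[node]) <= tv.thr[node];
    }
    node = go_left ? tv.left[node] : tv.right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export]]
List qrf_fit_cpp(NumericMatrix X, NumericVector y, LogicalVector is_cat,
                 int n_trees, int mtry, int min_node) {
  const int n = X.nrow();
  RNGScope scope;
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  Problem pb{X, y, is_cat, mtry, min_node};
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int d = (int)(unif_rand() * n);
      if (d >= n) d = n - 1;
      idx[i] = d;
      inbag(d, t) += 1;
    }
    std::sort(idx.begin(), idx.end());
    Tree tr;
    grow_node(tr, pb, idx);
    trees[t] = tree_to_r(tr);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericMatrix qrf_weights_cpp(List trees, NumericMatrix X, int n_train) {
  const int nq = X.nrow(), nt = trees.size();
  NumericMatrix W(nq, n_train);
  long unseen = 0;
  for (int t = 0; t < nt; ++t) {
    TreeView tv{List(trees[t])};
    for (int q = 0; q < nq; ++q) {
      int leaf = find_leaf(tv, X, q, unseen);
      const std::vector<int>& mem = tv.members[leaf];
      const double w = 1.0 / ((double)mem.size() * nt);
      for (int k = 0; k < mem.size(); ++k) W(q, mem[k]) += w;
    }
  }
  W.attr("unseen_levels") = (double)unseen;
  return W;
}

// Streaming mean/sd/quantiles without materialising the full weight matrix.
// Quantile rule: smallest training response whose cumulative weight reaches
// the level (inclusive empirical quantile, no interpolation).
// [[Rcpp::export]]
List qrf_stats_cpp(List trees, NumericMatrix X, NumericVector y,
                   NumericVector probs) {
  const int nq = X.nrow(), nt = trees.size(), n = y.size();
  const int npr = probs.size();
  NumericVector mean(nq), sd(nq);
  NumericMatrix Q(nq, npr);
  std::vector<TreeView> views;
  views.reserve(nt);
  for (int t = 0; t < nt; ++t) views.emplace_back(List(trees[t]));
  long unseen = 0;

  if (npr == 0) {
    // streaming mean/SD: Meinshausen weights decompose additively over
    // trees, so E[y] and E[y^2] are averages of per-leaf in-bag moments
    std::vector<double> m1(nq, 0.0), m2(nq, 0.0);
    for (int t = 0; t < nt; ++t) {
      const TreeView& tv = views[t];
      const int nn = tv.feat.size();
      std::vector<double> lm1(nn, 0.0), lm2(nn, 0.0);
      for (int node = 0; node < nn; ++node) {
        if (tv.feat[node] >= 0) continue;
        const std::vector<int>& mem = tv.members[node];
        double a = 0.0, b = 0.0;
        for (int k = 0; k < mem.size(); ++k) {
          a += y[mem[k]];
          b += y[mem[k]] * y[mem[k]];
        }
        lm1[node] = a / mem.size();
        lm2[node] = b / mem.size();
      }
      for (int q = 0; q < nq; ++q) {
        int leaf = find_leaf(tv, X, q, unseen);
        m1[q] += lm1[leaf];
        m2[q] += lm2[leaf];
      }
    }
    for (int q = 0; q < nq; ++q) {
      mean[q] = m1[q] / nt;
      sd[q] = std::sqrt(std::max(m2[q] / nt - mean[q] * mean[q], 0.0));
    }
    return List::create(_["mean"] = mean, _["sd"] = sd, _["quantiles"] = Q,
                        _["unseen_levels"] = (double)unseen);
  }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });
  std::vector<int> want(npr);
  for (int j = 0; j < npr; ++j) want[j] = j;
  std::sort(want.begin(), want.end(),
            [&](int a, int b) { return probs[a] < probs[b]; });
  std::vector<double> w(n);
  for (int q = 0; q < nq; ++q) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int t = 0; t < nt; ++t) {
      int leaf = find_leaf(views[t], X, q, unseen);
      const std::vector<int>& mem = views[t].members[leaf];
      const double ww = 1.0 / ((double)mem.size() * nt);
      for (int k = 0; k < mem.size(); ++k) w[mem[k]] += ww;
    }
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += w[i] * y[i];
    double v = 0.0;
    for (int i = 0; i < n; ++i) v += w[i] * (y[i] - m) * (y[i] - m);
    mean[q] = m;
    sd[q] = std::sqrt(std::max(v, 0.0));
    double cum = 0.0;
    int pi = 0;
    for (int i = 0; i < n && pi < npr; ++i) {
      cum += w[ord[i]];
      while (pi < npr && cum >= probs[want[pi]] - 1e-12) {
        Q(q, want[pi]) = y[ord[i]];
        ++pi;
      }
    }
    for (; pi < npr; ++pi) Q(q, want[pi]) = y[ord[n - 1]];
  }
  return List::create(_["mean"] = mean, _["sd"] = sd, _["quantiles"] = Q,
                      _["unseen_levels"] = (double)unseen);
}

// Out-of-bag mean prediction per training row: aggregate Meinshausen weights
// over the trees where the row is out-of-bag only.
// [[Rcpp::export]]
NumericVector qrf_oob_mean_cpp(List trees, IntegerMatrix inbag,
                               NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), nt = trees.size();
  std::vector<double> num(n, 0.0);
  std::vector<int> ntree_used(n, 0);
  long unseen = 0;
  for (int t = 0; t < nt; ++t) {
    TreeView tv{List(trees[t])};
    const int nn = tv.feat.size();
    std::vector<double> lm(nn, 0.0);
    for (int node = 0; node < nn; ++node) {
      if (tv.feat[node] >= 0) continue;
      const std::vector<int>& mem = tv.members[node];
      double a = 0.0;
      for (int k = 0; k < mem.size(); ++k) a += y[mem[k]];
      lm[node] = a / mem.size();
    }
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) > 0) continue;
      int leaf = find_leaf(tv, X, i, unseen);
      num[i] += lm[leaf];
      ntree_used[i] += 1;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ntree_used[i] ? num[i] / ntree_used[i] : NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher): squared
// distance from every cell to the nearest "source" (value 0) cell, in cell
// units. Two 1-D passes of the lower-envelope-of-parabolas algorithm.

namespace {
void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}
}  // namespace

// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(IntegerMatrix src) {
  const int nr = src.nrow(), nc = src.ncol();
  const double INF = 1e18;
  NumericMatrix D(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) D(i, j) = src(i, j) ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = D(i, j);
    f.resize(nr);
    d.resize(nr);
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) D(i, j) = d[i];
    f.resize(std::max(nr, nc));
    d.resize(std::max(nr, nc));
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = D(i, j);
    f.resize(nc);
    d.resize(nc);
    dt1d(f, d);
    for (int j = 0; j < nc; ++j) D(i, j) = d[j];
    f.resize(std::max(nr, nc));
    d.resize(std::max(nr, nc));
  }
  return D;
}
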