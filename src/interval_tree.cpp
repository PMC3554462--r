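// Augmented red-black interval tree (CLRS layout, index-based with a nil
// sentinel at slot 0).  Nodes are ordered by (start, end, payload) so that
// in-order traversal yields the canonical reporting order; every node
// carries the maximum interval end over its subtree, which drives pruning
// in window queries.  Coordinates are doubles so the full range of R's
// numeric chromosome positions round-trips exactly.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

struct Node {
  double start, end, maxend;
  int left, right, parent;
  bool red;
  std::string payload;
};

class ITree {
public:
  std::vector<Node> nodes;   // nodes[0] is the nil sentinel (black, -Inf)
  std::vector<int> freelist;
  int root;
  int count;

  ITree() : root(0), count(0) {
    Node nil;
    nil.start = 0; nil.end = 0; nil.maxend = R_NegInf;
    nil.left = nil.right = nil.parent = 0;
    nil.red = false;
    nodes.push_back(nil);
  }

  int cmp(double s, double e, const std::string& p, int x) const {
    const Node& nx = nodes[x];
    if (s < nx.start) return -1;
    if (s > nx.start) return 1;
    if (e < nx.end) return -1;
    if (e > nx.end) return 1;
    if (p < nx.payload) return -1;
    if (p > nx.payload) return 1;
    return 0;
  }

  void recompute_maxend(int x) {
    Node& nx = nodes[x];
    double m = nx.end;
    if (nx.left != 0) m = std::max(m, nodes[nx.left].maxend);
    if (nx.right != 0) m = std::max(m, nodes[nx.right].maxend);
    nx.maxend = m;
  }

  void fix_maxend_upward(int x) {
    while (x != 0) {
      recompute_maxend(x);
      x = nodes[x].parent;
    }
  }

  void left_rotate(int x) {
    int y = nodes[x].right;
    nodes[x].right = nodes[y].left;
    if (nodes[y].left != 0) nodes[nodes[y].left].parent = x;
    nodes[y].parent = nodes[x].parent;
    if (nodes[x].parent == 0) root = y;
    else if (x == nodes[nodes[x].parent].left) nodes[nodes[x].parent].left = y;
    else nodes[nodes[x].parent].right = y;
    nodes[y].left = x;
    nodes[x].parent = y;
    recompute_maxend(x);
    recompute_maxend(y);
  }

  void right_rotate(int x) {
    int y = nodes[x].left;
    nodes[x].left = nodes[y].right;
    if (nodes[y].right != 0) nodes[nodes[y].right].parent = x;
    nodes[y].parent = nodes[x].parent;
    if (nodes[x].parent == 0) root = y;
    else if (x == nodes[nodes[x].parent].right) nodes[nodes[x].parent].right = y;
    else nodes[nodes[x].parent].left = y;
    nodes[y].right = x;
    nodes[x].parent = y;
    recompute_maxend(x);
    recompute_maxend(y);
  }

  int alloc_node() {
    if (!freelist.empty()) {
      int id = freelist.back();
      freelist.pop_back();
      return id;
    }
    nodes.push_back(Node());
    return (int)nodes.size() - 1;
  }

  void insert(double s, double e, const std::string& p) {
    int z = alloc_node();
    Node& nz = nodes[z];
    nz.start = s; nz.end = e; nz.maxend = e; nz.payload = p;
    nz.left = nz.right = nz.parent = 0; nz.red = true;

    int y = 0, x = root;
    while (x != 0) {
      y = x;
      x = (cmp(s, e, p, x) < 0) ? nodes[x].left : nodes[x].right;
    }
    nodes[z].parent = y;
    if (y == 0) root = z;
    else if (cmp(s, e, p, y) < 0) nodes[y].left = z;
    else nodes[y].right = z;
    fix_maxend_upward(y);
    insert_fixup(z);
    count++;
  }

  void insert_fixup(int z) {
    while (nodes[nodes[z].parent].red) {
      int zp = nodes[z].parent;
      int zpp = nodes[zp].parent;
      if (zp == nodes[zpp].left) {
        int y = nodes[zpp].right;
        if (nodes[y].red) {
          nodes[zp].red = false; nodes[y].red = false; nodes[zpp].red = true;
          z = zpp;
        } else {
          if (z == nodes[zp].right) { z = zp; left_rotate(z); }
          zp = nodes[z].parent; zpp = nodes[zp].parent;
          nodes[zp].red = false; nodes[zpp].red = true;
          right_rotate(zpp);
        }
      } else {
        int y = nodes[zpp].left;
        if (nodes[y].red) {
          nodes[zp].red = false; nodes[y].red = false; nodes[zpp].red = true;
          z = zpp;
        } else {
          if (z == nodes[zp].left) { z = zp; right_rotate(z); }
          zp = nodes[z].parent; zpp = nodes[zp].parent;
          nodes[zp].red = false; nodes[zpp].red = true;
          left_rotate(zpp);
        }
      }
      if (z == root) break;
    }
    nodes[root].red = false;
  }

  int find(double s, double e, const std::string& p) const {
    int x = root;
    while (x != 0) {
      int c = cmp(s, e, p, x);
      if (c == 0) return x;
      x = (c < 0) ? nodes[x].left : nodes[x].right;
    }
    return 0;
  }

  void transplant(int u, int v) {
    if (nodes[u].parent == 0) root = v;
    else if (u == nodes[nodes[u].parent].left) nodes[nodes[u].parent].left = v;
    else nodes[nodes[u].parent].right = v;
    nodes[v].parent = nodes[u].parent;  // also recorded for the nil sentinel
  }

  int minimum(int x) const {
    while (nodes[x].left != 0) x = nodes[x].left;
    return x;
  }

  bool erase(double s, double e, const std::string& p) {
    int z = find(s, e, p);
    if (z == 0) return false;
    int y = z, x;
    bool y_was_red = nodes[y].red;
    if (nodes[z].left == 0) {
      x = nodes[z].right;
      transplant(z, x);
    } else if (nodes[z].right == 0) {
      x = nodes[z].left;
      transplant(z, x);
    } else {
      y = minimum(nodes[z].right);
      y_was_red = nodes[y].red;
      x = nodes[y].right;
      if (nodes[y].parent == z) {
        nodes[x].parent = y;
      } else {
        transplant(y, x);
        nodes[y].right = nodes[z].right;
        nodes[nodes[y].right].parent = y;
      }
      transplant(z, y);
      nodes[y].left = nodes[z].left;
      nodes[nodes[y].left].parent = y;
      nodes[y].red = nodes[z].red;
    }
    // subtree contents changed along the path above x's new position
    fix_maxend_upward(nodes[x].parent);
    if (!y_was_red) delete_fixup(x);
    nodes[0].parent = 0;  // keep the sentinel inert
    nodes[0].maxend = R_NegInf;
    freelist.push_back(z);
    count--;
    return true;
  }

  void delete_fixup(int x) {
    while (x != root && !nodes[x].red) {
      int xp = nodes[x].parent;
      if (x == nodes[xp].left) {
        int w = nodes[xp].right;
        if (nodes[w].red) {
          nodes[w].red = false; nodes[xp].red = true;
          left_rotate(xp);
          xp = nodes[x].parent; w = nodes[xp].right;
        }
        if (!nodes[nodes[w].left].red && !nodes[nodes[w].right].red) {
          nodes[w].red = true;
          x = xp;
        } else {
          if (!nodes[nodes[w].right].red) {
            nodes[nodes[w].left].red = false; nodes[w].red = true;
            right_rotate(w);
            xp = nodes[x].parent; w = nodes[xp].right;
          }
          nodes[w].red = nodes[xp].red;
          nodes[xp].red = false;
          nodes[nodes[w].right].red = false;
          left_rotate(xp);
          x = root;
        }
      } else {
        int w = nodes[xp].left;
        if (nodes[w].red) {
          nodes[w].red = false; nodes[xp].red = true;
          right_rotate(xp);
          xp = nodes[x].parent; w = nodes[xp].left;
        }
        if (!nodes[nodes[w].right].red && !nodes[nodes[w].left].red) {
          nodes[w].red = true;
          x = xp;
        } else {
          if (!nodes[nodes[w].left].red) {
            nodes[nodes[w].right].red = false; nodes[w].red = true;
            left_rotate(w);
            xp = nodes[x].parent; w = nodes[xp].left;
          }
          nodes[w].red = nodes[xp].red;
          nodes[xp].red = false;
          nodes[nodes[w].left].red = false;
          right_rotate(xp);
          x = root;
        }
      }
    }
    nodes[x].red = false;
  }

  void window(int x, double lo, double hi,
              std::vector<double>& rs, std::vector<double>& re,
              std::vector<std::string>& rp, long& visited) const {
    if (x == 0) return;
    visited++;
    const Node& nx = nodes[x];
    if (nx.left != 0 && nodes[nx.left].maxend >= lo)
      window(nx.left, lo, hi, rs, re, rp, visited);
    if (nx.start <= hi && nx.end >= lo) {
      rs.push_back(nx.start);
      re.push_back(nx.end);
      rp.push_back(nx.payload);
    }
    if (nx.right != 0 && nx.start <= hi)
      window(nx.right, lo, hi, rs, re, rp, visited);
  }
};

// [[Rcpp::export(name = ".it_create")]]
SEXP it_create() {
  XPtr<ITree> p(new ITree(), true);
  return p;
}

// [[Rcpp::export(name = ".it_insert")]]
void it_insert_cpp(SEXP xp, NumericVector start, NumericVector end,
                   CharacterVector payload) {
  XPtr<ITree> t(xp);
  int m = start.size();
  for (int i = 0; i < m; i++)
    t->insert(start[i], end[i], as<std::string>(payload[i]));
}

// [[Rcpp::export(name = ".it_erase")]]
LogicalVector it_erase_cpp(SEXP xp, NumericVector start, NumericVector end,
                           CharacterVector payload) {
  XPtr<ITree> t(xp);
  int m = start.size();
  LogicalVector out(m);
  for (int i = 0; i < m; i++)
    out[i] = t->erase(start[i], end[i], as<std::string>(payload[i]));
  return out;
}

// [[Rcpp::export(name = ".it_size")]]
int it_size_cpp(SEXP xp) {
  XPtr<ITree> t(xp);
  return t->count;
}

// [[Rcpp::export(name = ".it_window")]]
List it_window_cpp(SEXP xp, double lo, double hi) {
  XPtr<ITree> t(xp);
  std::vector<double> rs, re;
  std::vector<std::string> rp;
  long visited = 0;
  t->window(t->root, lo, hi, rs, re, rp, visited);
  return List::create(_["start"] = wrap(rs), _["end"] = wrap(re),
                      _["payload"] = wrap(rp),
                      _["visited"] = (double)visited);
}

// Flat structural snapshot for the R-side red-black validator.
// [[Rcpp::export(name = ".it_dump")]]
List it_dump_cpp(SEXP xp) {
  XPtr<ITree> t(xp);
  int n = t->count;
  std::vector<int> id; id.reserve(n);
  std::vector<double> st, en, me;
  std::vector<int> lf, rt, pa;
  std::vector<int> red;
  std::vector<std::string> pl;
  // preorder walk over live nodes
  std::vector<int> stack;
  if (t->root != 0) stack.push_back(t->root);
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    const Node& nx = t->nodes[x];
    id.push_back(x);
    st.push_back(nx.start); en.push_back(nx.end); me.push_back(nx.maxend);
    lf.push_back(nx.left); rt.push_back(nx.right); pa.push_back(nx.parent);
    red.push_back(nx.red ? 1 : 0);
    pl.push_back(nx.payload);
    if (nx.left != 0) stack.push_back(nx.left);
    if (nx.right != 0) stack.push_back(nx.right);
  }
  return List::create(_["id"] = wrap(id), _["start"] = wrap(st),
                      _["end"] = wrap(en), _["maxend"] = wrap(me),
                      _["left"] = wrap(lf), _["right"] = wrap(rt),
                      _["parent"] = wrap(pa), _["red"] = wrap(red),
                      _["payload"] = wrap(pl), _["root"] = t->root);
}
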