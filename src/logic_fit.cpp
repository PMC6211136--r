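// Simulated-annealing search for Boolean logic trees (AND/OR trees over
// binary literals), the base learner of the logic forest.  Trees are kept in
// flat parallel arrays so they can cross the R/C++ boundary cheaply and be
// manipulated in R (DNF extraction, serialization) without a parser.
//
// Node encoding: type 0 = leaf, 1 = AND, 2 = OR.  Leaves carry a 0-based
// predictor column `var` and a complement flag `neg`.  Internal nodes carry
// child slot indices.  Slot 0 is always the root; unused slots have type -1.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const int MAXSLOTS = 64;  // >= 2*max_leaves - 1 for max_leaves <= 8, with slack

struct Tree {
  int type[MAXSLOTS];
  int var[MAXSLOTS];
  int neg[MAXSLOTS];
  int left[MAXSLOTS];
  int right[MAXSLOTS];

  void clear() {
    for (int i = 0; i < MAXSLOTS; ++i) type[i] = -1;
  }
  int free_slot() const {
    for (int i = 0; i < MAXSLOTS; ++i)
      if (type[i] == -1) return i;
    return -1;  // unreachable under the leaf cap
  }
  int n_leaves() const {
    int k = 0;
    for (int i = 0; i < MAXSLOTS; ++i)
      if (type[i] == 0) ++k;
    return k;
  }
  // parent slot of node j, or -1 for the root
  int parent_of(int j) const {
    if (j == 0) return -1;
    for (int i = 0; i < MAXSLOTS; ++i)
      if (type[i] > 0 && (left[i] == j || right[i] == j)) return i;
    return -1;
  }
  void collect(int which, std::vector<int>& out) const {
    // which: 0 leaves, 1 internal, 2 all active
    out.clear();
    for (int i = 0; i < MAXSLOTS; ++i) {
      if (type[i] == -1) continue;
      if (which == 2 || (which == 0 && type[i] == 0) ||
          (which == 1 && type[i] > 0))
        out.push_back(i);
    }
  }
  void free_subtree(int j) {
    if (type[j] > 0) {
      free_subtree(left[j]);
      free_subtree(right[j]);
    }
    type[j] = -1;
  }
  // deep-copy subtree src (of `from`) into this tree, returning the new slot
  int graft(const Tree& from, int src) {
    int s = free_slot();
    type[s] = from.type[src];
    var[s] = from.var[src];
    neg[s] = from.neg[src];
    if (from.type[src] > 0) {
      left[s] = graft(from, from.left[src]);
      right[s] = graft(from, from.right[src]);
    }
    return s;
  }
  // move subtree rooted at slot j into slot 0 (used when a prune promotes a
  // child to root): relabel via a temporary copy
  void promote_to_root(int j) {
    if (j == 0) return;
    Tree tmp;
    tmp.clear();
    int r = tmp.graft(*this, j);  // r == 0 since tmp is empty
    (void)r;
    *this = tmp;
  }
};

inline int ir(int n) { return (int)(unif_rand() * n); }  // uniform 0..n-1

// evaluate subtree at slot j over rows `rows` (0-based) of X, writing 0/1
void eval_rec(const Tree& t, int j, const IntegerMatrix& X,
              const std::vector<int>& rows, std::vector<int>& out) {
  int n = rows.size();
  if (t.type[j] == 0) {
    int v = t.var[j];
    if (t.neg[j])
      for (int i = 0; i < n; ++i) out[i] = 1 - X(rows[i], v);
    else
      for (int i = 0; i < n; ++i) out[i] = X(rows[i], v);
    return;
  }
  std::vector<int> rbuf(n);
  eval_rec(t, t.left[j], X, rows, out);
  eval_rec(t, t.right[j], X, rows, rbuf);
  if (t.type[j] == 1)
    for (int i = 0; i < n; ++i) out[i] = out[i] & rbuf[i];
  else
    for (int i = 0; i < n; ++i) out[i] = out[i] | rbuf[i];
}

int misclass_count(const Tree& t, const IntegerMatrix& X,
                   const IntegerVector& y, const std::vector<int>& rows) {
  int n = rows.size();
  std::vector<int> pred(n);
  eval_rec(t, 0, X, rows, pred);
  int bad = 0;
  for (int i = 0; i < n; ++i)
    if (pred[i] != y[rows[i]]) ++bad;
  return bad;
}

// Move set: 0 alternate-leaf, 1 alternate-operator, 2 split-leaf,
//           3 grow-branch, 4 delete-leaf, 5 prune-branch.
// Returns false if no legal move exists (cannot happen for p >= 1).
bool propose(Tree& t, int p, int max_leaves) {
  std::vector<int> leaves, internals;
  t.collect(0, leaves);
  t.collect(1, internals);
  int nl = leaves.size();

  std::vector<int> legal;
  legal.push_back(0);
  if (!internals.empty()) legal.push_back(1);
  if (nl < max_leaves) {
    legal.push_back(2);
    if (!internals.empty()) legal.push_back(3);
  }
  if (nl >= 2) {
    legal.push_back(4);
    if (!internals.empty()) legal.push_back(5);
  }
  int mv = legal[ir((int)legal.size())];

  switch (mv) {
    case 0: {  // alternate-leaf: replace literal with a different one
      int j = leaves[ir(nl)];
      int cur = 2 * t.var[j] + t.neg[j];
      int nlit = 2 * p;
      int pick = (nlit > 1) ? (cur + 1 + ir(nlit - 1)) % nlit : cur;
      t.var[j] = pick / 2;
      t.neg[j] = pick % 2;
      break;
    }
    case 1: {  // alternate-operator
      int j = internals[ir((int)internals.size())];
      t.type[j] = (t.type[j] == 1) ? 2 : 1;
      break;
    }
    case 2: {  // split-leaf: leaf -> op(old leaf, new random leaf)
      int j = leaves[ir(nl)];
      int a = t.free_slot();
      t.type[a] = 0; t.var[a] = t.var[j]; t.neg[a] = t.neg[j];
      int b = t.free_slot();
      t.type[b] = 0; t.var[b] = ir(p); t.neg[b] = ir(2);
      t.type[j] = 1 + ir(2);
      t.left[j] = a; t.right[j] = b;
      break;
    }
    case 3: {  // grow-branch: internal subtree s -> op(s, new leaf)
      int j = internals[ir((int)internals.size())];
      Tree side; side.clear();
      int sroot = side.graft(t, j);        // copy subtree aside
      t.free_subtree(j);                   // vacate, keep slot j
      t.type[j] = 1 + ir(2);
      t.left[j] = t.graft(side, sroot);
      int b = t.free_slot();
      t.type[b] = 0; t.var[b] = ir(p); t.neg[b] = ir(2);
      t.right[j] = b;
      break;
    }
    case 4: {  // delete-leaf: parent replaced by sibling subtree
      int j = leaves[ir(nl)];
      int par = t.parent_of(j);
      int sib = (t.left[par] == j) ? t.right[par] : t.left[par];
      Tree side; side.clear();
      int sroot = side.graft(t, sib);
      t.free_subtree(par == -1 ? 0 : par);
      if (par == 0 || par == -1) {
        t.clear();
        t.graft(side, sroot);
      } else {
        int gp = -1;
        for (int i = 0; i < MAXSLOTS; ++i)
          if (t.type[i] > 0 && (t.left[i] == par || t.right[i] == par)) gp = i;
        int s = t.graft(side, sroot);
        if (t.left[gp] == par) t.left[gp] = s; else t.right[gp] = s;
      }
      break;
    }
    case 5: {  // prune-branch: internal node replaced by a random child
      int j = internals[ir((int)internals.size())];
      int child = (ir(2) == 0) ? t.left[j] : t.right[j];
      Tree side; side.clear();
      int sroot = side.graft(t, child);
      if (j == 0) {
        t.clear();
        t.graft(side, sroot);
      } else {
        int gp = t.parent_of(j);
        t.free_subtree(j);
        int s = t.graft(side, sroot);
        if (t.left[gp] == j) t.left[gp] = s; else t.right[gp] = s;
      }
      break;
    }
  }
  return true;
}

Tree from_list(const List& lt) {
  Tree t;
  t.clear();
  IntegerVector type = lt["type"], var = lt["var"], left = lt["left"],
                right = lt["right"];
  LogicalVector neg = lt["neg"];
  for (int i = 0; i < type.size(); ++i) {
    t.type[i] = type[i];
    t.var[i] = (var[i] == NA_INTEGER) ? 0 : var[i] - 1;  // R 1-based
    t.neg[i] = (neg[i] == NA_LOGICAL) ? 0 : (int)neg[i];
    t.left[i] = (left[i] == NA_INTEGER) ? -1 : left[i] - 1;
    t.right[i] = (right[i] == NA_INTEGER) ? -1 : right[i] - 1;
  }
  return t;
}

// compact active slots into a preorder list for R (root first)
void preorder(const Tree& t, int j, std::vector<int>& ty, std::vector<int>& va,
              std::vector<int>& ng, std::vector<int>& le, std::vector<int>& ri) {
  int me = ty.size();
  ty.push_back(t.type[j]);
  va.push_back(t.type[j] == 0 ? t.var[j] + 1 : NA_INTEGER);
  ng.push_back(t.type[j] == 0 ? t.neg[j] : NA_LOGICAL);
  le.push_back(NA_INTEGER);
  ri.push_back(NA_INTEGER);
  if (t.type[j] > 0) {
    le[me] = ty.size() + 1;  // next slot, 1-based
    preorder(t, t.left[j], ty, va, ng, le, ri);
    ri[me] = ty.size() + 1;
    preorder(t, t.right[j], ty, va, ng, le, ri);
  }
}

List to_list(const Tree& t) {
  std::vector<int> ty, va, ng, le, ri;
  preorder(t, 0, ty, va, ng, le, ri);
  int m = ty.size();
  IntegerVector type(m), var(m), left(m), right(m);
  LogicalVector neg(m);
  for (int i = 0; i < m; ++i) {
    type[i] = ty[i]; var[i] = va[i]; left[i] = le[i]; right[i] = ri[i];
    neg[i] = (ng[i] == NA_LOGICAL) ? NA_LOGICAL : (ng[i] != 0);
  }
  return List::create(_["type"] = type, _["var"] = var, _["neg"] = neg,
                      _["left"] = left, _["right"] = right);
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_eval_tree(List tree, IntegerMatrix X, IntegerVector rows) {
  Tree t = from_list(tree);
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); ++i) rr[i] = rows[i] - 1;
  std::vector<int> out(rr.size());
  eval_rec(t, 0, X, rr, out);
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_propose_move(List tree, int p, int max_leaves) {
  Tree t = from_list(tree);
  propose(t, p, max_leaves);
  return to_list(t);
}

// Bitmask evaluation over the fitting rows: predictor columns are packed
// into 64-bit words once, so scoring a candidate tree costs
// O(nodes * n/64) word operations regardless of n.
struct MaskEval {
  int W;                               // words per column
  std::vector<uint64_t> cols;          // p x W, row-bit i = X(rows[i], j)
  std::vector<uint64_t> ymask;         // outcome bits
  std::vector<uint64_t> tail;          // valid-bit mask (bits < nr)
  std::vector<uint64_t> arena;         // scratch, one buffer per depth

  MaskEval(const IntegerMatrix& X, const IntegerVector& y,
           const std::vector<int>& rr) {
    int nr = rr.size(), p = X.ncol();
    W = (nr + 63) / 64;
    cols.assign((size_t)p * W, 0);
    ymask.assign(W, 0);
    tail.assign(W, 0);
    arena.assign((size_t)(MAXSLOTS + 1) * W, 0);
    for (int i = 0; i < nr; ++i) {
      tail[i >> 6] |= (uint64_t)1 << (i & 63);
      if (y[rr[i]]) ymask[i >> 6] |= (uint64_t)1 << (i & 63);
      for (int j = 0; j < p; ++j)
        if (X(rr[i], j)) cols[(size_t)j * W + (i >> 6)] |=
          (uint64_t)1 << (i & 63);
    }
  }
  void eval(const Tree& t, int node, int depth, uint64_t* out) {
    if (t.type[node] == 0) {
      const uint64_t* c = &cols[(size_t)t.var[node] * W];
      if (t.neg[node])
        for (int w = 0; w < W; ++w) out[w] = ~c[w] & tail[w];
      else
        for (int w = 0; w < W; ++w) out[w] = c[w];
      return;
    }
    uint64_t* rbuf = &arena[(size_t)(depth + 1) * W];
    eval(t, t.left[node], depth + 1, out);
    eval(t, t.right[node], depth + 1, rbuf);
    if (t.type[node] == 1)
      for (int w = 0; w < W; ++w) out[w] &= rbuf[w];
    else
      for (int w = 0; w < W; ++w) out[w] |= rbuf[w];
  }
  int misclass(const Tree& t) {
    uint64_t* out = &arena[0];
    eval(t, 0, 0, out);
    int bad = 0;
    for (int w = 0; w < W; ++w)
      bad += __builtin_popcountll((out[w] ^ ymask[w]) & tail[w]);
    return bad;
  }
};

// Simulated annealing: minimise in-sample misclassification count over the
// bootstrap rows.  Start temperature is calibrated from a pilot of random
// moves when t0 <= 0 (target ~50% acceptance of worsening moves); cooling is
// geometric down to a temperature where worsening acceptance is ~accept_end.
// Ties in score prefer fewer leaves; the best state ever visited is returned.
// [[Rcpp::export]]
List cpp_fit_tree(IntegerMatrix X, IntegerVector y, IntegerVector rows,
                  int max_leaves, int iter, double t0, double accept_end,
                  int pilot) {
  int p = X.ncol();
  int nr = rows.size();
  std::vector<int> rr(nr);
  for (int i = 0; i < nr; ++i) rr[i] = rows[i] - 1;
  MaskEval ev(X, y, rr);

  Tree cur;
  cur.clear();
  cur.type[0] = 0;
  cur.var[0] = ir(p);
  cur.neg[0] = ir(2);
  int cur_bad = ev.misclass(cur);

  // pilot: estimate the scale of worsening deltas from random moves
  double dsum = 0; int dn = 0;
  if (t0 <= 0) {
    Tree probe = cur;
    int probe_bad = cur_bad;
    for (int k = 0; k < pilot; ++k) {
      Tree cand = probe;
      propose(cand, p, max_leaves);
      int bad = ev.misclass(cand);
      double d = (double)(bad - probe_bad) / nr;
      if (d > 0) { dsum += d; ++dn; }
      probe = cand;  // random walk
      probe_bad = bad;
    }
    double dtyp = dn > 0 ? dsum / dn : 0.02;
    if (dtyp <= 0) dtyp = 0.02;
    t0 = dtyp / std::log(2.0);  // ~50% acceptance of a typical worsening move
  }
  double t_end = t0 * std::log(2.0) / std::log(1.0 / accept_end);
  double cool = std::pow(t_end / t0, 1.0 / std::max(iter - 1, 1));

  Tree best = cur;
  int best_bad = cur_bad;
  int best_leaves = cur.n_leaves();

  double temp = t0;
  for (int k = 0; k < iter; ++k) {
    Tree cand = cur;
    propose(cand, p, max_leaves);
    int bad = ev.misclass(cand);
    double d = (double)(bad - cur_bad) / nr;
    if (d <= 0 || unif_rand() < std::exp(-d / temp)) {
      cur = cand;
      cur_bad = bad;
      int lv = cur.n_leaves();
      if (cur_bad < best_bad ||
          (cur_bad == best_bad && lv < best_leaves)) {
        best = cur;
        best_bad = cur_bad;
        best_leaves = lv;
      }
    }
    temp *= cool;
  }
  List out = to_list(best);
  out["score"] = (double)best_bad / nr;
  return out;
}
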