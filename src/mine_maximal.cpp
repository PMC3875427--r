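// Depth-first maximal frequent itemset miner over the item/transaction
// database produced by generate_items().  Transactions are genes; an
// itemset's support is the intersection of its items' gene sets.
//
// Standard techniques: bitset gene sets, support-ascending child ordering,
// parent-equivalence pruning (an item whose gene set contains the current
// support is absorbed without branching), HUT pruning and a local-MFI list
// so the maximality check is a constant-time emptiness test.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<uint64_t> bits;

static inline int popcnt(const bits &a) {
  int n = 0;
  for (uint64_t w : a) {
#if defined(__GNUC__) || defined(__clang__)
    n += __builtin_popcountll(w);
#else
    while (w) { n += (int)(w & 1); w >>= 1; }
#endif
  }
  return n;
}

static inline void and_into(const bits &a, const bits &b, bits &out) {
  for (size_t i = 0; i < a.size(); ++i) out[i] = a[i] & b[i];
}

static inline bool equal_bits(const bits &a, const bits &b) {
  return a == b;
}

static inline bool contains_all(const bits &big, const bits &small) {
  for (size_t i = 0; i < small.size(); ++i)
    if ((small[i] & ~big[i]) != 0) return false;
  return true;
}

struct Miner {
  int n_items, min_row;
  size_t wg, wi;                    // words per gene set / per item set
  std::vector<bits> genes;          // per item (original indexing)
  std::vector<bits> mfi;            // recorded maximal itemsets (item bitsets)

  void record(const bits &head_items) { mfi.push_back(head_items); }

  // head_items: item bitset; support: gene bitset; cand: candidate item
  // indices (frequent extensions of head, in this node's order);
  // local: indices into mfi of itemsets known to contain head_items.
  void dfs(bits head_items, const bits &support,
           const std::vector<int> &cand, std::vector<int> local) {
    // split candidates: absorb parent-equivalent items, keep branchers
    std::vector<int> branch;
    std::vector<bits> branch_sup;
    std::vector<int> branch_cnt;
    bits tmp(wg);
    for (int t : cand) {
      and_into(support, genes[t], tmp);
      int c = popcnt(tmp);
      if (c < min_row) continue;
      if (equal_bits(tmp, support)) {
        head_items[t >> 6] |= (uint64_t)1 << (t & 63);   // PEP absorb
      } else {
        branch.push_back(t);
        branch_sup.push_back(tmp);
        branch_cnt.push_back(c);
      }
    }
    // local MFIs must still contain the absorbed items
    {
      std::vector<int> keep;
      for (int m : local)
        if (contains_all(mfi[m], head_items)) keep.push_back(m);
      local.swap(keep);
    }
    if (branch.empty()) {
      if (local.empty() && popcnt(head_items) > 0) record(head_items);
      return;
    }
    // HUT pruning: head + every remaining candidate already inside an MFI
    if (!local.empty()) {
      bits hut = head_items;
      for (int t : branch) hut[t >> 6] |= (uint64_t)1 << (t & 63);
      for (int m : local)
        if (contains_all(mfi[m], hut)) return;
    }
    // order children by support ascending (then item index, deterministic)
    std::vector<int> ord(branch.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (branch_cnt[a] != branch_cnt[b]) return branch_cnt[a] < branch_cnt[b];
      return branch[a] < branch[b];
    });
    for (size_t ci = 0; ci < ord.size(); ++ci) {
      int k = ord[ci];
      int t = branch[k];
      bits child_head = head_items;
      child_head[t >> 6] |= (uint64_t)1 << (t & 63);
      // tail = later children in this node's order
      std::vector<int> child_cand;
      for (size_t cj = ci + 1; cj < ord.size(); ++cj)
        child_cand.push_back(branch[ord[cj]]);
      // local MFIs for the child: known-so-far itemsets containing child_head
      std::vector<int> child_local;
      for (int m : local)
        if (contains_all(mfi[m], child_head)) child_local.push_back(m);
      size_t mfi_before = mfi.size();
      dfs(child_head, branch_sup[k], child_cand, child_local);
      // itemsets recorded inside the child subtree contain head_items;
      // make them visible to later siblings
      for (size_t m = mfi_before; m < mfi.size(); ++m) local.push_back((int)m);
    }
  }
};

// [[Rcpp::export(name = ".mine_maximal_cpp")]]
List mine_maximal_cpp(List item_genes, int n_genes, int min_row) {
  if (n_genes < min_row) return List(0);
  Miner M;
  M.n_items = item_genes.size();
  M.min_row = min_row;
  M.wg = (size_t)((n_genes + 63) / 64);
  M.wi = (size_t)((M.n_items + 63) / 64);
  if (M.wg == 0) M.wg = 1;
  if (M.wi == 0) M.wi = 1;

  M.genes.resize(M.n_items);
  for (int i = 0; i < M.n_items; ++i) {
    IntegerVector g = item_genes[i];
    bits b(M.wg, 0);
    for (int v : g) {
      int idx = v - 1;                       // 1-based from R
      b[idx >> 6] |= (uint64_t)1 << (idx & 63);
    }
    M.genes[i] = b;
  }

  bits root_support(M.wg, 0);
  for (int i = 0; i < n_genes; ++i)
    root_support[i >> 6] |= (uint64_t)1 << (i & 63);
  std::vector<int> cand(M.n_items);
  for (int i = 0; i < M.n_items; ++i) cand[i] = i;

  bits empty_head(M.wi, 0);
  M.dfs(empty_head, root_support, cand, std::vector<int>());

  List out(M.mfi.size());
  for (size_t m = 0; m < M.mfi.size(); ++m) {
    std::vector<int> ids;
    for (int i = 0; i < M.n_items; ++i)
      if (M.mfi[m][i >> 6] & ((uint64_t)1 << (i & 63))) ids.push_back(i + 1);
    out[m] = IntegerVector(ids.begin(), ids.end());
  }
  return out;
}
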