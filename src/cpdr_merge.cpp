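// Merge engine for the distance-restricted clique-merging scan.
// Semantics (documented on cpdr_clusters in R/cpdr.R):
//   * units live in a pool in creation order;
//   * each unit U is compared against every other pool unit V;
//   * a pair merges when it shares >= min(|U|,|V|)-1 vertices and the
//     union induces a subgraph of diameter <= d;
//   * each merge appends the union at the pool tail (if not present);
//   * after all its comparisons, U is deleted iff it merged at least once;
//   * passes repeat until one completes with no merge.
// Units are bitsets over the host vertex set; diameter verdicts are
// memoized per union.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<uint64_t> BitSet;

static inline int popcount_bs(const BitSet& b) {
  int c = 0;
  for (uint64_t w : b) c += __builtin_popcountll(w);
  return c;
}

static inline int and_popcount(const BitSet& a, const BitSet& b) {
  int c = 0;
  for (size_t i = 0; i < a.size(); ++i) c += __builtin_popcountll(a[i] & b[i]);
  return c;
}

static void bits_of(const BitSet& b, std::vector<int>& out) {
  out.clear();
  for (size_t w = 0; w < b.size(); ++w) {
    uint64_t x = b[w];
    while (x) {
      out.push_back((int)(w * 64 + __builtin_ctzll(x)));
      x &= x - 1;
    }
  }
}

// connected with diameter <= d on the subgraph induced by `mem`?
static bool diam_le(const BitSet& mem, const std::vector<BitSet>& nbr,
                    int d, size_t words) {
  std::vector<int> verts;
  bits_of(mem, verts);
  const int m = (int)verts.size();
  if (m <= 1) return true;
  BitSet reached(words), frontier(words), nxt(words);
  std::vector<int> fverts;
  for (int s : verts) {
    std::fill(reached.begin(), reached.end(), 0ULL);
    std::fill(frontier.begin(), frontier.end(), 0ULL);
    reached[s / 64] |= 1ULL << (s % 64);
    frontier[s / 64] |= 1ULL << (s % 64);
    for (int depth = 0; depth < d; ++depth) {
      std::fill(nxt.begin(), nxt.end(), 0ULL);
      bits_of(frontier, fverts);
      for (int v : fverts)
        for (size_t w = 0; w < words; ++w) nxt[w] |= nbr[v][w];
      bool any = false;
      for (size_t w = 0; w < words; ++w) {
        nxt[w] &= mem[w] & ~reached[w];
        if (nxt[w]) any = true;
        reached[w] |= nxt[w];
      }
      if (!any) break;
      frontier = nxt;
    }
    if (popcount_bs(reached) < m) return false;
  }
  return true;
}

// merge two sorted provenance index vectors, deduplicated
static std::vector<int> prov_union(const std::vector<int>& a,
                                   const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_union(a.begin(), a.end(), b.begin(), b.end(),
                 std::back_inserter(out));
  return out;
}

// [[Rcpp::export(name = ".cpdr_merge_engine")]]
List cpdr_merge_engine(List clique_members, List adj, int n_vertices,
                       int d, int max_passes) {
  const size_t words = (size_t)((n_vertices + 63) / 64);

  std::vector<BitSet> nbr((size_t)n_vertices, BitSet(words, 0ULL));
  for (int v = 0; v < n_vertices; ++v) {
    IntegerVector nv = adj[v];
    for (int x : nv) {
      int u = x - 1;
      nbr[v][u / 64] |= 1ULL << (u % 64);
    }
  }

  std::vector<BitSet> units;
  std::vector<int> sizes;
  std::vector<std::vector<int>> provs;
  std::map<BitSet, int> key2id;   // live units only
  std::map<BitSet, bool> diam_cache;

  const int n_cliques = clique_members.size();
  for (int c = 0; c < n_cliques; ++c) {
    IntegerVector mv = clique_members[c];
    BitSet b(words, 0ULL);
    for (int x : mv) {
      int v = x - 1;
      b[v / 64] |= 1ULL << (v % 64);
    }
    units.push_back(b);
    sizes.push_back((int)mv.size());
    provs.push_back(std::vector<int>(1, c));
    key2id[b] = c;
  }

  std::vector<int> order(units.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;

  int passes = 0;
  for (;;) {
    if (++passes > max_passes)
      stop("merge scan did not reach a fixpoint within %d passes",
           max_passes);
    bool merged_in_pass = false;
    size_t i = 0;
    while (i < order.size()) {
      const int uid = order[i];
      bool merged_u = false;
      // order grows at the tail while uid is being compared
      for (size_t j = 0; j < order.size(); ++j) {
        if (j == i) continue;
        const int vid = order[j];
        const int ov = and_popcount(units[uid], units[vid]);
        const int need = std::min(sizes[uid], sizes[vid]) - 1;
        if (ov < need) continue;
        if (ov == sizes[vid] && ov == sizes[uid]) continue; // identical
        if (ov == sizes[vid]) {
          // v contained in u: union is u itself; not a merge for u
          provs[uid] = prov_union(provs[uid], provs[vid]);
          continue;
        }
        if (ov == sizes[uid]) {
          // u contained in v: union is v (diameter already certified)
          merged_u = true;
          merged_in_pass = true;
          provs[vid] = prov_union(provs[vid], provs[uid]);
          continue;
        }
        BitSet w(words);
        for (size_t k = 0; k < words; ++k)
          w[k] = units[uid][k] | units[vid][k];
        std::map<BitSet, int>::iterator it = key2id.find(w);
        if (it != key2id.end()) {
          merged_u = true;
          merged_in_pass = true;
          provs[it->second] = prov_union(
            prov_union(provs[it->second], provs[uid]), provs[vid]);
          continue;
        }
        std::map<BitSet, bool>::iterator dit = diam_cache.find(w);
        bool ok;
        if (dit != diam_cache.end()) ok = dit->second;
        else {
          ok = diam_le(w, nbr, d, words);
          diam_cache[w] = ok;
        }
        if (ok) {
          merged_u = true;
          merged_in_pass = true;
          const int wid = (int)units.size();
          units.push_back(w);
          sizes.push_back(popcount_bs(w));
          provs.push_back(prov_union(provs[uid], provs[vid]));
          key2id[w] = wid;
          order.push_back(wid);
        }
      }
      if (merged_u) {
        key2id.erase(units[uid]);
        order.erase(order.begin() + i);
        // do not advance i: the next unit shifted into this position
      } else {
        ++i;
      }
    }
    if (!merged_in_pass) break;
  }

  List members_out(order.size());
  List prov_out(order.size());
  std::vector<int> verts;
  for (size_t i = 0; i < order.size(); ++i) {
    const int id = order[i];
    bits_of(units[id], verts);
    IntegerVector mv(verts.size());
    for (size_t k = 0; k < verts.size(); ++k) mv[k] = verts[k] + 1;
    members_out[i] = mv;
    IntegerVector pv(provs[id].size());
    for (size_t k = 0; k < provs[id].size(); ++k) pv[k] = provs[id][k] + 1;
    prov_out[i] = pv;
  }
  return List::create(_["members"] = members_out,
                      _["provenance"] = prov_out,
                      _["passes"] = passes,
                      _["units_created"] = (int)units.size());
}
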