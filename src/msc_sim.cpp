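// Multispecies-coalescent gene-tree simulation.
//
// One lineage enters the gene tree at each species-tree tip (or more, with
// multi-allele sampling). Within a species branch holding k lineages,
// waiting times to the next coalescence are Exponential with rate
// k(k-1)/2 per coalescent unit; a uniformly chosen pair merges if the
// event falls inside the branch, otherwise the survivors are handed to
// the parent branch. Above the root, coalescence continues unbounded.
//
// Time is measured as "age": height above the deepest tip plane, so the
// age difference across any edge equals its branch length and gene
// coalescence ages can be compared directly with species divergence ages.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0;
  while (x) { c += x & 1u; x >>= 1; }
  return c;
#endif
}

struct Lineage {
  int id;          // gene-node id (0-based; tips first, then internals)
  double height;   // age of the node at the bottom of this lineage
  uint32_t mask;   // taxon bitmask (valid only when ntip <= 32)
};

// [[Rcpp::export]]
List msc_simulate_cpp(IntegerVector parent,     // 0-based parent, -1 = root
                      NumericVector age,        // node ages (root tallest)
                      IntegerVector porder,     // 0-based postorder, root last
                      IntegerVector tip_bit,    // bit index per tip node
                      IntegerVector n_alleles,  // lineages entering per tip
                      int ntip,
                      int nrep,
                      bool keys_only) {
  const int M = parent.size();
  std::vector< std::vector<int> > children(M);
  for (int v = 0; v < M; ++v)
    if (parent[v] >= 0) children[parent[v]].push_back(v);

  int total_tips = 0;
  std::vector<int> leaf_offset(ntip, 0);
  for (int i = 0; i < ntip; ++i) {
    leaf_offset[i] = total_tips;
    total_tips += n_alleles[i];
  }
  const int n_internal = total_tips - 1;

  CharacterVector keys(keys_only ? nrep : 0);
  List joins(keys_only ? 0 : nrep);
  NumericMatrix heights(keys_only ? 0 : nrep,
                        keys_only ? 0 : n_internal);

  std::vector< std::vector<Lineage> > surv(M);
  std::vector<int> join_l(n_internal), join_r(n_internal);
  std::vector<double> join_h(n_internal);
  std::vector<uint32_t> split_masks;
  const uint32_t full = (ntip >= 32) ? 0xffffffffu
                                     : ((uint32_t(1) << ntip) - 1u);

  for (int rep = 0; rep < nrep; ++rep) {
    int next_internal = 0;
    for (int oi = 0; oi < M; ++oi) {
      const int v = porder[oi];
      std::vector<Lineage> act;
      if (v < ntip) {
        for (int a = 0; a < n_alleles[v]; ++a) {
          Lineage ln;
          ln.id = leaf_offset[v] + a;
          ln.height = age[v];
          ln.mask = (ntip <= 32) ? (uint32_t(1) << tip_bit[v]) : 0u;
          act.push_back(ln);
        }
      } else {
        for (size_t c = 0; c < children[v].size(); ++c) {
          std::vector<Lineage>& s = surv[children[v][c]];
          act.insert(act.end(), s.begin(), s.end());
          s.clear();
        }
      }
      const bool at_root = (parent[v] < 0);
      const double tmax = at_root ? 0.0 : age[parent[v]];
      double cur = age[v];
      while ((int)act.size() >= 2) {
        const int k = (int)act.size();
        const double rate = 0.5 * k * (k - 1);
        const double w = exp_rand() / rate;
        if (!at_root && cur + w > tmax) break;
        cur += w;
        int i = (int)(k * unif_rand());
        if (i >= k) i = k - 1;
        int j = (int)((k - 1) * unif_rand());
        if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        const int gid = total_tips + next_internal;
        join_l[next_internal] = act[i].id;
        join_r[next_internal] = act[j].id;
        join_h[next_internal] = cur;
        Lineage merged;
        merged.id = gid;
        merged.height = cur;
        merged.mask = act[i].mask | act[j].mask;
        ++next_internal;
        if (i > j) std::swap(i, j);
        act[i] = merged;
        act.erase(act.begin() + j);
      }
      surv[v] = act;
    }
    // root of the species tree is porder[M-1]; its survivors coalesced
    // without bound, so exactly one lineage remains
    surv[porder[M - 1]].clear();

    if (keys_only) {
      split_masks.clear();
      // masks per gene node; join ids are created in increasing order so
      // children always precede parents
      std::vector<uint32_t> gmask(total_tips + n_internal);
      {
        int t = 0;
        for (int i = 0; i < ntip; ++i)
          for (int a = 0; a < n_alleles[i]; ++a)
            gmask[t++] = (uint32_t(1) << tip_bit[i]);
      }
      for (int t = 0; t < n_internal; ++t)
        gmask[total_tips + t] = gmask[join_l[t]] | gmask[join_r[t]];
      for (int t = 0; t < n_internal; ++t) {
        uint32_t m = gmask[total_tips + t];
        if (m & 1u) m = full & ~m;  // canonical: side without reference bit
        const int pc = popcount32(m);
        if (pc >= 2 && pc <= ntip - 2) split_masks.push_back(m);
      }
      std::sort(split_masks.begin(), split_masks.end());
      split_masks.erase(std::unique(split_masks.begin(), split_masks.end()),
                        split_masks.end());
      std::string key;
      char buf[16];
      for (size_t s = 0; s < split_masks.size(); ++s) {
        if (s) key += '-';
        snprintf(buf, sizeof(buf), "%u", split_masks[s]);
        key += buf;
      }
      keys[rep] = key;
    } else {
      IntegerMatrix jm(n_internal, 2);
      for (int t = 0; t < n_internal; ++t) {
        jm(t, 0) = join_l[t] + 1;  // 1-based for R
        jm(t, 1) = join_r[t] + 1;
        heights(rep, t) = join_h[t];
      }
      joins[rep] = jm;
    }
  }

  if (keys_only) return List::create(_["keys"] = keys);
  return List::create(_["joins"] = joins, _["heights"] = heights);
}
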