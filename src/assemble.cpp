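#include "common.h"
using namespace Rcpp;

// De Bruijn assembler over canonical kmers: solid-kmer graph, iterative tip
// clipping and simple-bubble popping, unitig (maximal unbranched path)
// extraction with mean kmer coverage.

namespace {

struct OKmer { u128 f, r; };  // one kmer in a fixed orientation

inline u128 canon(const OKmer& o) { return o.f < o.r ? o.f : o.r; }

struct Graph {
  int k;
  u128 mask;
  int shift;
  KmerMap kmers;  // canonical -> count

  bool has(const OKmer& o) const { return kmers.count(canon(o)) > 0; }
  uint32_t count(const OKmer& o) const {
    auto it = kmers.find(canon(o));
    return it == kmers.end() ? 0 : it->second;
  }
  OKmer succ(const OKmer& o, int b) const {
    OKmer n;
    n.f = ((o.f << 2) | (u128)b) & mask;
    n.r = (o.r >> 2) | ((u128)(3 - b) << shift);
    return n;
  }
  OKmer pred(const OKmer& o, int b) const {
    OKmer n;
    n.f = (o.f >> 2) | ((u128)b << shift);
    n.r = ((o.r << 2) | (u128)(3 - b)) & mask;
    return n;
  }
  int out_deg(const OKmer& o, int* only_b = nullptr) const {
    int d = 0;
    for (int b = 0; b < 4; ++b)
      if (has(succ(o, b))) { ++d; if (only_b) *only_b = b; }
    return d;
  }
  int in_deg(const OKmer& o, int* only_b = nullptr) const {
    int d = 0;
    for (int b = 0; b < 4; ++b)
      if (has(pred(o, b))) { ++d; if (only_b) *only_b = b; }
    return d;
  }
};

struct Unitig {
  std::string seq;
  double covsum = 0;
  int nk = 0;
  OKmer first, last;  // oriented terminal kmers (orientation of seq)
};

// Maximal unbranched paths over the current kmer set.
std::vector<Unitig> build_unitigs(const Graph& g) {
  std::vector<Unitig> out;
  KmerSet visited;
  visited.reserve(g.kmers.size() * 2);
  for (auto& kv : g.kmers) {
    if (visited.count(kv.first)) continue;
    OKmer start;
    start.f = kv.first;
    start.r = rc_kmer(kv.first, g.k);
    visited.insert(kv.first);

    Unitig u;
    u.seq = decode_kmer(start.f, g.k);
    u.covsum = kv.second;
    u.nk = 1;
    u.first = start;
    u.last = start;

    // extend right
    OKmer cur = start;
    while (true) {
      int b = -1;
      if (g.out_deg(cur, &b) != 1) break;
      OKmer nxt = g.succ(cur, b);
      if (g.in_deg(nxt) != 1) break;
      u128 cn = canon(nxt);
      if (visited.count(cn)) break;  // cycle or already consumed
      visited.insert(cn);
      u.seq.push_back(bit2base(b));
      u.covsum += g.count(nxt);
      u.nk += 1;
      cur = nxt;
    }
    u.last = cur;

    // extend left
    cur = start;
    while (true) {
      int b = -1;
      if (g.in_deg(cur, &b) != 1) break;
      OKmer prv = g.pred(cur, b);
      if (g.out_deg(prv) != 1) break;
      u128 cn = canon(prv);
      if (visited.count(cn)) break;
      visited.insert(cn);
      u.seq.insert(u.seq.begin(), bit2base(b));
      u.covsum += g.count(prv);
      u.nk += 1;
      cur = prv;
    }
    u.first = cur;
    out.push_back(std::move(u));
  }
  return out;
}

void erase_unitig_kmers(Graph& g, const Unitig& u) {
  for_each_kmer(u.seq, g.k, [&](u128 f, u128 r, long) {
    g.kmers.erase(f < r ? f : r);
  });
}

// Banded unit-cost edit distance (identity check for bubbles).
int banded_edit(const std::string& a, const std::string& b, int band) {
  int m = (int)a.size(), n = (int)b.size();
  if (std::abs(m - n) > band + std::abs(m - n)) return std::max(m, n);
  int lo = std::min(0, n - m) - band, hi = std::max(0, n - m) + band;
  const int INF = 1 << 28;
  int width = hi - lo + 1;
  std::vector<int> prev(width, INF), cur(width, INF);
  for (int d = lo; d <= hi; ++d) if (d >= 0) prev[d - lo] = d;
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int d = lo; d <= hi; ++d) {
      int j = i + d;
      if (j < 0 || j > n) continue;
      int best = INF;
      if (j == 0) best = i;
      if (j > 0 && prev[d - lo] < INF)  // diagonal (prev i-1, j-1 same d)
        best = std::min(best, prev[d - lo] + (a[i - 1] == b[j - 1] ? 0 : 1));
      if (d - 1 >= lo && cur[d - 1 - lo] < INF)  // gap in a (consume b)
        best = std::min(best, cur[d - 1 - lo] + 1);
      if (d + 1 <= hi && prev[d + 1 - lo] < INF)  // gap in b (consume a)
        best = std::min(best, prev[d + 1 - lo] + 1);
      cur[d - lo] = best;
    }
    std::swap(prev, cur);
  }
  int d = n - m;
  if (d < lo || d > hi) return std::max(m, n);
  return prev[d - lo];
}

u128 node_canon(const std::string& seq, int k, bool left) {
  // canonical (k-1)-mer at a unitig end
  std::string nm = left ? seq.substr(0, k - 1) : seq.substr(seq.size() - (k - 1));
  u128 f = 0;
  for (char c : nm) f = (f << 2) | (u128)base2bit(c);
  u128 r = rc_kmer(f, k - 1);
  return f < r ? f : r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int min_cov, int tip_len_max,
                  double bubble_identity, int max_rounds) {
  Graph g;
  g.k = k;
  g.mask = ((u128)1 << (2 * k)) - 1;
  g.shift = 2 * (k - 1);

  {
    KmerMap all;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
      std::string s(CHAR(STRING_ELT(reads, i)));
      for_each_kmer(s, k, [&](u128 f, u128 r, long) {
        u128 c = f < r ? f : r;
        ++all[c];
      });
    }
    for (auto& kv : all)
      if ((int)kv.second >= min_cov) g.kmers.emplace(kv.first, kv.second);
  }
  if (g.kmers.empty())
    stop("empty kmer graph after coverage filtering (min_cov = %d)", min_cov);

  for (int round = 0; round < max_rounds; ++round) {
    std::vector<Unitig> us = build_unitigs(g);

    // ---- tip clipping ----
    // A tip dangles at exactly one end, is shorter than tip_len_max, and its
    // attachment junction has an alternative branch.  When several tips share
    // one junction the best one (longest, then highest coverage) is kept.
    std::vector<int> tip_idx;
    std::vector<u128> tip_node;
    for (size_t i = 0; i < us.size(); ++i) {
      const Unitig& u = us[i];
      if ((int)u.seq.size() >= tip_len_max) continue;
      Graph& gc = g;
      int ld = gc.in_deg(u.first), rd = gc.out_deg(u.last);
      bool left_free = (ld == 0), right_free = (rd == 0);
      if (left_free == right_free) continue;  // internal or isolated
      // junction alternative check at the attached end
      bool alt = false;
      if (right_free) {
        for (int b = 0; b < 4; ++b) {
          OKmer p = gc.pred(u.first, b);
          if (gc.has(p) && gc.out_deg(p) >= 2) { alt = true; break; }
        }
        if (alt) { tip_idx.push_back((int)i); tip_node.push_back(node_canon(u.seq, k, true)); }
      } else {
        for (int b = 0; b < 4; ++b) {
          OKmer s = gc.succ(u.last, b);
          if (gc.has(s) && gc.in_deg(s) >= 2) { alt = true; break; }
        }
        if (alt) { tip_idx.push_back((int)i); tip_node.push_back(node_canon(u.seq, k, false)); }
      }
    }
    int removed = 0;
    if (!tip_idx.empty()) {
      // group tips by attachment node; keep the best per group
      std::unordered_map<u128, std::vector<int>, U128Hash> groups;
      for (size_t t = 0; t < tip_idx.size(); ++t)
        groups[tip_node[t]].push_back(tip_idx[t]);
      for (auto& kv : groups) {
        std::vector<int>& v = kv.second;
        if (v.size() > 1) {
          std::sort(v.begin(), v.end(), [&](int a, int b) {
            if (us[a].seq.size() != us[b].seq.size())
              return us[a].seq.size() > us[b].seq.size();
            double ca = us[a].covsum / us[a].nk, cb = us[b].covsum / us[b].nk;
            if (ca != cb) return ca > cb;
            return us[a].seq < us[b].seq;
          });
          for (size_t j = 1; j < v.size(); ++j) {
            erase_unitig_kmers(g, us[v[j]]);
            ++removed;
          }
        } else {
          erase_unitig_kmers(g, us[v[0]]);
          ++removed;
        }
      }
    }
    if (removed > 0) continue;

    // ---- simple bubble popping ----
    // Two unitigs sharing both junction (k-1)-mer endpoints with sequence
    // identity >= bubble_identity: keep the higher-coverage path.
    std::map<std::pair<u128, u128>, std::vector<int>> pairs;
    for (size_t i = 0; i < us.size(); ++i) {
      const Unitig& u = us[i];
      if (g.in_deg(u.first) == 0 || g.out_deg(u.last) == 0) continue;
      u128 a = node_canon(u.seq, k, true), b = node_canon(u.seq, k, false);
      if (a > b) std::swap(a, b);
      pairs[{a, b}].push_back((int)i);
    }
    std::vector<char> dead(us.size(), 0);
    for (auto& kv : pairs) {
      std::vector<int>& v = kv.second;
      if (v.size() < 2) continue;
      std::sort(v.begin(), v.end(), [&](int a, int b) {
        double ca = us[a].covsum / us[a].nk, cb = us[b].covsum / us[b].nk;
        if (ca != cb) return ca > cb;
        if (us[a].seq.size() != us[b].seq.size())
          return us[a].seq.size() > us[b].seq.size();
        return us[a].seq < us[b].seq;
      });
      const Unitig& keep = us[v[0]];
      for (size_t j = 1; j < v.size(); ++j) {
        const Unitig& cand = us[v[j]];
        if (dead[v[j]]) continue;
        std::string a = keep.seq, b = cand.seq;
        std::string brc = revcomp(b);
        int band = (int)(std::abs((long)a.size() - (long)b.size())) + 16;
        int d1 = banded_edit(a, b, band);
        int d2 = banded_edit(a, brc, band);
        int d = std::min(d1, d2);
        double ident = 1.0 - (double)d / std::max(a.size(), b.size());
        if (ident >= bubble_identity) {
          erase_unitig_kmers(g, cand);
          dead[v[j]] = 1;
          ++removed;
        }
      }
    }
    if (removed == 0) break;
  }

  std::vector<Unitig> finals = build_unitigs(g);
  // canonical strand, deterministic order (length desc, then lexicographic)
  std::vector<std::pair<std::string, double>> res;
  res.reserve(finals.size());
  for (auto& u : finals) {
    std::string rc = revcomp(u.seq);
    std::string s = std::min(u.seq, rc);
    res.emplace_back(s, u.covsum / u.nk);
  }
  std::sort(res.begin(), res.end(), [](const auto& a, const auto& b) {
    if (a.first.size() != b.first.size()) return a.first.size() > b.first.size();
    return a.first < b.first;
  });
  CharacterVector seqs(res.size());
  NumericVector cov(res.size());
  for (size_t i = 0; i < res.size(); ++i) {
    seqs[i] = res[i].first;
    cov[i] = res[i].second;
  }
  return List::create(_["sequence"] = seqs, _["mean_cov"] = cov);
}
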