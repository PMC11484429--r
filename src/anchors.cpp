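#include "common.h"
using namespace Rcpp;

// Exact kmer anchor matching between query sequences and a target, used by
// the scaffolder (contig ordering/orientation), whole-sequence alignment and
// cross-contig filtering.  Strand +1 means query[qpos..qpos+k) equals
// target[tpos..tpos+k); strand -1 means it equals its reverse complement.

// [[Rcpp::export]]
DataFrame cpp_anchor_map(CharacterVector queries, std::string target, int k,
                         int max_occ, int step) {
  // target index: canonical kmer -> encoded positions (sign = orientation)
  std::unordered_map<u128, std::vector<long>, U128Hash> ix;
  KmerSet banned;
  for_each_kmer(target, k, [&](u128 f, u128 r, long p) {
    u128 c = f < r ? f : r;
    if (banned.count(c)) return;
    auto& v = ix[c];
    if ((int)v.size() >= max_occ) {
      ix.erase(c);
      banned.insert(c);
      return;
    }
    v.push_back(f <= r ? (p + 1) : -(p + 1));
  });

  std::vector<int> qidx;
  std::vector<double> qpos, tpos;
  std::vector<int> strand;
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string q(CHAR(STRING_ELT(queries, qi)));
    for_each_kmer(q, k, [&](u128 f, u128 r, long p) {
      if (step > 1 && (p % step)) return;
      u128 c = f < r ? f : r;
      auto it = ix.find(c);
      if (it == ix.end()) return;
      bool q_fwd_is_canon = (f <= r);
      for (long enc : it->second) {
        long tp = std::labs(enc) - 1;
        bool t_fwd_is_canon = enc > 0;
        qidx.push_back((int)qi + 1);
        qpos.push_back((double)p);
        tpos.push_back((double)tp);
        strand.push_back(q_fwd_is_canon == t_fwd_is_canon ? 1 : -1);
      }
    });
  }
  return DataFrame::create(_["query"] = wrap(qidx), _["qpos"] = wrap(qpos),
                           _["tpos"] = wrap(tpos), _["strand"] = wrap(strand),
                           _["stringsAsFactors"] = false);
}

// Internal low-complexity annotator: homopolymer runs >= hp_min and tandem
// repeats of period <= max_period with >= min_copies copies.  0-based
// half-open merged intervals.
// [[Rcpp::export]]
DataFrame cpp_low_complexity(std::string seq, int hp_min, int max_period,
                             int min_copies) {
  long n = (long)seq.size();
  std::vector<std::pair<long, long>> iv;
  // homopolymers
  long i = 0;
  while (i < n) {
    long j = i;
    while (j < n && toupper(seq[j]) == toupper(seq[i])) ++j;
    if (j - i >= hp_min && base2bit(seq[i]) >= 0) iv.push_back({i, j});
    i = j;
  }
  // short tandems
  for (int p = 2; p <= max_period; ++p) {
    long s = p;
    while (s < n) {
      if (toupper(seq[s]) == toupper(seq[s - p]) && base2bit(seq[s]) >= 0) {
        long e = s;
        while (e < n && toupper(seq[e]) == toupper(seq[e - p]) &&
               base2bit(seq[e]) >= 0)
          ++e;
        long span = e - (s - p);
        if (span >= (long)p * min_copies) iv.push_back({s - p, e});
        s = e + 1;
      } else {
        ++s;
      }
    }
  }
  std::sort(iv.begin(), iv.end());
  std::vector<double> st, en;
  for (auto& pr : iv) {
    if (!st.empty() && pr.first <= en.back())
      en.back() = std::max(en.back(), (double)pr.second);
    else {
      st.push_back((double)pr.first);
      en.push_back((double)pr.second);
    }
  }
  return DataFrame::create(_["start"] = wrap(st), _["end"] = wrap(en),
                           _["stringsAsFactors"] = false);
}
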