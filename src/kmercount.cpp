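#include "common.h"
using namespace Rcpp;

static KmerMap count_canonical(const CharacterVector& reads, int k) {
  KmerMap m;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* p = CHAR(STRING_ELT(reads, i));
    std::string s(p);
    for_each_kmer(s, k, [&](u128 f, u128 r, long) {
      u128 c = f < r ? f : r;
      ++m[c];
    });
  }
  return m;
}

// Canonical kmer multiset as (kmer string, count), sorted by kmer.
// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector reads, int k) {
  KmerMap m = count_canonical(reads, k);
  std::vector<std::pair<u128, uint32_t>> v(m.begin(), m.end());
  std::sort(v.begin(), v.end());
  CharacterVector kk(v.size());
  IntegerVector cc(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    kk[i] = decode_kmer(v[i].first, k);
    cc[i] = (int)v[i].second;
  }
  return List::create(_["kmer"] = kk, _["count"] = cc);
}

// Number of distinct canonical kmers with multiplicity >= min_cov.
// [[Rcpp::export]]
double cpp_distinct_solid(CharacterVector reads, int k, int min_cov) {
  KmerMap m = count_canonical(reads, k);
  double n = 0;
  for (auto& kv : m) if ((int)kv.second >= min_cov) ++n;
  return n;
}

// Total kmer instances (sum over reads of max(0, len - k + 1), N-free windows).
// [[Rcpp::export]]
double cpp_total_kmers(CharacterVector reads, int k) {
  double tot = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s(CHAR(STRING_ELT(reads, i)));
    for_each_kmer(s, k, [&](u128, u128, long) { ++tot; });
  }
  return tot;
}

// Number of distinct canonical kmers across the reads; supports k beyond
// the packed-integer limit (e.g. full-read 150mers) via a string set.
// [[Rcpp::export]]
double cpp_unique_kmer_count(CharacterVector reads, int k) {
  if (k <= 63) {
    KmerSet s;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
      std::string x(CHAR(STRING_ELT(reads, i)));
      for_each_kmer(x, k, [&](u128 f, u128 r, long) {
        s.insert(f < r ? f : r);
      });
    }
    return (double)s.size();
  }
  std::unordered_set<std::string> s;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string x(CHAR(STRING_ELT(reads, i)));
    int n = (int)x.size();
    for (int p = 0; p + k <= n; ++p) {
      bool ok = true;
      for (int j = p; j < p + k; ++j)
        if (base2bit(x[j]) < 0) { ok = false; p = j; break; }
      if (!ok) continue;
      std::string w = x.substr(p, k);
      for (auto& c : w) c = toupper(c);
      std::string r = revcomp(w);
      s.insert(w < r ? w : r);
    }
  }
  return (double)s.size();
}

// Histogram of multiplicities: res[m] = number of distinct kmers seen m times
// (multiplicities above max_mult are lumped into the last bin).
// [[Rcpp::export]]
NumericVector cpp_kmer_spectrum(CharacterVector reads, int k, int max_mult) {
  KmerMap m = count_canonical(reads, k);
  NumericVector h(max_mult);
  for (auto& kv : m) {
    int c = std::min((int)kv.second, max_mult);
    h[c - 1] += 1;
  }
  return h;
}
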