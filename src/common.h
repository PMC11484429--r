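#pragma once

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

// 2-bit packed kmers up to k = 63 in an unsigned 128-bit integer.
typedef unsigned __int128 u128;

inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

inline char bit2base(int b) { return "ACGT"[b & 3]; }

inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct U128Hash {
  size_t operator()(u128 x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    lo ^= hi * 0xC2B2AE3D27D4EB4FULL;
    lo *= 0x9E3779B97F4A7C15ULL;
    lo ^= lo >> 32;
    lo *= 0xBF58476D1CE4E5B9ULL;
    lo ^= lo >> 29;
    return (size_t)lo;
  }
};

// Calls f(fwd, rc, pos0) for every kmer window free of non-ACGT bases.
template <typename F>
inline void for_each_kmer(const std::string& s, int k, F f) {
  if ((int)s.size() < k) return;
  const u128 mask = ((u128)1 << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  u128 fwd = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128)b) & mask;
    rc = (rc >> 2) | ((u128)(3 - b) << shift);
    if (++run >= k) f(fwd, rc, (long)(i + 1 - k));
  }
}

inline std::string decode_kmer(u128 x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bit2base((int)(x & 3)); x >>= 2; }
  return s;
}

inline u128 rc_kmer(u128 x, int k) {
  u128 r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (u128)(3 - (int)(x & 3)); x >>= 2; }
  return r;
}

typedef std::unordered_map<u128, uint32_t, U128Hash> KmerMap;
typedef std::unordered_set<u128, U128Hash> KmerSet;
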