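#include "common.h"
using namespace Rcpp;

// Seed-chain-extend short-read mapper and banded Gotoh alignment.
// Scoring follows end-to-end semantics: match 0, mismatch -mm, gap of
// length L costs -(gapopen + gapext * L).  A read maps when its score is
// >= score_coef * read_length (the "L,0,-0.6" linear threshold).

namespace {

const int NEG = -(1 << 28);

struct AlnResult {
  bool ok = false;
  int score = NEG;
  long tstart = 0, tend = 0;
  std::string cigar;  // ops =, X, I (consumes query), D (consumes target)
};

inline int sub_score(char a, char b, int mismatch) {
  char ua = toupper(a), ub = toupper(b);
  if (ua == 'N' || ub == 'N') return -1;
  return ua == ub ? 0 : -mismatch;
}

void push_op(std::string& cig, char op, int n) {
  if (n <= 0) return;
  cig += std::to_string(n);
  cig.push_back(op);
}

// Banded Gotoh with traceback.  Band: j - i in [lo, hi].
// free_t_ends: leading/trailing target bases are unpenalised (fit alignment);
// the query is always consumed end to end.
AlnResult gotoh_band(const std::string& q, const std::string& t, int lo, int hi,
                     int mismatch, int gapopen, int gapext, bool free_t_ends,
                     double max_cells) {
  AlnResult res;
  int m = (int)q.size(), n = (int)t.size();
  int width = hi - lo + 1;
  if (width <= 0) return res;
  if ((double)(m + 1) * width > max_cells) return res;

  std::vector<int> M((size_t)(m + 1) * width, NEG);
  std::vector<int> I((size_t)(m + 1) * width, NEG);
  std::vector<int> D((size_t)(m + 1) * width, NEG);
  auto idx = [&](int i, int j) { return (size_t)i * width + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= n && j - i >= lo && j - i <= hi;
  };

  for (int j = 0; j <= n; ++j) {
    if (!inband(0, j)) continue;
    if (free_t_ends) M[idx(0, j)] = 0;
    else {
      if (j == 0) M[idx(0, 0)] = 0;
      else D[idx(0, j)] = -(gapopen + gapext * j);
    }
  }
  for (int i = 1; i <= m; ++i) {
    for (int d = lo; d <= hi; ++d) {
      int j = i + d;
      if (j < 0 || j > n) continue;
      size_t c = idx(i, j);
      // I: gap in target, consumes query base i
      if (inband(i - 1, j)) {
        size_t p = idx(i - 1, j);
        int open_from = std::max(M[p], D[p]);
        I[c] = std::max(open_from == NEG ? NEG : open_from - gapopen - gapext,
                        I[p] == NEG ? NEG : I[p] - gapext);
      }
      // D: gap in query, consumes target base j
      if (inband(i, j - 1)) {
        size_t p = idx(i, j - 1);
        int open_from = std::max(M[p], I[p]);
        D[c] = std::max(open_from == NEG ? NEG : open_from - gapopen - gapext,
                        D[p] == NEG ? NEG : D[p] - gapext);
      }
      // M: (mis)match consumes both
      if (j >= 1 && inband(i - 1, j - 1)) {
        size_t p = idx(i - 1, j - 1);
        int best = std::max(M[p], std::max(I[p], D[p]));
        if (best > NEG) M[c] = best + sub_score(q[i - 1], t[j - 1], mismatch);
      }
    }
  }

  // terminal cell
  int bj = -1, bscore = NEG;
  char bstate = 'M';
  if (free_t_ends) {
    for (int d = lo; d <= hi; ++d) {
      int j = m + d;
      if (j < 0 || j > n) continue;
      size_t c = idx(m, j);
      if (M[c] > bscore) { bscore = M[c]; bj = j; bstate = 'M'; }
      if (I[c] > bscore) { bscore = I[c]; bj = j; bstate = 'I'; }
    }
  } else {
    if (!inband(m, n)) return res;
    size_t c = idx(m, n);
    bscore = std::max(M[c], std::max(I[c], D[c]));
    bj = n;
    bstate = (bscore == M[c]) ? 'M' : (bscore == I[c] ? 'I' : 'D');
  }
  if (bj < 0 || bscore <= NEG) return res;

  // traceback
  std::string ops;
  int i = m, j = bj;
  char st = bstate;
  while (i > 0 || (!free_t_ends && j > 0)) {
    if (i == 0 && free_t_ends) break;
    size_t c = idx(i, j);
    if (st == 'M') {
      int v = M[c];
      ops.push_back(toupper(q[i - 1]) == toupper(t[j - 1]) &&
                            toupper(q[i - 1]) != 'N'
                        ? '='
                        : 'X');
      size_t p = idx(i - 1, j - 1);
      int prevbest = v - sub_score(q[i - 1], t[j - 1], mismatch);
      --i; --j;
      if (i == 0 && free_t_ends) break;
      if (inband(i, j)) {
        if (M[idx(i, j)] == prevbest) st = 'M';
        else if (I[idx(i, j)] == prevbest) st = 'I';
        else st = 'D';
      }
    } else if (st == 'I') {
      ops.push_back('I');
      size_t p = idx(i - 1, j);
      int v = I[c];
      --i;
      if (inband(i, j)) {
        if (I[p] != NEG && v == I[p] - gapext) st = 'I';
        else st = (M[p] >= D[p]) ? 'M' : 'D';
      }
    } else {  // D
      ops.push_back('D');
      size_t p = idx(i, j - 1);
      int v = D[c];
      --j;
      if (j >= 0 && inband(i, j)) {
        if (D[p] != NEG && v == D[p] - gapext) st = 'D';
        else st = (M[p] >= I[p]) ? 'M' : 'I';
      }
      if (j == 0 && i == 0) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // compress
  std::string cig;
  size_t s = 0;
  while (s < ops.size()) {
    size_t e = s;
    while (e < ops.size() && ops[e] == ops[s]) ++e;
    push_op(cig, ops[s], (int)(e - s));
    s = e;
  }
  res.ok = true;
  res.score = bscore;
  res.tstart = free_t_ends ? j : 0;
  res.tend = bj;
  res.cigar = cig;
  return res;
}

struct SeedIndex {
  int k = 21;
  std::unordered_map<u128, std::vector<int>, U128Hash> pos;  // fwd kmer -> positions
  KmerSet banned;

  void build(const std::string& ref, int kk, int max_occ) {
    k = kk;
    for_each_kmer(ref, k, [&](u128 f, u128, long p) {
      if (banned.count(f)) return;
      auto& v = pos[f];
      if ((int)v.size() >= max_occ) {
        pos.erase(f);
        banned.insert(f);
        return;
      }
      v.push_back((int)p);
    });
  }
};

// best diagonal by seed voting; returns votes (0 = no seeds)
int best_diagonal(const std::string& q, const SeedIndex& ix, int step,
                  long* diag_out) {
  std::vector<long> diags;
  for_each_kmer(q, ix.k, [&](u128 f, u128, long qp) {
    if (step > 1 && (qp % step)) return;
    auto it = ix.pos.find(f);
    if (it == ix.pos.end()) return;
    for (int tp : it->second) diags.push_back((long)tp - qp);
  });
  if (diags.empty()) return 0;
  std::sort(diags.begin(), diags.end());
  int best = 0;
  long bestd = diags[0];
  size_t j = 0;
  for (size_t i = 0; i < diags.size(); ++i) {
    while (diags[i] - diags[j] > 16) ++j;
    int cnt = (int)(i - j + 1);
    if (cnt > best) { best = cnt; bestd = diags[j] + (diags[i] - diags[j]) / 2; }
  }
  *diag_out = bestd;
  return best;
}

AlnResult extend_at(const std::string& q, const std::string& ref, long diag,
                    int band, int mismatch, int gapopen, int gapext,
                    bool want_cigar) {
  AlnResult res;
  long m = (long)q.size(), n = (long)ref.size();
  // gap-free fast path
  if (diag >= 0 && diag + m <= n) {
    int mm = 0;
    for (long i = 0; i < m; ++i)
      if (toupper(q[i]) != toupper(ref[diag + i])) ++mm;
    if (mm <= 2) {
      res.ok = true;
      res.score = -mismatch * mm;
      res.tstart = diag;
      res.tend = diag + m;
      if (want_cigar) {
        std::string ops;
        for (long i = 0; i < m; ++i)
          ops.push_back(toupper(q[i]) == toupper(ref[diag + i]) ? '=' : 'X');
        std::string cig;
        size_t s = 0;
        while (s < ops.size()) {
          size_t e = s;
          while (e < ops.size() && ops[e] == ops[s]) ++e;
          push_op(res.cigar, ops[s], (int)(e - s));
          s = e;
        }
      }
      return res;
    }
  }
  long ws = std::max(0L, diag - band);
  long we = std::min(n, diag + m + band);
  if (we <= ws) return res;
  std::string win = ref.substr(ws, we - ws);
  AlnResult a = gotoh_band(q, win, 0, (int)std::min((long)2 * band + 8, (long)win.size()),
                           mismatch, gapopen, gapext, true, 4e7);
  if (!a.ok) return res;
  a.tstart += ws;
  a.tend += ws;
  if (!want_cigar) a.cigar.clear();
  return a;
}

}  // namespace

// Exposed banded pairwise alignment (global, or fit when free_t_ends).
// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band, int mismatch,
                      int gapopen, int gapext, bool free_t_ends) {
  int m = (int)a.size(), n = (int)b.size();
  int lo, hi;
  if (free_t_ends) { lo = -band; hi = n - m + band; }
  else { lo = std::min(0, n - m) - band; hi = std::max(0, n - m) + band; }
  AlnResult r = gotoh_band(a, b, lo, hi, mismatch, gapopen, gapext, free_t_ends, 6e7);
  if (!r.ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["score"] = r.score,
                      _["cigar"] = r.cigar, _["tstart"] = (double)r.tstart,
                      _["tend"] = (double)r.tend);
}

// Map reads to a reference; per read the best end-to-end placement.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string ref, int k_seed,
                        int step, int band, int mismatch, int gapopen,
                        int gapext, double score_coef, int max_occ) {
  SeedIndex ix;
  ix.build(ref, k_seed, max_occ);
  R_xlen_t nr = reads.size();
  NumericVector pos(nr), tend(nr);
  IntegerVector score(nr), strand(nr);
  LogicalVector mapped(nr);
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::string q(CHAR(STRING_ELT(reads, i)));
    std::string qr = revcomp(q);
    long d1 = 0, d2 = 0;
    int v1 = best_diagonal(q, ix, step, &d1);
    int v2 = best_diagonal(qr, ix, step, &d2);
    AlnResult best;
    int bstrand = 0;
    if (v1 > 0) {
      AlnResult r = extend_at(q, ref, d1, band, mismatch, gapopen, gapext, false);
      if (r.ok) { best = r; bstrand = 1; }
    }
    if (v2 > 0) {
      AlnResult r = extend_at(qr, ref, d2, band, mismatch, gapopen, gapext, false);
      if (r.ok && r.score > best.score) { best = r; bstrand = -1; }
    }
    double thr = score_coef * (double)q.size();
    if (bstrand != 0 && best.ok) {
      pos[i] = (double)best.tstart;
      tend[i] = (double)best.tend;
      score[i] = best.score;
      strand[i] = bstrand;
      mapped[i] = best.score >= thr;
    } else {
      pos[i] = NA_REAL;
      tend[i] = NA_REAL;
      score[i] = NA_INTEGER;
      strand[i] = NA_INTEGER;
      mapped[i] = false;
    }
  }
  return DataFrame::create(_["pos"] = pos, _["end"] = tend, _["score"] = score,
                           _["strand"] = strand, _["mapped"] = mapped,
                           _["stringsAsFactors"] = false);
}

// Pileup-based polishing: map reads onto the contig set, majority-vote
// substitution and small indel corrections (depth >= min_depth and majority
// fraction >= min_frac).
// [[Rcpp::export]]
List cpp_polish(CharacterVector contigs, CharacterVector reads, int k_seed,
                int step, int band, int mismatch, int gapopen, int gapext,
                double score_coef, int max_occ, int min_depth,
                double min_frac) {
  // concatenate contigs with N spacers
  std::string ref;
  std::vector<long> off;
  std::vector<long> clen;
  for (R_xlen_t i = 0; i < contigs.size(); ++i) {
    std::string s(CHAR(STRING_ELT(contigs, i)));
    off.push_back((long)ref.size());
    clen.push_back((long)s.size());
    ref += s;
    ref.push_back('N');
  }
  long L = (long)ref.size();
  SeedIndex ix;
  ix.build(ref, k_seed, max_occ);

  std::vector<std::array<uint32_t, 5>> cnt(L, {0, 0, 0, 0, 0});  // A C G T DEL
  std::vector<int32_t> spandiff(L + 2, 0);
  std::unordered_map<long, std::map<std::string, int>> ins;  // before col j

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string q(CHAR(STRING_ELT(reads, i)));
    std::string qr = revcomp(q);
    long d1 = 0, d2 = 0;
    int v1 = best_diagonal(q, ix, step, &d1);
    int v2 = best_diagonal(qr, ix, step, &d2);
    AlnResult best;
    const std::string* used = nullptr;
    if (v1 > 0) {
      AlnResult r = extend_at(q, ref, d1, band, mismatch, gapopen, gapext, true);
      if (r.ok) { best = r; used = &q; }
    }
    if (v2 > 0) {
      AlnResult r = extend_at(qr, ref, d2, band, mismatch, gapopen, gapext, true);
      if (r.ok && r.score > best.score) { best = r; used = &qr; }
    }
    if (!used || !best.ok) continue;
    if (best.score < score_coef * (double)q.size()) continue;
    // walk cigar
    long j = best.tstart;
    size_t qi = 0;
    size_t ci = 0;
    const std::string& cg = best.cigar;
    const std::string& qq = *used;
    while (ci < cg.size()) {
      long n = 0;
      while (ci < cg.size() && isdigit(cg[ci])) n = n * 10 + (cg[ci++] - '0');
      char op = cg[ci++];
      if (op == '=' || op == 'X') {
        for (long x = 0; x < n; ++x) {
          int b = base2bit(qq[qi + x]);
          if (b >= 0 && j + x < L) cnt[j + x][b]++;
        }
        qi += n;
        j += n;
      } else if (op == 'D') {
        for (long x = 0; x < n; ++x)
          if (j + x < L) cnt[j + x][4]++;
        j += n;
      } else if (op == 'I') {
        if (j > best.tstart && j < L) ins[j][qq.substr(qi, n)]++;
        qi += n;
      }
    }
    if (best.tend - best.tstart >= 2) {
      spandiff[best.tstart + 1] += 1;
      spandiff[best.tend - 1 >= 0 ? best.tend - 1 : 0] -= 1;
    }
  }
  // spanning depth at junction "before column j"
  std::vector<int64_t> span(L + 1, 0);
  int64_t run = 0;
  for (long j = 0; j <= L; ++j) {
    run += spandiff[j];
    span[j] = run;
  }

  CharacterVector outseqs(contigs.size());
  std::vector<int> c_contig;
  std::vector<double> c_pos, c_depth, c_frac;
  std::vector<std::string> c_type, c_ref, c_alt;

  for (R_xlen_t ci2 = 0; ci2 < contigs.size(); ++ci2) {
    long o = off[ci2], len = clen[ci2];
    std::string out;
    out.reserve(len);
    for (long p = 0; p < len; ++p) {
      long j = o + p;
      // insertion before this column
      auto iit = ins.find(j);
      if (iit != ins.end() && p > 0) {
        long jd = span[j];
        if (jd >= min_depth) {
          const std::string* bestins = nullptr;
          int bc = 0;
          for (auto& kv : iit->second)
            if (kv.second > bc || (kv.second == bc && bestins && kv.first < *bestins)) {
              bc = kv.second;
              bestins = &kv.first;
            }
          if (bestins && (double)bc / jd >= min_frac) {
            out += *bestins;
            c_contig.push_back((int)ci2 + 1);
            c_pos.push_back((double)p);
            c_type.push_back("INS");
            c_ref.push_back("");
            c_alt.push_back(*bestins);
            c_depth.push_back((double)jd);
            c_frac.push_back((double)bc / jd);
          }
        }
      }
      auto& cc = cnt[j];
      long depth = (long)cc[0] + cc[1] + cc[2] + cc[3] + cc[4];
      char orig = ref[j];
      if (depth >= min_depth) {
        int bi = 0;
        for (int b = 1; b < 5; ++b) if (cc[b] > cc[bi]) bi = b;
        double frac = (double)cc[bi] / depth;
        if (frac >= min_frac) {
          if (bi == 4) {  // deletion
            if (toupper(orig) != 'N') {
              c_contig.push_back((int)ci2 + 1);
              c_pos.push_back((double)p);
              c_type.push_back("DEL");
              c_ref.push_back(std::string(1, orig));
              c_alt.push_back("");
              c_depth.push_back((double)depth);
              c_frac.push_back(frac);
            }
            continue;  // drop base
          }
          char nb = bit2base(bi);
          if (toupper(orig) != nb) {
            c_contig.push_back((int)ci2 + 1);
            c_pos.push_back((double)p);
            c_type.push_back("SUB");
            c_ref.push_back(std::string(1, orig));
            c_alt.push_back(std::string(1, nb));
            c_depth.push_back((double)depth);
            c_frac.push_back(frac);
          }
          out.push_back(nb);
          continue;
        }
      }
      out.push_back(orig);
    }
    outseqs[ci2] = out;
  }
  DataFrame corr = DataFrame::create(
      _["contig"] = wrap(c_contig), _["pos"] = wrap(c_pos),
      _["type"] = wrap(c_type), _["ref"] = wrap(c_ref), _["alt"] = wrap(c_alt),
      _["depth"] = wrap(c_depth), _["frac"] = wrap(c_frac),
      _["stringsAsFactors"] = false);
  return List::create(_["sequence"] = outseqs, _["corrections"] = corr);
}
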