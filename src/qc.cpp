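#include "common.h"
using namespace Rcpp;

// Quality trimming per read: strip leading/trailing bases with Q < lead_q
// or base N, then scan 5'->3' with windows of window_len, truncating at the
// start of the first window whose mean quality < window_meanq.
// Returns 1-based [start, end] of the retained interval (end < start when
// nothing survives).
// [[Rcpp::export]]
List cpp_trim(CharacterVector seqs, CharacterVector quals, int lead_q,
              int window_len, double window_meanq) {
  R_xlen_t n = seqs.size();
  IntegerVector start(n), end(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const char* q = CHAR(STRING_ELT(quals, i));
    int len = (int)strlen(s);
    int a = 0, b = len - 1;
    while (a < len && ((q[a] - 33) < lead_q || toupper(s[a]) == 'N')) ++a;
    while (b >= a && ((q[b] - 33) < lead_q || toupper(s[b]) == 'N')) --b;
    // sliding window truncation
    if (b - a + 1 >= window_len) {
      for (int w = a; w + window_len - 1 <= b; ++w) {
        int sum = 0;
        for (int j = 0; j < window_len; ++j) sum += q[w + j] - 33;
        if ((double)sum / window_len < window_meanq) {
          b = w - 1;
          break;
        }
      }
    }
    start[i] = a + 1;
    end[i] = b + 1;
  }
  return List::create(_["start"] = start, _["end"] = end);
}
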