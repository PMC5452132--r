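#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped scan: every placement of every read on every target
// with at most max_mismatch positional mismatches. Bytes are compared
// directly, so any non-matching character (including 'N' in a read versus
// an ACGT reference) counts as a mismatch. Early exit once the bound is
// exceeded keeps the inner loop near O(1) per offset for small bounds.
//
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
List hamming_scan_cpp(std::vector<std::string> reads,
                      std::vector<std::string> targets,
                      int max_mismatch) {
  std::vector<int> r_idx, t_idx, starts, mms;
  for (size_t ri = 0; ri < reads.size(); ++ri) {
    const std::string &rd = reads[ri];
    const int L = (int)rd.size();
    const char *rp = rd.data();
    for (size_t ti = 0; ti < targets.size(); ++ti) {
      const std::string &tg = targets[ti];
      const int last = (int)tg.size() - L;
      for (int s = 0; s <= last; ++s) {
        const char *tp = tg.data() + s;
        int mm = 0;
        for (int p = 0; p < L; ++p) {
          if (tp[p] != rp[p] && ++mm > max_mismatch) break;
        }
        if (mm <= max_mismatch) {
          r_idx.push_back((int)ri + 1);
          t_idx.push_back((int)ti + 1);
          starts.push_back(s);
          mms.push_back(mm);
        }
      }
    }
  }
  return List::create(_["read"] = r_idx, _["target"] = t_idx,
                      _["start"] = starts, _["mismatches"] = mms);
}
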