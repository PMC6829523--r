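#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// 3' adapter location + per-read QC summaries for small RNA reads.
//
// The adapter is searched as in conventional sRNA trimmers: at each read
// position p the read suffix must match a prefix of the adapter (the
// adapter runs to the read end, or the full adapter if the read is longer),
// allowing up to floor(max_error_rate * overlap) mismatches, requiring
// overlap >= min_overlap.  The leftmost admissible position wins.
// [[Rcpp::export(name = ".read_qc_cpp")]]
List read_qc_cpp(CharacterVector seqs, CharacterVector quals,
                 std::string adapter, int min_overlap,
                 double max_error_rate, int qual_offset = 33) {
    const int n = seqs.size();
    const int alen = adapter.size();
    IntegerVector insert_len(n);
    NumericVector mean_q(n);
    LogicalVector has_n(n);
    for (int r = 0; r < n; ++r) {
        std::string s = as<std::string>(seqs[r]);
        std::string q = as<std::string>(quals[r]);
        const int len = s.size();
        // mean Phred quality
        double qs = 0.0;
        for (int i = 0; i < len; ++i) qs += q[i] - qual_offset;
        mean_q[r] = len > 0 ? qs / len : 0.0;
        // N content
        bool nn = false;
        for (int i = 0; i < len; ++i)
            if (s[i] == 'N' || s[i] == 'n') { nn = true; break; }
        has_n[r] = nn;
        // adapter search
        int ins = len;
        for (int p = 0; p + min_overlap <= len; ++p) {
            int o = std::min(alen, len - p);
            int max_mm = (int)(max_error_rate * o);
            int mm = 0;
            bool hit = true;
            for (int i = 0; i < o; ++i) {
                if (s[p + i] != adapter[i]) {
                    if (++mm > max_mm) { hit = false; break; }
                }
            }
            if (hit) { ins = p; break; }
        }
        insert_len[r] = ins;
    }
    return List::create(_["insert_len"] = insert_len, _["mean_q"] = mean_q,
                        _["has_n"] = has_n);
}
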