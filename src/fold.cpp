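#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Canonical + wobble pairs on the DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
    switch (a) {
    case 'A': return b == 'T' || b == 'U';
    case 'C': return b == 'G';
    case 'G': return b == 'C' || b == 'T' || b == 'U';
    case 'T':
    case 'U': return b == 'A' || b == 'G';
    default:  return false;
    }
}

// Nussinov base-pair maximisation with a minimum hairpin loop size.
// Returns the dot-bracket structure, the pair count, and the 1-based
// partner vector (0 = unpaired).
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
    const int n = seq.size();
    if (n == 0)
        return List::create(_["structure"] = "", _["pairs"] = 0,
                            _["partner"] = IntegerVector(0));
    // M[i][j] = max pairs in seq[i..j]
    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            const int j = i + len - 1;
            int best = M[i][j - 1];  // j unpaired
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!can_pair(seq[k], seq[j])) continue;
                int v = 1;
                if (k > i) v += M[i][k - 1];
                if (j - k - 1 > 0) v += M[k + 1][j - 1];
                if (v > best) best = v;
            }
            M[i][j] = best;
        }
    }
    std::string db(n, '.');
    IntegerVector partner(n, 0);
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        if (M[i][j] == M[i][j - 1]) {  // prefer leaving j unpaired: deterministic
            stack.push_back(std::make_pair(i, j - 1));
            continue;
        }
        for (int k = i; k <= j - min_loop - 1; ++k) {
            if (!can_pair(seq[k], seq[j])) continue;
            int v = 1;
            if (k > i) v += M[i][k - 1];
            if (j - k - 1 > 0) v += M[k + 1][j - 1];
            if (v == M[i][j]) {
                db[k] = '(';
                db[j] = ')';
                partner[k] = j + 1;
                partner[j] = k + 1;
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                if (j - k - 1 > 0) stack.push_back(std::make_pair(k + 1, j - 1));
                break;
            }
        }
    }
    return List::create(_["structure"] = db, _["pairs"] = M[0][n - 1],
                        _["partner"] = partner);
}
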