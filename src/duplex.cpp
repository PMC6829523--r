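#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Plant miRNA-target duplex penalty scoring (Allen-style):
//   Watson-Crick pair 0, G:U wobble 0.5, mismatch 1, each bulged
//   nucleotide 1; penalties at miRNA positions 2-13 (5' end = 1) are
//   doubled.  The alignment is antiparallel (miRNA 5'->3' against the
//   target window 3'->5') and at most one single-nucleotide bulge, on
//   either strand, is allowed; all placements are enumerated and the
//   minimum-score alignment kept.
//
// Window widths: M (ungapped), M+1 (one bulged target nt), M-1 (one
// bulged miRNA nt), where M = miRNA length.

static inline bool is_wc(char m, char t) {
    return (m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
           (m == 'G' && t == 'C') || (m == 'C' && t == 'G');
}
static inline bool is_gu(char m, char t) {
    // miRNA G : target U(T), or miRNA U(T) : target G
    return (m == 'G' && t == 'T') || (m == 'T' && t == 'G');
}

struct Duplex {
    double score;
    std::string pairing;
    int cleavage;   // window offset (1-based) opposite miRNA position 10
    int gap;        // 0 none, 1 target bulge, 2 mirna bulge
    int bulge;      // placement index b
    bool ok;
};

static inline double pos_pen(char m, char t, int i) {
    double p;
    if (is_wc(m, t)) p = 0.0;
    else if (is_gu(m, t)) p = 0.5;
    else p = 1.0;
    if (i >= 2 && i <= 13) p *= 2.0;
    return p;
}
static inline char pos_sym(char m, char t) {
    if (is_wc(m, t)) return '|';
    if (is_gu(m, t)) return 'o';
    return '.';
}

// Score one alignment of mirna against window given the gap mode and
// bulge placement b.  Returns score and fills pairing string.
static Duplex align_one(const std::string &mir, const std::string &win,
                        int gap, int b) {
    const int M = mir.size(), W = win.size();
    Duplex d;
    d.score = 0.0;
    d.gap = gap;
    d.bulge = b;
    d.cleavage = NA_INTEGER;
    d.ok = true;
    std::string pairing;
    pairing.reserve(M + 1);
    for (int i = 1; i <= M; ++i) {
        int t;  // window position paired with miRNA position i
        if (gap == 0) {
            t = W + 1 - i;
        } else if (gap == 1) {            // bulged target nt after miRNA pos b
            t = (i <= b) ? (W + 1 - i) : (W - i);
        } else {                          // miRNA position b bulged
            if (i == b) {
                double p = 1.0;
                if (i >= 2 && i <= 13) p *= 2.0;
                d.score += p;
                pairing.push_back('-');
                if (i == 10) d.cleavage = W - 9;  // midpoint convention
                continue;
            }
            t = (i < b) ? (W + 1 - i) : (W + 2 - i);
        }
        char mc = mir[i - 1], tc = win[t - 1];
        d.score += pos_pen(mc, tc, i);
        pairing.push_back(pos_sym(mc, tc));
        if (gap == 1 && i == b) pairing.push_back('-');
        if (i == 10) d.cleavage = t;
    }
    if (gap == 1) {
        // bulged target nt sits between miRNA positions b and b+1
        double p = 1.0;
        int q = b + 1;
        if (q >= 2 && q <= 13) p *= 2.0;
        d.score += p;
        if (b == 0) pairing.insert(pairing.begin(), '-');
    }
    d.pairing = pairing;
    return d;
}

static Duplex best_duplex(const std::string &mir, const std::string &win) {
    const int M = mir.size(), W = win.size();
    Duplex best;
    best.ok = false;
    best.score = R_PosInf;
    if (W == M) {
        best = align_one(mir, win, 0, 0);
    } else if (W == M + 1) {
        for (int b = 0; b <= M; ++b) {
            Duplex d = align_one(mir, win, 1, b);
            if (!best.ok || d.score < best.score) best = d;
        }
    } else if (W == M - 1) {
        for (int b = 1; b <= M; ++b) {
            Duplex d = align_one(mir, win, 2, b);
            if (!best.ok || d.score < best.score) best = d;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".score_duplex_cpp")]]
List score_duplex_cpp(std::string mirna, std::string window) {
    Duplex d = best_duplex(mirna, window);
    if (!d.ok)
        stop("window width must be within 1 nt of the miRNA length");
    return List::create(_["score"] = d.score, _["pairing"] = d.pairing,
                        _["cleavage_offset"] = d.cleavage,
                        _["gap"] = d.gap, _["bulge"] = d.bulge);
}

// Slide a miRNA over a transcript, scoring windows of width M-1, M, M+1,
// and return all alignments with score <= max_score.
// [[Rcpp::export(name = ".scan_transcript_cpp")]]
DataFrame scan_transcript_cpp(std::string mirna, std::string transcript,
                              double max_score) {
    const int M = mirna.size(), L = transcript.size();
    std::vector<int> start, width, cleavage;
    std::vector<double> score;
    std::vector<std::string> pairing;
    for (int W = M - 1; W <= M + 1; ++W) {
        if (W < 1) continue;
        for (int s = 0; s + W <= L; ++s) {
            std::string win = transcript.substr(s, W);
            Duplex d = best_duplex(mirna, win);
            if (d.ok && d.score <= max_score) {
                start.push_back(s + 1);
                width.push_back(W);
                score.push_back(d.score);
                cleavage.push_back(d.cleavage == NA_INTEGER
                                       ? NA_INTEGER : s + d.cleavage);
                pairing.push_back(d.pairing);
            }
        }
    }
    return DataFrame::create(_["start"] = start, _["width"] = width,
                             _["score"] = score, _["cleavage"] = cleavage,
                             _["pairing"] = pairing,
                             _["stringsAsFactors"] = false);
}
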