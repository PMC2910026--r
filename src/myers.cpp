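#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Bit-parallel semi-global matcher (Myers' column-difference encoding).
// The pattern is represented by per-letter acceptance masks built in R
// (IUPAC expansion happens there, once per tag); bit i of mask[c] is set
// iff pattern position i accepts read letter c.  Vectors are blocked into
// 64-bit words so the pattern length is unbounded; carries of the
// arithmetic step and of the left shift propagate across words.

typedef uint64_t word;
static const int WBITS = 64;

struct BitVec {
    std::vector<word> w;
    explicit BitVec(int nwords, word fill = 0) : w(nwords, fill) {}
};

// column index for a read letter; anything unexpected maps to -1
static inline int letter_index(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
    }
}

// [[Rcpp::export]]
IntegerVector myers_column_minima(LogicalMatrix masks, std::string text) {
    const int m = masks.nrow();
    const int n = (int) text.size();
    if (m < 1) stop("pattern must be non-empty");
    if (n < 1) stop("text must be non-empty");
    if (masks.ncol() != 5) stop("masks must have 5 columns (A,C,G,T,N)");

    const int B = (m + WBITS - 1) / WBITS;
    const int hw = (m - 1) / WBITS;         // word holding the top pattern bit
    const word hbit = (word)1 << ((m - 1) % WBITS);

    // per-letter pattern masks
    std::vector<std::vector<word> > eq(5, std::vector<word>(B, 0));
    for (int c = 0; c < 5; ++c)
        for (int i = 0; i < m; ++i)
            if (masks(i, c)) eq[c][i / WBITS] |= (word)1 << (i % WBITS);

    std::vector<word> Pv(B, ~(word)0), Mv(B, 0);
    std::vector<word> Xv(B), Xh(B), Ph(B), Mh(B), tmp(B);
    int score = m;
    IntegerVector out(n);

    for (int j = 0; j < n; ++j) {
        int ci = letter_index(text[j]);
        if (ci < 0) stop("invalid read letter '%s' at position %d",
                         std::string(1, text[j]), j + 1);
        const std::vector<word>& Eq = eq[ci];

        // Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq  with carry across words
        word carry = 0;
        for (int b = 0; b < B; ++b) {
            word a = Eq[b] & Pv[b];
            word s = a + Pv[b];
            word c1 = (s < a) ? 1 : 0;
            word s2 = s + carry;
            word c2 = (s2 < s) ? 1 : 0;
            carry = c1 | c2;
            Xh[b] = (s2 ^ Pv[b]) | Eq[b];
            Xv[b] = Eq[b] | Mv[b];
        }
        for (int b = 0; b < B; ++b) {
            Ph[b] = Mv[b] | ~(Xh[b] | Pv[b]);
            Mh[b] = Pv[b] & Xh[b];
        }
        if (Ph[hw] & hbit) ++score;
        else if (Mh[hw] & hbit) --score;
        // shift Ph, Mh left by one; the incoming bit is 0 (first DP row is 0)
        word phc = 0, mhc = 0;
        for (int b = 0; b < B; ++b) {
            word phn = Ph[b] >> (WBITS - 1);
            word mhn = Mh[b] >> (WBITS - 1);
            Ph[b] = (Ph[b] << 1) | phc;
            Mh[b] = (Mh[b] << 1) | mhc;
            phc = phn; mhc = mhn;
        }
        for (int b = 0; b < B; ++b) {
            Pv[b] = Mh[b] | ~(Xv[b] | Ph[b]);
            Mv[b] = Ph[b] & Xv[b];
        }
        out[j] = score;
    }
    return out;
}
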