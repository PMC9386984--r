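#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window Hamming search of a primer within each read (full overlap
// only). Returns a two-column integer matrix: 0-based offset of the best
// (leftmost minimal-distance) window and its Hamming distance; (-1, -1)
// when the primer is longer than the read.
// [[Rcpp::export]]
IntegerMatrix primer_search_cpp(CharacterVector reads, std::string primer) {
    int n = reads.size();
    int p = primer.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        const char *r = CHAR(STRING_ELT(reads, i));
        int len = LENGTH(STRING_ELT(reads, i));
        int best_pos = -1, best_d = p + 1;
        for (int off = 0; off + p <= len; ++off) {
            int d = 0;
            for (int j = 0; j < p && d < best_d; ++j)
                if (r[off + j] != primer[j]) ++d;
            if (d < best_d) { // strict: ties keep the leftmost window
                best_d = d;
                best_pos = off;
                if (d == 0) break;
            }
        }
        out(i, 0) = best_pos;
        out(i, 1) = best_pos < 0 ? -1 : best_d;
    }
    return out;
}
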