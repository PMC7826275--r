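#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Match-run profile of a read (seq1, length n) against the periodic
// extension of a repeat unit (seq2, length m).
//
// Conceptually an n x n matrix is formed whose column j is the wrapped,
// shifted unit: a[i][j] = r[(i - j) mod m]. Cells matching s[i] become 1,
// vertical runs of 1s are replaced by their run length, runs shorter than
// X are zeroed, and c[i] is the row sum. Columns j and j + m are
// identical, so each distinct phase p = j mod m is computed once and
// weighted by its column multiplicity floor(n/m) + (p < n mod m).
//
// Ambiguous bases never match (strict A/C/G/T byte comparison against a
// unit restricted to A/C/G/T), so N in a read contributes nothing.
//
// Returns a numeric vector: counts can exceed integer range on
// pathological low-complexity input (c_i <= n * n in the worst case).
// [[Rcpp::export(name = ".match_run_profile_cpp")]]
NumericVector match_run_profile_cpp(std::string seq1, std::string seq2,
                                    int X) {
    const int n = (int) seq1.size();
    const int m = (int) seq2.size();
    if (m < 1) stop("unit length m must be >= 1");
    if (X < 1) stop("X must be >= 1");
    NumericVector out(n);
    if (n == 0) return out;

    const char *s = seq1.c_str();
    const char *r = seq2.c_str();
    const int base_w = n / m;
    const int rem = n % m;

    std::vector<int> runstart(n);

    for (int p = 0; p < m; ++p) {
        const double w = base_w + (p < rem ? 1 : 0);
        if (w == 0) continue;
        // q = (i - p) mod m for i = 0, starting index into the unit
        int q = (m - (p % m)) % m;
        int start = -1; // start of current match run, -1 = not in run
        for (int i = 0; i < n; ++i) {
            const bool match = (s[i] == r[q]);
            if (match) {
                if (start < 0) start = i;
            } else if (start >= 0) {
                const int len = i - start;
                if (len >= X) {
                    const double add = w * (double) len;
                    for (int t = start; t < i; ++t) out[t] += add;
                }
                start = -1;
            }
            if (++q == m) q = 0;
        }
        if (start >= 0) {
            const int len = n - start;
            if (len >= X) {
                const double add = w * (double) len;
                for (int t = start; t < n; ++t) out[t] += add;
            }
        }
    }
    return out;
}

// Exact k-mer matches between a read and a reference, forward strand
// only (strand handling and reverse complementing are done in R).
// Returns 0-based positions. A simple rolling 2-bit hash over A/C/G/T;
// windows containing other letters are skipped on both sides.
// [[Rcpp::export(name = ".kmer_matches_cpp")]]
DataFrame kmer_matches_cpp(std::string read, std::string ref, int k) {
    const int n = (int) read.size();
    const int M = (int) ref.size();
    std::vector<int> rpos, fpos;
    if (k < 1 || n < k || M < k)
        return DataFrame::create(Named("readPos") = IntegerVector(0),
                                 Named("refPos") = IntegerVector(0));
    if (k > 31) stop("k must be <= 31");

    auto code = [](char c) -> int {
        switch (c) {
        case 'A': return 0; case 'C': return 1;
        case 'G': return 2; case 'T': return 3;
        default: return -1;
        }
    };

    // hash table of reference k-mers -> positions (chained)
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::unordered_multimap<uint64_t, int> tab;
    tab.reserve(M);
    {
        uint64_t h = 0; int valid = 0;
        for (int i = 0; i < M; ++i) {
            int c = code(ref[i]);
            if (c < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t) c) & mask;
            if (++valid >= k) tab.emplace(h, i - k + 1);
        }
    }
    {
        uint64_t h = 0; int valid = 0;
        for (int i = 0; i < n; ++i) {
            int c = code(read[i]);
            if (c < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t) c) & mask;
            if (++valid >= k) {
                auto range = tab.equal_range(h);
                const int rp = i - k + 1;
                for (auto it = range.first; it != range.second; ++it) {
                    // verify (hash is exact for k <= 31, but be safe)
                    if (std::memcmp(read.c_str() + rp,
                                    ref.c_str() + it->second, k) == 0) {
                        rpos.push_back(rp);
                        fpos.push_back(it->second);
                    }
                }
            }
        }
    }
    return DataFrame::create(Named("readPos") = wrap(rpos),
                             Named("refPos") = wrap(fpos));
}
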