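#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// Canonical k-mers are 2-bit encoded (A=0, C=1, G=2, T=3, first base most
// significant), so for k <= 26 a code occupies <= 52 bits and is exactly
// representable as an R double. Lexicographic order on ACGT strings equals
// numeric order on codes, so min(code, revcomp code) is the canonical form.

static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

static inline bool keep_kmer(uint64_t code, double sketch_fraction,
                             uint64_t seed_mix) {
    if (sketch_fraction >= 1.0) return true;
    uint64_t h = splitmix64(code ^ seed_mix);
    // threshold = f * 2^64, computed once per call in the caller would be
    // marginally faster but this stays exact and deterministic
    uint64_t thr = (uint64_t)(sketch_fraction * 18446744073709551616.0);
    return h < thr;
}

static void collect_kmers(const std::string& seq, int k,
                          double sketch_fraction, uint64_t seed_mix,
                          std::vector<uint64_t>& out) {
    const size_t n = seq.size();
    if ((int)n < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int filled = 0;
    for (size_t i = 0; i < n; ++i) {
        int b = base2bits(seq[i]);
        if (b < 0) { filled = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++filled >= k) {
            uint64_t canon = std::min(fwd, rev);
            if (keep_kmer(canon, sketch_fraction, seed_mix))
                out.push_back(canon);
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_kmer_set(std::vector<std::string> seqs, int k,
                           double sketch_fraction, int hash_seed) {
    if (k < 1 || k > 26) stop("k must be in 1..26");
    uint64_t seed_mix = splitmix64((uint64_t)hash_seed);
    std::vector<uint64_t> km;
    for (const auto& s : seqs) collect_kmers(s, k, sketch_fraction, seed_mix, km);
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    NumericVector out(km.size());
    for (size_t i = 0; i < km.size(); ++i) out[i] = (double)km[i];
    return out;
}

// [[Rcpp::export]]
List cpp_shared_count(std::string seq, int k, double sketch_fraction,
                      int hash_seed, NumericVector db_sorted) {
    if (k < 1 || k > 26) stop("k must be in 1..26");
    uint64_t seed_mix = splitmix64((uint64_t)hash_seed);
    std::vector<uint64_t> km;
    collect_kmers(seq, k, sketch_fraction, seed_mix, km);
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    std::vector<uint64_t> db(db_sorted.size());
    for (R_xlen_t i = 0; i < db_sorted.size(); ++i)
        db[i] = (uint64_t)db_sorted[i];
    long shared = 0;
    for (uint64_t x : km)
        if (std::binary_search(db.begin(), db.end(), x)) ++shared;
    return List::create(_["n_query_kmers"] = (double)km.size(),
                        _["n_shared"] = (double)shared);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
    if (k < 1 || k > 26) stop("k must be in 1..26");
    static const char bases[] = "ACGT";
    CharacterVector out(codes.size());
    std::string buf(k, 'A');
    for (R_xlen_t i = 0; i < codes.size(); ++i) {
        uint64_t c = (uint64_t)codes[i];
        for (int j = k - 1; j >= 0; --j) {
            buf[j] = bases[c & 3ULL];
            c >>= 2;
        }
        out[i] = buf;
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_encode_kmers(std::vector<std::string> kmers, int k,
                               bool canonical) {
    if (k < 1 || k > 26) stop("k must be in 1..26");
    const int shift = 2 * (k - 1);
    NumericVector out(kmers.size());
    for (size_t i = 0; i < kmers.size(); ++i) {
        if ((int)kmers[i].size() != k) stop("k-mer length mismatch");
        uint64_t fwd = 0, rev = 0;
        for (int j = 0; j < k; ++j) {
            int b = base2bits(kmers[i][j]);
            if (b < 0) stop("ambiguous k-mer");
            fwd = (fwd << 2) | (uint64_t)b;
            rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        }
        out[i] = (double)(canonical ? std::min(fwd, rev) : fwd);
    }
    return out;
}

// Best ungapped local alignment score between two integer-encoded strings:
// per diagonal, maximum-sum segment (Kadane) of match/mismatch scores.
// [[Rcpp::export]]
double cpp_ungapped_local(IntegerVector a, IntegerVector b,
                          double match, double mismatch) {
    const int m = a.size(), n = b.size();
    if (m == 0 || n == 0) return 0.0;
    double best = 0.0;
    for (int d = -(m - 1); d <= n - 1; ++d) {
        int i0 = std::max(0, -d);
        int j0 = i0 + d;
        double run = 0.0;
        for (int i = i0, j = j0; i < m && j < n; ++i, ++j) {
            double s = (a[i] == b[j]) ? match : mismatch;
            run = std::max(0.0, run + s);
            if (run > best) best = run;
        }
    }
    return best;
}

// Standard-code translation; codons with non-ACGT characters become 'X'.
// [[Rcpp::export]]
std::string cpp_translate(std::string seq) {
    static const char* aa =
        // index = 16*b1 + 4*b2 + b3 over ACGT
        "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";
    const size_t n = seq.size() / 3;
    std::string out(n, 'X');
    for (size_t i = 0; i < n; ++i) {
        int b1 = base2bits(seq[3 * i]);
        int b2 = base2bits(seq[3 * i + 1]);
        int b3 = base2bits(seq[3 * i + 2]);
        if (b1 >= 0 && b2 >= 0 && b3 >= 0)
            out[i] = aa[16 * b1 + 4 * b2 + b3];
    }
    return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
    std::string out(seq.size(), 'N');
    for (size_t i = 0; i < seq.size(); ++i) {
        char c = seq[seq.size() - 1 - i];
        switch (c) {
        case 'A': case 'a': out[i] = 'T'; break;
        case 'C': case 'c': out[i] = 'G'; break;
        case 'G': case 'g': out[i] = 'C'; break;
        case 'T': case 't': out[i] = 'A'; break;
        default: out[i] = 'N';
        }
    }
    return out;
}

// Order-2 Markov sequence sampler; trans is 16 x 4 (rows indexed by the two
// previous bases, 4*b1+b2), rows sum to 1. Uses R's RNG so set.seed() governs.
// [[Rcpp::export]]
std::string cpp_markov_seq(int n, NumericMatrix trans) {
    if (trans.nrow() != 16 || trans.ncol() != 4) stop("trans must be 16 x 4");
    static const char bases[] = "ACGT";
    std::string out;
    if (n <= 0) return out;
    out.reserve(n);
    RNGScope scope;
    // first two bases from the stationary-ish uniform draw over rows
    int b1 = (int)(unif_rand() * 4.0); if (b1 > 3) b1 = 3;
    out.push_back(bases[b1]);
    if (n == 1) return out;
    int b2 = (int)(unif_rand() * 4.0); if (b2 > 3) b2 = 3;
    out.push_back(bases[b2]);
    for (int i = 2; i < n; ++i) {
        int row = 4 * b1 + b2;
        double u = unif_rand(), acc = 0.0;
        int nb = 3;
        for (int j = 0; j < 4; ++j) {
            acc += trans(row, j);
            if (u < acc) { nb = j; break; }
        }
        out.push_back(bases[nb]);
        b1 = b2; b2 = nb;
    }
    return out;
}
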