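// In-memory canonical k-mer counter. k-mers (k <= 31) are 2-bit encoded into
// uint64 keys; tables are std::unordered_map held behind an XPtr because R
// doubles cannot represent 62-bit keys exactly.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>

using namespace Rcpp;

typedef std::unordered_map<uint64_t, int32_t> KmerMap;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline uint64_t revcomp_code(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3ULL - (x & 3ULL));
        x >>= 2;
    }
    return r;
}

static inline uint64_t canon_code(uint64_t x, int k) {
    uint64_t r = revcomp_code(x, k);
    return x < r ? x : r;
}

static std::string decode_kmer(uint64_t x, int k) {
    static const char bases[] = "ACGT";
    std::string s(k, 'N');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bases[x & 3ULL];
        x >>= 2;
    }
    return s;
}

// Encode one k-mer string; returns false if it contains a non-ACGT base.
static bool encode_kmer(const char* s, int k, uint64_t& out) {
    uint64_t x = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[i]);
        if (c < 0) return false;
        x = (x << 2) | (uint64_t)c;
    }
    out = x;
    return true;
}

template <typename F>
static void for_each_canonical_kmer(const char* s, R_xlen_t n, int k, F f) {
    uint64_t mask = (1ULL << (2 * k)) - 1;  // k <= 31 enforced R-side
    uint64_t cur = 0;
    int have = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { have = 0; cur = 0; continue; }
        cur = ((cur << 2) | (uint64_t)c) & mask;
        if (++have >= k) f(canon_code(cur, k));
    }
}

static void check_k(int k) {
    if (k < 2 || k > 31) stop("k must be between 2 and 31");
}

static KmerMap* get_map(SEXP ptr) {
    XPtr<KmerMap> p(ptr);
    if (!p) stop("invalid k-mer table pointer");
    return p.get();
}

// [[Rcpp::export(name = ".cpp_kmer_table_build")]]
SEXP cpp_kmer_table_build(CharacterVector seqs, int k) {
    check_k(k);
    XPtr<KmerMap> tab(new KmerMap(), true);
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        if (seqs[j] == NA_STRING) continue;
        const char* s = CHAR(seqs[j]);
        R_xlen_t n = LENGTH(seqs[j]);
        for_each_canonical_kmer(s, n, k, [&](uint64_t km) { (*tab)[km]++; });
    }
    return tab;
}

// Count canonical k-mers of `seqs` that are keys of `universe`.
// [[Rcpp::export(name = ".cpp_kmer_count_in")]]
SEXP cpp_kmer_count_in(SEXP universe, CharacterVector seqs, int k) {
    check_k(k);
    KmerMap* uni = get_map(universe);
    XPtr<KmerMap> tab(new KmerMap(), true);
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        if (seqs[j] == NA_STRING) continue;
        const char* s = CHAR(seqs[j]);
        R_xlen_t n = LENGTH(seqs[j]);
        for_each_canonical_kmer(s, n, k, [&](uint64_t km) {
            if (uni->count(km)) (*tab)[km]++;
        });
    }
    return tab;
}

// [[Rcpp::export(name = ".cpp_kmer_table_lookup")]]
IntegerVector cpp_kmer_table_lookup(SEXP ptr, CharacterVector kmers, int k) {
    check_k(k);
    KmerMap* tab = get_map(ptr);
    R_xlen_t n = kmers.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (kmers[i] == NA_STRING || LENGTH(kmers[i]) != k) {
            out[i] = NA_INTEGER;
            continue;
        }
        uint64_t x;
        if (!encode_kmer(CHAR(kmers[i]), k, x)) { out[i] = NA_INTEGER; continue; }
        KmerMap::const_iterator it = tab->find(canon_code(x, k));
        out[i] = (it == tab->end()) ? 0 : it->second;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_kmer_table_size")]]
double cpp_kmer_table_size(SEXP ptr) {
    return (double)get_map(ptr)->size();
}

// [[Rcpp::export(name = ".cpp_kmer_table_counts")]]
IntegerVector cpp_kmer_table_counts(SEXP ptr) {
    KmerMap* tab = get_map(ptr);
    IntegerVector out(tab->size());
    R_xlen_t i = 0;
    for (KmerMap::const_iterator it = tab->begin(); it != tab->end(); ++it)
        out[i++] = it->second;
    return out;
}

// All k-mers of one sequence in positional order; canonical form if requested;
// NA where the window contains a non-ACGT base.
// [[Rcpp::export(name = ".cpp_seq_kmers")]]
CharacterVector cpp_seq_kmers(std::string seq, int k, bool canonical) {
    check_k(k);
    R_xlen_t n = (R_xlen_t)seq.size();
    if (n < k) return CharacterVector(0);
    CharacterVector out(n - k + 1);
    uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t cur = 0;
    int have = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { have = 0; cur = 0; } else {
            cur = ((cur << 2) | (uint64_t)c) & mask;
            ++have;
        }
        if (i >= k - 1) {
            if (have >= k) {
                uint64_t x = canonical ? canon_code(cur, k) : cur;
                out[i - k + 1] = decode_kmer(x, k);
            } else {
                out[i - k + 1] = NA_STRING;
            }
        }
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_canonical_kmer")]]
CharacterVector cpp_canonical_kmer(CharacterVector kmers, int k) {
    check_k(k);
    R_xlen_t n = kmers.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (kmers[i] == NA_STRING || LENGTH(kmers[i]) != k) { out[i] = NA_STRING; continue; }
        uint64_t x;
        if (!encode_kmer(CHAR(kmers[i]), k, x)) { out[i] = NA_STRING; continue; }
        out[i] = decode_kmer(canon_code(x, k), k);
    }
    return out;
}
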