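#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Bob Jenkins' one-at-a-time hash over a byte string, exact uint32 semantics.
static uint32_t oaat(const unsigned char *key, R_xlen_t len) {
    uint32_t h = 0;
    for (R_xlen_t i = 0; i < len; ++i) {
        h += key[i];
        h += h << 10;
        h ^= h >> 6;
    }
    h += h << 3;
    h ^= h >> 11;
    h += h << 15;
    return h;
}

// [[Rcpp::export]]
NumericVector oaat_hash(List keys) {
    R_xlen_t nk = keys.size();
    NumericVector out(nk);
    for (R_xlen_t i = 0; i < nk; ++i) {
        RawVector k = keys[i];
        out[i] = static_cast<double>(oaat(RAW(k), k.size()));
    }
    return out;
}
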