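#include <Rcpp.h>
using namespace Rcpp;

// FNV-1a 32-bit hash over the bytes of a string.
static uint32_t fnv1a(const char *s, int len) {
  uint32_t h = 2166136261u;
  for (int i = 0; i < len; ++i) {
    h ^= (uint32_t)(unsigned char)s[i];
    h *= 16777619u;
  }
  return h;
}

// Hashed character n-gram bag embedding. Each text is padded with '#'
// on both sides, every character n-gram with n in [n_min, n_max] is
// FNV-1a-hashed into one of `dim` buckets, and the bucket counts are
// L2-normalized (empty text -> zero vector). Columns are texts.
// [[Rcpp::export]]
NumericMatrix hash_ngram_embed_cpp(CharacterVector texts, int dim,
                                   int n_min, int n_max) {
  int m = texts.size();
  NumericMatrix out(dim, m);
  for (int j = 0; j < m; ++j) {
    if (CharacterVector::is_na(texts[j])) continue;
    std::string raw = Rcpp::as<std::string>(texts[j]);
    if (raw.empty()) continue;
    std::string s = "#" + raw + "#";
    int L = (int)s.size();
    double *col = &out(0, j);
    for (int n = n_min; n <= n_max; ++n) {
      for (int i = 0; i + n <= L; ++i) {
        uint32_t h = fnv1a(s.c_str() + i, n);
        col[h % (uint32_t)dim] += 1.0;
      }
    }
    double ss = 0.0;
    for (int k = 0; k < dim; ++k) ss += col[k] * col[k];
    if (ss > 0) {
      double inv = 1.0 / std::sqrt(ss);
      for (int k = 0; k < dim; ++k) col[k] *= inv;
    }
  }
  return out;
}

// FNV-1a bucket indices (0-based) of each string in `grams`, used by
// tests to recompute bucket positions independently of the embedder.
// [[Rcpp::export]]
IntegerVector fnv1a_bucket_cpp(CharacterVector grams, int dim) {
  int m = grams.size();
  IntegerVector out(m);
  for (int j = 0; j < m; ++j) {
    std::string s = Rcpp::as<std::string>(grams[j]);
    out[j] = (int)(fnv1a(s.c_str(), (int)s.size()) % (uint32_t)dim);
  }
  return out;
}
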