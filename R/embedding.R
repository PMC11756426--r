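#' Embedding backends
#'
#' Texts are encoded into fixed-size vectors before cosine-similarity
#' retrieval. The default backend is a deterministic hashed character
#' 3--5-gram bag-of-ngrams: each text is padded with `#` on both sides,
#' every character n-gram is hashed with 32-bit FNV-1a modulo the
#' dimension, and the bucket counts are L2-normalized. It requires no
#' model download and preserves "similar strings get similar vectors"
#' well enough for retrieval of close paraphrases. A pretrained
#' sentence-transformer backend can be named in configuration
#' (`sentence_transformer` with a `model_id`), but encoding with it
#' requires the external model and raises a capability error here.
#'
#' @param name Backend name: `"hashed_ngram"` or `"sentence_transformer"`.
#' @param dimension Embedding dimension (default 512 for the hashed
#'   backend).
#' @param n_min,n_max Character n-gram range for the hashed backend.
#' @param model_id Model identifier for the sentence-transformer backend.
#' @return A list of class `embedding_backend` with fields `name`,
#'   `dimension`, `normalizes`.
#' @export
#' @examples
#' b <- embedding_backend()
#' v <- embed_texts(b, c("poor effort with pushing", "poor effort pushing"))
#' cosine_similarity(v[, 1], v[, 2])
embedding_backend <- function(name = c("hashed_ngram", "sentence_transformer"),
                              dimension = 512L, n_min = 3L, n_max = 5L,
                              model_id = "multi-qa-distilbert-cos-v1") {
  name <- match.arg(name)
  stopifnot(dimension >= 1, n_min >= 1, n_max >= n_min)
  structure(list(name = name, dimension = as.integer(dimension),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 model_id = model_id, normalizes = TRUE),
            class = "embedding_backend")
}

#' Embed texts into fixed-size vectors
#'
#' @param backend An [embedding_backend()].
#' @param texts Character vector.
#' @return A `dimension x length(texts)` numeric matrix; each non-empty
#'   text gives a unit-L2-norm column, empty text a zero column.
#' @export
embed_texts <- function(backend, texts) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (backend$name == "sentence_transformer") {
    stop("capability error: the pretrained sentence-transformer backend '",
         backend$model_id, "' is not available in this installation; ",
         "use the hashed_ngram backend", call. = FALSE)
  }
  hash_ngram_embed_cpp(as.character(texts), backend$dimension,
                       backend$n_min, backend$n_max)
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`, defined as 0 when either norm is zero so
#' empty-text embeddings never propagate NaN.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

# Cosine similarities of one query against the columns of a matrix,
# with the zero-norm-gives-0 convention.
cosine_to_columns <- function(mat, query) {
  nq <- sqrt(sum(query^2))
  if (nq == 0) return(rep(0, ncol(mat)))
  norms <- sqrt(colSums(mat^2))
  dots <- as.numeric(crossprod(mat, query))
  sims <- ifelse(norms == 0, 0, dots / (norms * nq))
  pmin(1, pmax(-1, sims))
}

# FNV-1a bucket of each string (0-based), exposed for independent
# recomputation of hashed-backend bucket positions.
fnv1a_bucket <- function(grams, dimension) {
  fnv1a_bucket_cpp(as.character(grams), as.integer(dimension))
}
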